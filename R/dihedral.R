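# torsion angle (deg, IUPAC sign) for four points given as n x 3 matrices
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (any(rownorm(n1) < 1e-9) || any(rownorm(n2) < 1e-9))
    stop("undefined torsion: collinear atoms", call. = FALSE)
  b2u <- b2 / rownorm(b2)
  x <- rowSums(n1 * n2)
  y <- rowSums(cross3(n1, n2) * b2u)
  atan2(y, x) * 180 / pi
}

#' Backbone dihedral time series of a trajectory ensemble
#'
#' Extracts phi(i) = C(i-1)-N(i)-CA(i)-C(i) and psi(i) =
#' N(i)-CA(i)-C(i)-N(i+1) for every frame of every replica (IUPAC sign
#' convention). Terminal residues lacking a torsion are omitted. Replicas are
#' concatenated with the boundaries recorded.
#'
#' @param ens A `traj_ensemble` whose topology contains `N`, `CA` and `C`
#'   atoms for consecutive residues.
#' @return A `dihedral_ensemble`: `angles` (total frames x torsions matrix,
#'   degrees in (-180, 180]), `torsions` (data frame `resno`, `torsion`),
#'   `replica` (replica id per row).
#' @export
compute_dihedrals <- function(ens) {
  stopifnot(inherits(ens, "traj_ensemble"))
  topo <- ens$topology
  resnos <- sort(unique(topo$resno))
  idx_of <- function(r, ety) {
    i <- which(topo$resno == r & topo$elety == ety)
    if (length(i) == 0L) NA_integer_ else i[1]
  }
  iN  <- vapply(resnos, idx_of, integer(1), "N")
  iCA <- vapply(resnos, idx_of, integer(1), "CA")
  iC  <- vapply(resnos, idx_of, integer(1), "C")
  if (anyNA(iN) || anyNA(iCA) || anyNA(iC))
    stop("topology must contain N, CA and C atoms for every residue",
         call. = FALSE)
  nres <- length(resnos)
  # torsion definitions: (atom indices) and labels
  defs <- list()
  for (k in seq_len(nres)) {
    consec_prev <- k > 1L && resnos[k] - resnos[k - 1L] == 1L
    consec_next <- k < nres && resnos[k + 1L] - resnos[k] == 1L
    if (consec_prev)
      defs[[length(defs) + 1L]] <- list(resno = resnos[k], torsion = "phi",
                                        atoms = c(iC[k - 1L], iN[k], iCA[k], iC[k]))
    if (consec_next)
      defs[[length(defs) + 1L]] <- list(resno = resnos[k], torsion = "psi",
                                        atoms = c(iN[k], iCA[k], iC[k], iN[k + 1L]))
  }
  if (length(defs) == 0L) stop("no torsions definable", call. = FALSE)
  tor <- data.frame(resno = vapply(defs, `[[`, integer(1), "resno"),
                    torsion = vapply(defs, `[[`, character(1), "torsion"))
  coords_of <- function(mat, a) mat[, (3L * a - 2L):(3L * a), drop = FALSE]
  ang_list <- lapply(seq_along(ens$replicas), function(r) {
    mat <- ens$replicas[[r]]
    a <- matrix(NA_real_, nrow(mat), length(defs))
    for (j in seq_along(defs)) {
      at <- defs[[j]]$atoms
      a[, j] <- dihedral_angle(coords_of(mat, at[1]), coords_of(mat, at[2]),
                               coords_of(mat, at[3]), coords_of(mat, at[4]))
    }
    a
  })
  angles <- do.call(rbind, ang_list)
  colnames(angles) <- paste0(tor$torsion, tor$resno)
  structure(list(angles = angles, torsions = tor,
                 replica = rep(seq_along(ens$replicas),
                               vapply(ens$replicas, nrow, integer(1)))),
            class = "dihedral_ensemble")
}

#' @export
print.dihedral_ensemble <- function(x, ...) {
  cat(sprintf("Dihedral ensemble: %d torsions over %d residues, %d frames (%d replicas)\n",
              ncol(x$angles), length(unique(x$torsions$resno)),
              nrow(x$angles), length(unique(x$replica))))
  invisible(x)
}

# equal-width circular bin index over (-180, 180]
bin_angles <- function(x, bin_count) {
  b <- ceiling((x + 180) / (360 / bin_count))
  b[b < 1L] <- 1L
  b[b > bin_count] <- bin_count
  as.integer(b)
}

entropy_from_counts <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

# plug-in MI (nats) from precomputed bin indices
mi_from_bins <- function(bx, by, B) {
  n <- length(bx)
  hxy <- entropy_from_counts(tabulate(bx + B * (by - 1L), B * B), n)
  hx <- entropy_from_counts(tabulate(bx, B), n)
  hy <- entropy_from_counts(tabulate(by, B), n)
  hx + hy - hxy
}

#' Mutual information between two angle series
#'
#' Histogram estimate MI = H(x) + H(y) - H(x, y) in nats, with equal-width
#' circular binning over (-180, 180]. The optional shuffle correction
#' subtracts the mean MI of `n_shuffle` independent permutations of `y`
#' (the finite-sample bias of the plug-in estimator), so corrected values for
#' independent series scatter around zero.
#'
#' @param x,y Angle series, degrees, equal length >= 10 * `bin_count`.
#' @param bin_count Number of bins (default 24, i.e. 15-degree bins).
#' @param bias_correction `"none"` or `"shuffle"`.
#' @param n_shuffle Number of permutations for the shuffle null.
#' @param seed Seed for the permutation generator.
#' @return MI in nats. With shuffle correction the result carries attributes
#'   `raw`, `null_mean` and `null_sd`.
#' @export
mutual_information <- function(x, y, bin_count = 24L,
                               bias_correction = c("none", "shuffle"),
                               n_shuffle = 10L, seed = 1L) {
  bias_correction <- match.arg(bias_correction)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (bin_count < 2L) stop("bin_count must be >= 2", call. = FALSE)
  if (length(x) < 10L * bin_count)
    stop("need at least 10 samples per bin (length >= 10 * bin_count)",
         call. = FALSE)
  B <- as.integer(bin_count)
  bx <- bin_angles(x, B); by <- bin_angles(y, B)
  mi <- mi_from_bins(bx, by, B)
  if (bias_correction == "none") return(mi)
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffle),
           function(i) mi_from_bins(bx, sample(by), B), numeric(1))
  })
  structure(mi - mean(null), raw = mi, null_mean = mean(null),
            null_sd = sd0(null))
}

#' Residue-pair mutual-information matrix
#'
#' Raw residue-pair MI is the sum of the pairwise torsion MIs between the two
#' residues' torsion sets (phi/psi), estimated over the concatenated
#' replicas. The normalized matrix divides by the smaller of the two
#' residues' summed marginal torsion entropies and is clipped to [0, 1];
#' shuffle-corrected raw values are floored at 0 first. The diagonal of the
#' raw matrix is zero by convention (self-coupling is reported as 1 in the
#' normalized matrix).
#'
#' @param dih A `dihedral_ensemble`.
#' @param bin_count Bins per angle (default 24).
#' @param bias_correction `"shuffle"` (default) or `"none"`.
#' @param n_shuffle Permutations per torsion pair for the shuffle null.
#' @param seed Seed for the permutation generator.
#' @return An `mi_matrix`: `raw` and `normalized` residue x residue matrices
#'   (dimnames = residue numbers), `marginal_entropy` per residue,
#'   `bin_count`, `bias_corrected`.
#' @export
residue_mi_matrix <- function(dih, bin_count = 24L,
                              bias_correction = c("shuffle", "none"),
                              n_shuffle = 10L, seed = 1L) {
  bias_correction <- match.arg(bias_correction)
  stopifnot(inherits(dih, "dihedral_ensemble"))
  resnos <- sort(unique(dih$torsions$resno))
  if (length(resnos) < 2L) stop("need torsions for at least 2 residues",
                                call. = FALSE)
  B <- as.integer(bin_count)
  n <- nrow(dih$angles)
  bins <- apply(dih$angles, 2, bin_angles, bin_count = B)
  h_tor <- apply(bins, 2, function(b) entropy_from_counts(tabulate(b, B), n))
  tor_of <- lapply(resnos, function(r) which(dih$torsions$resno == r))
  h_res <- vapply(tor_of, function(ix) sum(h_tor[ix]), numeric(1))

  # one shared set of permutations for the shuffle null across all pairs
  perms <- if (bias_correction == "shuffle")
    with_seed(seed, replicate(n_shuffle, sample.int(n), simplify = FALSE))
  else list()

  nres <- length(resnos)
  raw <- matrix(0, nres, nres, dimnames = list(resnos, resnos))
  for (i in seq_len(nres - 1L)) {
    for (j in (i + 1L):nres) {
      s <- 0
      for (ti in tor_of[[i]]) {
        bi <- bins[, ti]
        for (tj in tor_of[[j]]) {
          bj <- bins[, tj]
          mi <- mi_from_bins(bi, bj, B)
          if (bias_correction == "shuffle") {
            null <- vapply(perms, function(p) mi_from_bins(bi, bj[p], B),
                           numeric(1))
            mi <- mi - mean(null)
          }
          s <- s + mi
        }
      }
      raw[i, j] <- raw[j, i] <- s
    }
  }
  norm <- raw
  norm[norm < 0] <- 0
  denom <- outer(h_res, h_res, pmin)
  pos <- denom > 0
  norm[pos] <- pmin(norm[pos] / denom[pos], 1)
  norm[!pos] <- 0
  diag(norm) <- 1
  names(h_res) <- resnos
  structure(list(raw = raw, normalized = norm, marginal_entropy = h_res,
                 bin_count = B, bias_corrected = bias_correction == "shuffle"),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  off <- x$normalized[upper.tri(x$normalized)]
  cat(sprintf("MI matrix: %d residues, %d bins, bias %scorrected\n",
              nrow(x$raw), x$bin_count, if (x$bias_corrected) "" else "un"))
  cat(sprintf("Normalized off-diagonal: median %.3f, max %.3f\n",
              stats::median(off), max(off)))
  invisible(x)
}

#' Thresholded intra/inter-domain coupling report
#'
#' Lists residue pairs whose normalized mutual information strictly exceeds
#' the threshold (0.3 by default, the fixed cutoff for highly correlated
#' pairs), classifies each pair by domain membership, and compares the mean
#' coupling strength between and within domains.
#'
#' @param mi An `mi_matrix`.
#' @param domain1,domain2 Non-overlapping `domain_def` ranges.
#' @param threshold Normalized-MI cutoff (default 0.3).
#' @return A `coupling_report`: `pairs` (data frame `res_i`, `res_j`, `mi`,
#'   `class`), `summary` (mean normalized MI per class), `inter_intra_ratio`
#'   (NA with `ratio_defined = FALSE` when either class is empty),
#'   `threshold`.
#' @export
coupling_report <- function(mi, domain1, domain2, threshold = 0.3) {
  stopifnot(inherits(mi, "mi_matrix"),
            inherits(domain1, "domain_def"), inherits(domain2, "domain_def"))
  if (domain1$end >= domain2$start && domain2$end >= domain1$start)
    stop("domains overlap", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  resnos <- as.integer(rownames(mi$normalized))
  ut <- which(upper.tri(mi$normalized) & mi$normalized > threshold,
              arr.ind = TRUE)
  classify <- function(ri, rj) {
    a1 <- in_domain(ri, domain1); a2 <- in_domain(ri, domain2)
    b1 <- in_domain(rj, domain1); b2 <- in_domain(rj, domain2)
    if (a1 && b1) paste0("intra-", domain1$name)
    else if (a2 && b2) paste0("intra-", domain2$name)
    else if ((a1 && b2) || (a2 && b1)) "inter-domain"
    else "linker-involving"
  }
  pairs <- if (nrow(ut)) {
    data.frame(res_i = resnos[ut[, 1]], res_j = resnos[ut[, 2]],
               mi = mi$normalized[ut],
               class = mapply(classify, resnos[ut[, 1]], resnos[ut[, 2]]))
  } else {
    data.frame(res_i = integer(), res_j = integer(), mi = numeric(),
               class = character())
  }
  summary <- if (nrow(pairs)) tapply(pairs$mi, pairs$class, mean) else
    stats::setNames(numeric(0), character(0))
  intra <- pairs$mi[startsWith(pairs$class, "intra")]
  inter <- pairs$mi[pairs$class == "inter-domain"]
  ratio_defined <- length(intra) > 0 && length(inter) > 0
  structure(list(pairs = pairs, summary = summary,
                 inter_intra_ratio = if (ratio_defined)
                   mean(inter) / mean(intra) else NA_real_,
                 ratio_defined = ratio_defined,
                 threshold = threshold,
                 domains = list(domain1, domain2)),
            class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat(sprintf("Coupling report (normalized MI > %.2f): %d pair(s)\n",
              x$threshold, nrow(x$pairs)))
  if (nrow(x$pairs)) {
    print(table(x$pairs$class))
    if (x$ratio_defined)
      cat(sprintf("inter/intra mean strength ratio: %.2f\n", x$inter_intra_ratio))
    else cat("inter/intra ratio undefined (a class is empty)\n")
  }
  invisible(x)
}
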