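#' Build a replica trajectory ensemble
#'
#' Container for replica MD trajectories sharing one topology. Coordinates
#' follow the bio3d `xyz` convention: one row per frame, columns
#' `(x1, y1, z1, x2, ...)`.
#'
#' @param replicas List of frame x (3 * n_atoms) coordinate matrices
#'   (Angstrom), one per replica.
#' @param topology Data frame with one row per atom: `resno`, `elety`.
#' @param frame_spacing Time between frames, ns.
#' @return A `traj_ensemble`.
#' @export
trajectory_ensemble <- function(replicas, topology, frame_spacing = 0.1) {
  if (!is.list(replicas) || length(replicas) == 0L)
    stop("`replicas` must be a non-empty list of coordinate matrices",
         call. = FALSE)
  n_xyz <- 3L * nrow(topology)
  for (r in seq_along(replicas)) {
    m <- replicas[[r]]
    if (!is.matrix(m) || ncol(m) != n_xyz)
      stop(sprintf("replica %d: expected %d coordinate columns, got %s",
                   r, n_xyz, ncol(m)), call. = FALSE)
    if (nrow(m) < 2L)
      stop(sprintf("replica %d has fewer than 2 frames", r), call. = FALSE)
    if (!all(is.finite(m)))
      stop(sprintf("replica %d contains non-finite coordinates", r),
           call. = FALSE)
  }
  structure(list(replicas = replicas,
                 topology = topology,
                 frame_spacing = frame_spacing),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d replica(s) x %s frames, %d atoms, %d residues\n",
              length(x$replicas),
              paste(vapply(x$replicas, nrow, integer(1)), collapse = "/"),
              nrow(x$topology), length(unique(x$topology$resno))))
  invisible(x)
}

#' Read replica trajectories from multi-model PDB files
#'
#' Each file holds one replica, one MODEL block per frame. All files must
#' share the same topology (residue numbering and atom names).
#'
#' @param paths Character vector of multi-model PDB files.
#' @param frame_spacing Time between frames, ns.
#' @return A `traj_ensemble`.
#' @export
read_trajectory <- function(paths, frame_spacing = 0.1) {
  reps <- vector("list", length(paths))
  topo <- NULL
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) stop("trajectory not found: ", paths[i],
                                     call. = FALSE)
    pdb <- bio3d::read.pdb(paths[i], multi = TRUE, verbose = FALSE)
    ti <- data.frame(resno = pdb$atom$resno, elety = pdb$atom$elety)
    if (is.null(topo)) topo <- ti
    else if (!identical(topo, ti))
      stop("replica topologies differ: ", paths[i], call. = FALSE)
    reps[[i]] <- pdb$xyz
  }
  trajectory_ensemble(reps, topo, frame_spacing = frame_spacing)
}

#' Write a trajectory ensemble as multi-model PDB files
#'
#' @param ens A `traj_ensemble`.
#' @param paths Output paths, one per replica.
#' @return `paths`, invisibly.
#' @export
write_trajectory <- function(ens, paths) {
  stopifnot(inherits(ens, "traj_ensemble"),
            length(paths) == length(ens$replicas))
  resid <- rep("ALA", nrow(ens$topology))
  for (i in seq_along(paths)) {
    bio3d::write.pdb(file = paths[i], xyz = ens$replicas[[i]],
                     resno = ens$topology$resno, resid = resid,
                     eleno = seq_len(nrow(ens$topology)),
                     elety = ens$topology$elety,
                     chain = rep("A", nrow(ens$topology)))
  }
  invisible(paths)
}

# atom indices for a residue-range / atom-name selection
select_atoms <- function(topology, resno_range = NULL, elety = "CA") {
  idx <- seq_len(nrow(topology))
  if (!is.null(elety)) idx <- idx[topology$elety[idx] %in% elety]
  if (!is.null(resno_range)) {
    if (inherits(resno_range, "domain_def"))
      resno_range <- c(resno_range$start, resno_range$end)
    idx <- idx[topology$resno[idx] >= resno_range[1] &
               topology$resno[idx] <= resno_range[2]]
  }
  idx
}

xyz_cols <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

drop_burn_in <- function(mat, burn_in_ns, frame_spacing) {
  drop <- floor(burn_in_ns / frame_spacing)
  if (drop <= 0) return(mat)
  if (nrow(mat) - drop < 2L)
    stop("burn-in leaves fewer than 2 frames", call. = FALSE)
  mat[(drop + 1L):nrow(mat), , drop = FALSE]
}

as_coords <- function(row, cols) matrix(row[cols], ncol = 3, byrow = TRUE)

# Kabsch-fit each frame of `mat[, cols]` onto reference coords; returns
# list(rmsd = per-frame rmsd, fitted = frames x (3*natoms) fitted coords)
fit_frames <- function(mat, cols, ref_xyz, keep_fitted = FALSE) {
  n_fr <- nrow(mat)
  rmsd <- numeric(n_fr)
  fitted <- if (keep_fitted) matrix(NA_real_, n_fr, length(cols)) else NULL
  for (f in seq_len(n_fr)) {
    X <- as_coords(mat[f, ], cols)
    sup <- kabsch_superpose(ref_xyz, X)
    rmsd[f] <- sup$rmsd
    if (keep_fitted) {
      Xf <- sweep(X, 2, colMeans(X)) %*% sup$rotation
      Xf <- sweep(Xf, 2, colMeans(ref_xyz), `+`)
      fitted[f, ] <- as.vector(t(Xf))
    }
  }
  list(rmsd = rmsd, fitted = fitted)
}

#' Per-replica RMSD time series
#'
#' For each replica every frame is Kabsch-superposed onto the reference over
#' the selected atoms and the RMSD recorded. The pooled mean and sample sd
#' are computed over all frames of all replicas.
#'
#' @param ens A `traj_ensemble`.
#' @param resno_range Residue range (length-2 vector or `domain_def`), or
#'   `NULL` for all residues.
#' @param elety Atom-name filter (default `"CA"`).
#' @param ref Reference conformation per replica: the first frame (default)
#'   or the mean structure after a first-frame superposition.
#' @param burn_in_ns Equilibration stretch discarded from the start of every
#'   replica, ns (default 0: no burn-in).
#' @return An `rmsd_series`: `per_replica` (list of per-frame RMSD, Angstrom),
#'   `mean`, `sd` (pooled), `selection`.
#' @export
rmsd_series <- function(ens, resno_range = NULL, elety = "CA",
                        ref = c("first", "mean"), burn_in_ns = 0) {
  ref <- match.arg(ref)
  stopifnot(inherits(ens, "traj_ensemble"))
  atom_idx <- select_atoms(ens$topology, resno_range, elety)
  if (length(atom_idx) < 3L)
    stop("selection has fewer than 3 atoms", call. = FALSE)
  cols <- xyz_cols(atom_idx)
  per <- lapply(ens$replicas, function(mat) {
    mat <- drop_burn_in(mat, burn_in_ns, ens$frame_spacing)
    ref_xyz <- as_coords(mat[1L, ], cols)
    if (ref == "mean") {
      ft <- fit_frames(mat, cols, ref_xyz, keep_fitted = TRUE)
      ref_xyz <- as_coords(colMeans(ft$fitted), seq_len(length(cols)))
    }
    fit_frames(mat, cols, ref_xyz)$rmsd
  })
  pooled <- unlist(per)
  structure(list(per_replica = per, mean = mean(pooled), sd = sd0(pooled),
                 selection = sprintf("%s%s, ref %s",
                                     paste(elety, collapse = "/"),
                                     if (is.null(resno_range)) "" else
                                       sprintf(" residues %d-%d",
                                               min(ens$topology$resno[atom_idx]),
                                               max(ens$topology$resno[atom_idx])),
                                     ref),
                 n_atoms = length(atom_idx),
                 frame_spacing = ens$frame_spacing),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("RMSD series (%s): %.2f +/- %.2f A over %d replica(s), %d atoms\n",
              x$selection, x$mean, x$sd, length(x$per_replica), x$n_atoms))
  invisible(x)
}

#' @export
plot.rmsd_series <- function(x, ...) {
  n <- max(vapply(x$per_replica, length, integer(1)))
  t <- (seq_len(n) - 1) * x$frame_spacing
  graphics::plot(NULL, xlim = range(t), ylim = range(unlist(x$per_replica)),
                 xlab = "time (ns)", ylab = "RMSD (A)", main = x$selection, ...)
  for (i in seq_along(x$per_replica))
    graphics::lines((seq_along(x$per_replica[[i]]) - 1) * x$frame_spacing,
                    x$per_replica[[i]], col = i)
  invisible(x)
}

#' Domain-only overlay RMSD
#'
#' [rmsd_series()] restricted to the C-alpha atoms of one domain's structured
#' range, the overlay that excludes unstructured termini and inter-domain
#' hinge motion.
#'
#' @param ens A `traj_ensemble`.
#' @param domain A `domain_def`.
#' @param ... Passed to [rmsd_series()].
#' @return An `rmsd_series`.
#' @export
domain_overlay_rmsd <- function(ens, domain, ...) {
  stopifnot(inherits(domain, "domain_def"))
  out <- rmsd_series(ens, resno_range = domain, ...)
  out$selection <- paste0(domain$name, ": ", out$selection)
  out
}

#' Replica-averaged RMSF profile
#'
#' Per replica, frames are superposed onto the replica's mean structure
#' (obtained after an initial first-frame superposition); the RMSF of atom i
#' is the square root of its time-averaged squared deviation from its mean
#' position. Profiles are averaged over replicas.
#'
#' @inheritParams rmsd_series
#' @return An `rmsf_profile`: `values` (residue -> RMSF, Angstrom, replica
#'   mean), `per_replica` (matrix residues x replicas), `resno`.
#' @export
rmsf_profile <- function(ens, resno_range = NULL, elety = "CA",
                         burn_in_ns = 0) {
  stopifnot(inherits(ens, "traj_ensemble"))
  atom_idx <- select_atoms(ens$topology, resno_range, elety)
  if (length(atom_idx) < 1L) stop("empty selection", call. = FALSE)
  cols <- xyz_cols(atom_idx)
  per <- vapply(ens$replicas, function(mat) {
    mat <- drop_burn_in(mat, burn_in_ns, ens$frame_spacing)
    ref_xyz <- as_coords(mat[1L, ], cols)
    ft1 <- fit_frames(mat, cols, ref_xyz, keep_fitted = TRUE)
    mean1 <- as_coords(colMeans(ft1$fitted), seq_len(length(cols)))
    ft2 <- fit_frames(mat, cols, mean1, keep_fitted = TRUE)
    mean2 <- colMeans(ft2$fitted)
    dev2 <- sweep(ft2$fitted, 2, mean2)^2
    msf <- colMeans(dev2)
    sqrt(msf[seq(1, length(cols), 3)] + msf[seq(2, length(cols), 3)] +
           msf[seq(3, length(cols), 3)])
  }, numeric(length(atom_idx)))
  per <- matrix(per, nrow = length(atom_idx))
  values <- rowMeans(per)
  resno <- ens$topology$resno[atom_idx]
  names(values) <- resno
  structure(list(values = values, per_replica = per, resno = resno),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("RMSF profile: %d residues, mean %.2f A (range %.2f-%.2f)\n",
              length(x$values), mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.rmsf_profile <- function(x, ...) {
  graphics::plot(x$resno, x$values, type = "l", xlab = "residue",
                 ylab = "RMSF (A)", ...)
  invisible(x)
}

#' RMSF difference between tethered and isolated forms
#'
#' Computes, residue by residue, tethered RMSF minus the RMSF of the isolated
#' form covering that residue's domain, then applies the mean + one sd
#' significance rule (strict inequality) over the domain residues. Residues
#' of the tethered profile outside both domains (linker/termini) are excluded
#' from selection and reported separately.
#'
#' @param tethered,isolated_rrm1,isolated_rrm2 `rmsf_profile` objects.
#' @param domain1,domain2 `domain_def` ranges assigning residues to the
#'   isolated profiles.
#' @return A `delta_rmsf`: `delta` (named by residue), `mean`, `sd`,
#'   `threshold`, `selected`, `excluded` (residues outside both domains).
#' @export
delta_rmsf <- function(tethered, isolated_rrm1, isolated_rrm2,
                       domain1, domain2) {
  stopifnot(inherits(tethered, "rmsf_profile"),
            inherits(isolated_rrm1, "rmsf_profile"),
            inherits(isolated_rrm2, "rmsf_profile"),
            inherits(domain1, "domain_def"), inherits(domain2, "domain_def"))
  res <- tethered$resno
  in1 <- in_domain(res, domain1)
  in2 <- in_domain(res, domain2)
  excluded <- res[!in1 & !in2]
  need1 <- res[in1]; need2 <- res[in2]
  gap1 <- setdiff(need1, isolated_rrm1$resno)
  gap2 <- setdiff(need2, isolated_rrm2$resno)
  if (length(gap1) || length(gap2))
    stop("isolated profiles do not cover domain residue(s): ",
         paste(c(gap1, gap2), collapse = ", "), call. = FALSE)
  d1 <- tethered$values[in1] - isolated_rrm1$values[match(need1, isolated_rrm1$resno)]
  d2 <- tethered$values[in2] - isolated_rrm2$values[match(need2, isolated_rrm2$resno)]
  delta <- c(d1, d2)
  names(delta) <- c(need1, need2)
  delta <- delta[order(as.integer(names(delta)))]
  m <- mean(delta); s <- sd0(delta)
  thr <- m + s
  structure(list(delta = delta, mean = m, sd = s, threshold = thr,
                 selected = as.integer(names(delta)[delta > thr]),
                 excluded = excluded),
            class = "delta_rmsf")
}

#' @export
print.delta_rmsf <- function(x, ...) {
  cat(sprintf("Delta-RMSF (tethered - isolated): mean %.3f, sd %.3f, threshold %.3f A\n",
              x$mean, x$sd, x$threshold))
  cat("Residues above threshold:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "none", "\n")
  if (length(x$excluded))
    cat(sprintf("%d linker/terminal residue(s) outside both domains excluded\n",
                length(x$excluded)))
  invisible(x)
}
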