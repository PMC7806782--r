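#' Define an inclusive residue range for a domain
#'
#' @param name Domain name, e.g. `"RRM1"`.
#' @param start,end First and last residue numbers (inclusive, `start < end`).
#' @return A `domain_def` object.
#' @export
#' @examples
#' domain_def("RRM1", 105, 180)  # TDP-43 RRM1 structured range
domain_def <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (!(start < end)) stop("domain start must be < end", call. = FALSE)
  structure(list(name = name, start = start, end = end), class = "domain_def")
}

#' @export
print.domain_def <- function(x, ...) {
  cat(sprintf("Domain %s: residues %d-%d\n", x$name, x$start, x$end))
  invisible(x)
}

in_domain <- function(resno, domain) resno >= domain$start & resno <= domain$end

#' Read the C-alpha trace of one model of a PDB file
#'
#' @param path PDB file (ATOM/MODEL records).
#' @param model_index Which model of an NMR ensemble to use (default 1).
#' @param chain_id Chain to read; default is the first chain in the file.
#' @return A `structure_model`: data frame `resno`, `resid`, `x`, `y`, `z`
#'   (Angstrom), ordered by residue number, first alternate location kept;
#'   attributes `model_index`, `chain_id`.
#' @export
read_structure <- function(path, model_index = 1L, chain_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models)
    stop(sprintf("model %d requested but file has %d model(s)", model_index,
                 n_models), call. = FALSE)
  atoms <- pdb$atom
  if (is.null(chain_id)) chain_id <- atoms$chain[1]
  sel <- which(atoms$elety == "CA" & atoms$chain %in% chain_id &
               (is.na(atoms$alt) | atoms$alt %in% c("", "A")))
  if (length(sel) == 0L)
    stop("no C-alpha atoms for chain ", chain_id, " in ", path, call. = FALSE)
  sel <- sel[!duplicated(atoms$resno[sel])]  # first altloc per residue
  xyz <- matrix(pdb$xyz[model_index, bio3d::atom2xyz(sel)], ncol = 3, byrow = TRUE)
  ord <- order(atoms$resno[sel])
  out <- data.frame(resno = atoms$resno[sel][ord], resid = atoms$resid[sel][ord],
                    x = xyz[ord, 1], y = xyz[ord, 2], z = xyz[ord, 3])
  if (!all(is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path, call. = FALSE)
  structure(out, model_index = model_index, chain_id = chain_id,
            class = c("structure_model", "data.frame"))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("C-alpha trace: %d residues (%d-%d), chain %s, model %d\n",
              nrow(x), min(x$resno), max(x$resno), attr(x, "chain_id"),
              attr(x, "model_index")))
  invisible(x)
}

#' Paired C-alpha coordinates over the shared residues of a domain
#'
#' Intersects the residue numbers of two structures inside a domain range
#' (after adding `offset_b` to the second structure's numbering) and returns
#' matched coordinate matrices. No sequence alignment is attempted.
#'
#' @param a,b `structure_model` objects.
#' @param domain A `domain_def`.
#' @param offset_b Fixed offset added to `b`'s residue numbers to reconcile
#'   construct numbering (default 0).
#' @return List with `xyz_a`, `xyz_b` (n x 3 matrices) and `resno`.
#' @export
common_range <- function(a, b, domain, offset_b = 0L) {
  stopifnot(inherits(domain, "domain_def"))
  resno_b <- b$resno + offset_b
  shared <- intersect(a$resno[in_domain(a$resno, domain)],
                      resno_b[in_domain(resno_b, domain)])
  if (length(shared) < 3L)
    stop(sprintf("only %d shared residue(s) in %s range %d-%d; need >= 3",
                 length(shared), domain$name, domain$start, domain$end),
         call. = FALSE)
  shared <- sort(shared)
  ia <- match(shared, a$resno)
  ib <- match(shared, resno_b)
  list(xyz_a = as.matrix(a[ia, c("x", "y", "z")]),
       xyz_b = as.matrix(b[ib, c("x", "y", "z")]),
       resno = shared)
}

#' Optimal least-squares superposition (Kabsch)
#'
#' Removes the centroids, finds the proper rotation minimising the summed
#' squared distances (reflections corrected via the SVD determinant), and
#' reports the RMSD of the superposed pair. The returned rotation applied to
#' the centered `coords_b` attains exactly the reported RMSD.
#'
#' @param coords_a,coords_b Matched n x 3 coordinate matrices (n >= 2).
#' @return A `superposition`: `rmsd` (Angstrom), `n_atoms`, `rotation`
#'   (3 x 3, det +1; maps centered b onto centered a as `Bc %*% rotation`),
#'   `translation` (so that `coords_b %*% rotation + translation` superposes
#'   onto `coords_a`).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L)
    stop("coords must be matched n x 3 matrices", call. = FALSE)
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 coordinate pairs", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (min(svd(Ac)$d[2], svd(Bc)$d[2]) < 1e-8)
    warning("degenerate (collinear or coincident) coordinates; ",
            "rotation is not unique though the RMSD is well defined")
  H <- crossprod(Bc, Ac)        # minimise ||Bc %*% R - Ac||
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  resid <- Bc %*% R - Ac
  structure(list(rmsd = sqrt(mean(rowSums(resid^2))),
                 n_atoms = n,
                 rotation = R,
                 translation = as.numeric(ca - cb %*% R)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: RMSD = %.3f A\n", x$n_atoms, x$rmsd))
  if (!is.null(x$selection)) cat("Selection:", x$selection, "\n")
  invisible(x)
}

#' Tethered-vs-isolated domain RMSD
#'
#' Superposes the C-alpha traces of two structures over the structured range
#' of one domain (shared residues only) and reports the RMSD, the comparison
#' used to show that a domain keeps its fold in tethered and isolated forms.
#'
#' @inheritParams common_range
#' @param tethered,isolated `structure_model` objects to compare.
#' @return A `superposition` with an added `selection` description.
#' @export
domain_rmsd_report <- function(tethered, isolated, domain, offset_b = 0L) {
  pr <- common_range(tethered, isolated, domain, offset_b = offset_b)
  sup <- kabsch_superpose(pr$xyz_a, pr$xyz_b)
  sup$selection <- sprintf("CA, %s %d-%d (%d shared residues)", domain$name,
                           domain$start, domain$end, length(pr$resno))
  sup$resno <- pr$resno
  sup
}
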