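#' Read an assigned HSQC peak list
#'
#' Parses a Sparky-style whitespace table of assigned amide peaks. Each data
#' row is `Assignment w1 w2`, with the assignment token carrying a one-letter
#' residue code and construct residue number (e.g. `G142N-H`). In the default
#' `sparky` dialect `w1` is the nitrogen shift and `w2` the proton shift; set
#' `w1 = "1H"` for files written the other way around. A single header line
#' (e.g. `Assignment w1 w2`) is tolerated and skipped.
#'
#' @param path Path to the peak-list file.
#' @param dialect Peak-list dialect; only `"sparky"` is implemented.
#' @param w1 Which nucleus the first shift column holds: `"15N"` (default)
#'   or `"1H"`.
#' @param validate When `TRUE` (default) shifts are required to fall in the
#'   amide windows 5--13 ppm (1H) and 100--140 ppm (15N).
#' @param label Optional condition label; defaults to the file name.
#' @return A `peak_list`: a data frame with columns `residue`, `resname`,
#'   `w_H`, `w_N` (ppm) and attributes `label`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".list")
#' writeLines(c("Assignment w1 w2", "G142N-H 107.230 8.410"), f)
#' read_peaklist(f)
read_peaklist <- function(path, dialect = "sparky", w1 = c("15N", "1H"),
                          validate = TRUE, label = NULL) {
  dialect <- match.arg(dialect, "sparky")
  w1 <- match.arg(w1)
  if (!file.exists(path)) stop("peak list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(peak_list(data.frame(residue = integer(), resname = character(),
                                w_H = numeric(), w_N = numeric()),
                     label = label %||% basename(path), validate = validate))
  }
  res <- vector("list", length(keep))
  first <- TRUE
  for (k in seq_along(keep)) {
    i <- keep[k]
    fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    m <- regmatches(fields[1], regexec("^([A-Za-z])([0-9]+)N-H[N]?$", fields[1]))[[1]]
    if (length(m) == 0L) {
      # tolerate exactly one header line at the top of the file
      if (first && k == 1L) { first <- FALSE; next }
      stop(sprintf("malformed assignment token '%s' at line %d of %s",
                   fields[1], i, path), call. = FALSE)
    }
    first <- FALSE
    if (length(fields) < 3L || anyNA(suppressWarnings(as.numeric(fields[2:3]))))
      stop(sprintf("expected two numeric shift columns at line %d of %s", i, path),
           call. = FALSE)
    v <- as.numeric(fields[2:3])
    res[[k]] <- data.frame(residue = as.integer(m[3]),
                           resname = toupper(m[2]),
                           w_H = if (w1 == "15N") v[2] else v[1],
                           w_N = if (w1 == "15N") v[1] else v[2])
  }
  peaks <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(peaks))
    peaks <- data.frame(residue = integer(), resname = character(),
                        w_H = numeric(), w_N = numeric())
  peak_list(peaks, label = label %||% basename(path), validate = validate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a validated peak list
#'
#' @param peaks Data frame with columns `residue`, `resname`, `w_H`, `w_N`.
#' @param label Condition label.
#' @param validate Check chemical-shift windows (1H 5--13, 15N 100--140 ppm).
#' @return A `peak_list` object.
#' @export
peak_list <- function(peaks, label = "", validate = TRUE) {
  need <- c("residue", "resname", "w_H", "w_N")
  if (!all(need %in% names(peaks)))
    stop("peaks must have columns ", paste(need, collapse = ", "), call. = FALSE)
  peaks <- peaks[, need, drop = FALSE]
  if (nrow(peaks) > 0) {
    if (any(peaks$residue < 1L))
      stop("residue numbers must be >= 1", call. = FALSE)
    dup <- peaks$residue[duplicated(peaks$residue)]
    if (length(dup))
      stop("duplicate residue number(s) in peak list: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    if (validate) {
      bad_h <- peaks$w_H < 5 | peaks$w_H > 13
      bad_n <- peaks$w_N < 100 | peaks$w_N > 140
      if (any(bad_h | bad_n))
        stop("chemical shifts outside amide windows for residue(s): ",
             paste(peaks$residue[bad_h | bad_n], collapse = ", "), call. = FALSE)
    }
  }
  rownames(peaks) <- NULL
  structure(peaks, label = label, class = c("peak_list", "data.frame"))
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("Assigned peak list '%s': %d peaks\n", attr(x, "label"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Write a peak list in the Sparky dialect
#'
#' Shifts are written to three decimals, `w1` = 15N, `w2` = 1H, with a
#' one-line header, so that [read_peaklist()] round-trips the file.
#'
#' @param pl A `peak_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path) {
  stopifnot(inherits(pl, "peak_list"))
  lines <- c("Assignment w1 w2",
             sprintf("%s%dN-H %10.3f %8.3f", pl$resname, pl$residue, pl$w_N, pl$w_H))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble peak lists into a ligand titration series
#'
#' Residues present in the 0 mM reference list but absent at a higher ligand
#' concentration are recorded as "disappeared" at that point; they are never
#' silently dropped from the series.
#'
#' @param peaklists List of `peak_list` objects, one per ligand concentration,
#'   in the same order as `ligand_concs` (first entry is the reference).
#' @param ligand_concs Ligand concentrations in mM, strictly increasing and
#'   starting at 0.
#' @param protein_conc Protein concentration in mM (e.g. 0.05 for 50 uM).
#' @return A `titration_series` with elements `protein_conc`, `ligand_concs`,
#'   `peaklists` and `disappeared` (per concentration, residues present in the
#'   reference but missing there).
#' @export
assemble_titration <- function(peaklists, ligand_concs, protein_conc) {
  stop_if_not_scalar_pos(protein_conc, "protein_conc")
  if (!all(vapply(peaklists, inherits, logical(1), "peak_list")))
    stop("all elements of `peaklists` must be peak_list objects", call. = FALSE)
  if (length(peaklists) != length(ligand_concs))
    stop("number of peak lists (", length(peaklists),
         ") does not match number of ligand concentrations (",
         length(ligand_concs), ")", call. = FALSE)
  if (length(ligand_concs) < 2L)
    stop("a titration needs the reference plus at least one ligand point",
         call. = FALSE)
  if (ligand_concs[1] != 0)
    stop("the first ligand concentration must be 0 (reference)", call. = FALSE)
  if (any(diff(ligand_concs) <= 0))
    stop("ligand concentrations must be strictly increasing", call. = FALSE)
  ref_res <- peaklists[[1]]$residue
  disappeared <- lapply(peaklists, function(pl) sort(setdiff(ref_res, pl$residue)))
  structure(list(protein_conc = protein_conc,
                 ligand_concs = as.numeric(ligand_concs),
                 peaklists = peaklists,
                 disappeared = disappeared),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series: [P] = %g mM, %d ligand points (%g-%g mM)\n",
              x$protein_conc, length(x$ligand_concs) - 1L,
              min(x$ligand_concs[-1]), max(x$ligand_concs)))
  cat(sprintf("Reference peaks: %d; residues disappearing at any point: %d\n",
              nrow(x$peaklists[[1]]),
              length(unique(unlist(x$disappeared)))))
  invisible(x)
}

#' Write a results table as CSV
#'
#' Thin deterministic wrapper around [utils::write.csv()]: header included,
#' no row names, columns in the order supplied.
#'
#' @param records Non-empty data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data frame", call. = FALSE)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
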