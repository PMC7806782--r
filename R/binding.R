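#' One-site ligand-depletion binding isotherm
#'
#' Predicted CSD at protein concentration `[P]` and total ligand `[L]` for a
#' single binding site, accounting for ligand depletion via the quadratic
#' solution for the complex concentration:
#'
#' CSDobs = CSDmax * ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P)
#'
#' In the weak-depletion regime (`[P] << Kd`) this reduces to the hyperbolic
#' isotherm CSDmax * L / (L + Kd).
#'
#' @param kd Dissociation constant, mM.
#' @param csd_max Saturating CSD, ppm.
#' @param protein_conc Protein concentration `[P]`, mM.
#' @param ligand_conc Total ligand concentration(s) `[L]`, mM; vectorised.
#' @return Predicted CSD(s), ppm, in `[0, csd_max]`.
#' @export
#' @examples
#' csd_model(kd = 16.7, csd_max = 1, protein_conc = 0.05, ligand_conc = 10)
csd_model <- function(kd, csd_max, protein_conc, ligand_conc) {
  stop_if_not_scalar_pos(protein_conc, "protein_conc")
  if (any(ligand_conc < 0)) stop("ligand_conc must be >= 0", call. = FALSE)
  s <- protein_conc + ligand_conc + kd
  disc <- pmax(s^2 - 4 * protein_conc * ligand_conc, 0)
  csd_max * (s - sqrt(disc)) / (2 * protein_conc)
}

#' Fit a residue-specific dissociation constant
#'
#' Nonlinear least squares of [csd_model()] to one residue's CSD trace over a
#' ligand titration, with `Kd` and `CSDmax` free and bounded positive
#' (Levenberg-Marquardt). Initialisation: `Kd0` = median nonzero ligand
#' concentration, `CSDmax0` = 1.5 x the largest observed CSD, with a
#' multi-start over `{0.1, 1, 10} x Kd0`; if no start converges the result is
#' flagged as failed rather than defaulted.
#'
#' @param trace Data frame (or 2-column matrix) with columns `ligand_conc`
#'   (mM) and `csd` (ppm). `NA` rows (e.g. disappeared peaks) are dropped.
#' @param protein_conc Protein concentration, mM.
#' @param residue Optional residue number carried into the result.
#' @return An object of class `kdfit` with components `coefficients`
#'   (`kd`, `csd_max`), `se`, `rss`, `converged`, `data`, `protein_conc`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`, `simulate`.
#' @export
fit_kd_residue <- function(trace, protein_conc, residue = NA_integer_) {
  trace <- as.data.frame(trace)
  if (!all(c("ligand_conc", "csd") %in% names(trace)))
    names(trace)[1:2] <- c("ligand_conc", "csd")
  trace <- trace[is.finite(trace$ligand_conc) & is.finite(trace$csd), , drop = FALSE]
  lpos <- trace$ligand_conc[trace$ligand_conc > 0]
  if (nrow(trace) < 4L)
    stop("need at least 4 finite titration points to fit Kd", call. = FALSE)
  if (length(lpos) == 0L || max(lpos) / min(lpos) < 4)
    stop("titration must span at least a 4-fold ligand concentration range",
         call. = FALSE)
  stop_if_not_scalar_pos(protein_conc, "protein_conc")

  out <- structure(list(coefficients = c(kd = NA_real_, csd_max = NA_real_),
                        se = c(kd = NA_real_, csd_max = NA_real_),
                        rss = NA_real_, converged = FALSE, reason = "",
                        data = trace, protein_conc = protein_conc,
                        residue = residue, n = nrow(trace)),
                   class = "kdfit")

  cmax0 <- 1.5 * max(trace$csd)
  if (!(cmax0 > 0) || stats::sd(trace$csd) == 0) {
    out$reason <- "flat trace: Kd unidentifiable"
    return(out)
  }
  kd0 <- stats::median(lpos)
  best <- NULL
  for (s in kd0 * c(0.1, 1, 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        csd ~ csd_model(kd, cmax, protein_conc, ligand_conc),
        data = trace,
        start = list(kd = s, cmax = cmax0),
        lower = c(kd = 1e-9, cmax = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    out$reason <- "no start converged"
    return(out)
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(NA_real_, NA_real_))
  out$coefficients <- c(kd = unname(cf["kd"]), csd_max = unname(cf["cmax"]))
  out$se <- c(kd = unname(se[1]), csd_max = unname(se[2]))
  out$rss <- best$rss
  out$converged <- TRUE
  out$fit <- best$fit
  out
}

#' @export
print.kdfit <- function(x, digits = 4, ...) {
  if (x$converged) {
    cat(sprintf("One-site ligand-depletion fit%s: Kd = %.*g +/- %.*g mM, CSDmax = %.*g ppm\n",
                if (is.na(x$residue)) "" else sprintf(" (residue %d)", x$residue),
                digits, x$coefficients["kd"], digits, x$se["kd"],
                digits, x$coefficients["csd_max"]))
    cat(sprintf("  n = %d points, [P] = %g mM, RSS = %.3g\n",
                x$n, x$protein_conc, x$rss))
  } else {
    cat("One-site fit failed:", x$reason, "\n")
  }
  invisible(x)
}

#' @export
coef.kdfit <- function(object, ...) object$coefficients

#' @export
summary.kdfit <- function(object, ...) {
  structure(list(coefficients = cbind(Estimate = object$coefficients,
                                      `Std. Error` = object$se),
                 rss = object$rss, n = object$n, converged = object$converged,
                 sigma = if (object$converged)
                   sqrt(object$rss / max(object$n - 2L, 1L)) else NA_real_,
                 residue = object$residue),
            class = "summary.kdfit")
}

#' @export
print.summary.kdfit <- function(x, ...) {
  cat("One-site ligand-depletion binding fit\n")
  if (!is.na(x$residue)) cat("Residue:", x$residue, "\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Residual sum of squares: %.4g on %d points (sigma %.4g ppm)\n",
              x$rss, x$n, x$sigma))
  invisible(x)
}

#' @export
predict.kdfit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed fit", call. = FALSE)
  L <- if (is.null(newdata)) object$data$ligand_conc else newdata$ligand_conc
  csd_model(object$coefficients["kd"], object$coefficients["csd_max"],
            object$protein_conc, L)
}

#' @export
fitted.kdfit <- function(object, ...) predict.kdfit(object)

#' @export
residuals.kdfit <- function(object, ...) object$data$csd - fitted(object)

#' @export
simulate.kdfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sigma <- sqrt(object$rss / max(object$n - 2L, 1L))
  as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma)))
}

#' @export
plot.kdfit <- function(x, ...) {
  graphics::plot(x$data$ligand_conc, x$data$csd, xlab = "[L] (mM)",
                 ylab = "CSD (ppm)",
                 main = if (is.na(x$residue)) "Kd fit"
                        else sprintf("Residue %d", x$residue), ...)
  if (x$converged) {
    L <- seq(0, max(x$data$ligand_conc), length.out = 200)
    graphics::lines(L, csd_model(x$coefficients["kd"], x$coefficients["csd_max"],
                                 x$protein_conc, L))
  }
  invisible(x)
}

#' Fit dissociation constants across the residues of a titration
#'
#' Builds per-residue shift traces from the series (disappeared peaks are
#' excluded, never imputed) and fits them with [fit_kd_residue()].
#' `per_residue_mean` mode fits each residue independently and aggregates the
#' converged Kd values as mean +/- sample sd; `global_shared_kd` fits one
#' shared Kd with residue-specific CSDmax values, the aggregate sd then being
#' the standard error of the shared Kd.
#'
#' @param series A `titration_series`.
#' @param residues Residue numbers to fit (e.g. the significantly shifted
#'   set). Must be present in the reference list.
#' @param mode `"per_residue_mean"` (default) or `"global_shared_kd"`.
#' @return A `kdfit_profile`: data frame `per_residue` (residue, kd, kd_se,
#'   csd_max, csd_max_se, rss, converged), `aggregate_kd`, `aggregate_kd_sd`,
#'   `mode`, `n_converged`, and the individual `fits`.
#' @export
fit_kd_profile <- function(series, residues,
                           mode = c("per_residue_mean", "global_shared_kd")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "titration_series"))
  residues <- as.integer(residues)
  if (length(residues) == 0L) stop("empty residue set", call. = FALSE)
  ref <- series$peaklists[[1]]
  missing <- setdiff(residues, ref$residue)
  if (length(missing))
    stop("residue(s) not in the reference list: ",
         paste(missing, collapse = ", "), call. = FALSE)

  concs <- series$ligand_concs
  traces <- lapply(residues, function(r) {
    csd <- vapply(seq_along(concs), function(k) {
      pl <- series$peaklists[[k]]
      j <- match(r, pl$residue)
      if (is.na(j)) return(NA_real_)  # disappeared at this point
      i <- match(r, ref$residue)
      csd_index(pl$w_H[j] - ref$w_H[i], pl$w_N[j] - ref$w_N[i])
    }, numeric(1))
    data.frame(ligand_conc = concs, csd = csd)[concs > 0, , drop = FALSE]
  })
  names(traces) <- residues

  fits <- Map(function(tr, r) {
    tryCatch(fit_kd_residue(tr, series$protein_conc, residue = r),
             error = function(e) {
               structure(list(coefficients = c(kd = NA_real_, csd_max = NA_real_),
                              se = c(kd = NA_real_, csd_max = NA_real_),
                              rss = NA_real_, converged = FALSE,
                              reason = conditionMessage(e), data = tr,
                              protein_conc = series$protein_conc,
                              residue = r, n = nrow(tr)),
                         class = "kdfit")
             })
  }, traces, residues)

  per <- data.frame(
    residue = residues,
    kd = vapply(fits, function(f) unname(f$coefficients["kd"]), numeric(1)),
    kd_se = vapply(fits, function(f) unname(f$se["kd"]), numeric(1)),
    csd_max = vapply(fits, function(f) unname(f$coefficients["csd_max"]), numeric(1)),
    csd_max_se = vapply(fits, function(f) unname(f$se["csd_max"]), numeric(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)))

  ok <- per$converged
  if (!any(ok)) stop("all per-residue fits failed", call. = FALSE)

  if (mode == "per_residue_mean") {
    agg <- mean(per$kd[ok])
    agg_sd <- sd0(per$kd[ok])
    global_fit <- NULL
  } else {
    stacked <- do.call(rbind, Map(function(tr, r) {
      tr$res <- factor(r, levels = residues[ok])
      tr
    }, traces[ok], residues[ok]))
    stacked <- stacked[is.finite(stacked$csd), , drop = FALSE]
    cmax0 <- vapply(split(stacked$csd, stacked$res), function(v) 1.5 * max(v),
                    numeric(1))
    P <- series$protein_conc
    global_fit <- stats::nls(
      csd ~ csd_model(kd, cmax[res], P, ligand_conc),
      data = stacked,
      start = list(kd = stats::median(stacked$ligand_conc), cmax = cmax0),
      algorithm = "port", lower = rep(1e-9, 1L + length(cmax0)),
      control = stats::nls.control(maxiter = 200, warnOnly = FALSE))
    agg <- unname(stats::coef(global_fit)["kd"])
    agg_sd <- unname(summary(global_fit)$coefficients["kd", "Std. Error"])
  }

  structure(list(per_residue = per, aggregate_kd = agg, aggregate_kd_sd = agg_sd,
                 mode = mode, n_converged = sum(ok), fits = fits,
                 global_fit = global_fit,
                 single_residue = sum(ok) == 1L && mode == "per_residue_mean"),
            class = "kdfit_profile")
}

#' @export
print.kdfit_profile <- function(x, ...) {
  cat(sprintf("Kd fits over %d residues (%d converged), mode '%s'\n",
              nrow(x$per_residue), x$n_converged, x$mode))
  cat(sprintf("Aggregate Kd = %.3g +/- %.3g mM%s\n", x$aggregate_kd,
              x$aggregate_kd_sd,
              if (isTRUE(x$single_residue)) " (single residue; sd not defined)" else ""))
  invisible(x)
}

#' @export
coef.kdfit_profile <- function(object, ...) {
  c(kd = object$aggregate_kd)
}

#' @export
summary.kdfit_profile <- function(object, ...) {
  object$per_residue
}
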