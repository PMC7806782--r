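#' Construct a thermal denaturation curve
#'
#' @param temperature Strictly increasing temperatures, degrees C (>= 10
#'   points).
#' @param signal Fluorescence signal, arbitrary units.
#' @param label Curve label.
#' @return A `melt_curve` data frame.
#' @export
melt_curve <- function(temperature, signal, label = "") {
  if (length(temperature) != length(signal))
    stop("temperature and signal lengths differ", call. = FALSE)
  if (length(temperature) < 10L)
    stop("a melt curve needs at least 10 points", call. = FALSE)
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  structure(data.frame(temperature = temperature, signal = signal),
            label = label, class = c("melt_curve", "data.frame"))
}

#' First derivative dF/dT of a melt curve
#'
#' Moving-average smoothing followed by a centered finite difference;
#' endpoints use one-sided differences. This is the standard readout for
#' differential scanning fluorimetry, where a transition appears as a
#' derivative peak at its midpoint.
#'
#' @param curve A `melt_curve`.
#' @param smoothing_window Odd window length, shorter than the curve;
#'   1 disables smoothing.
#' @return Numeric vector of dF/dT values at the curve's temperatures.
#' @export
melt_derivative <- function(curve, smoothing_window = 3L) {
  stopifnot(inherits(curve, "melt_curve"))
  w <- as.integer(smoothing_window)
  n <- nrow(curve)
  if (w %% 2L == 0L) stop("smoothing_window must be odd", call. = FALSE)
  if (w >= n) stop("smoothing_window must be shorter than the curve",
                   call. = FALSE)
  s <- curve$signal
  if (w > 1L) {
    half <- (w - 1L) %/% 2L
    sm <- as.numeric(stats::filter(s, rep(1 / w, w), sides = 2))
    # shrink the window at the edges instead of dropping points
    for (i in which(is.na(sm))) {
      k <- min(i - 1L, n - i, half)
      sm[i] <- mean(s[(i - k):(i + k)])
    }
    s <- sm
  }
  t <- curve$temperature
  d <- numeric(n)
  d[1] <- (s[2] - s[1]) / (t[2] - t[1])
  d[n] <- (s[n] - s[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  d[i] <- (s[i + 1] - s[i - 1]) / (t[i + 1] - t[i - 1])
  d
}

# prominence of local maxima of y: height above the higher of the two
# valley floors separating the peak from higher terrain
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p - 1L)]
    right <- y[seq(p + 1L, length(y), length.out = max(length(y) - p, 0L))]
    higher_l <- which(left > y[p])
    lmin <- if (length(higher_l)) min(left[(max(higher_l) + 1L):(p - 1L)])
            else if (length(left)) min(left) else y[p]
    higher_r <- which(right > y[p])
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)])
            else if (length(right)) min(right) else y[p]
    y[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Extract melting temperatures from a melt curve
#'
#' Tm values are the temperatures of the dF/dT peaks with prominence at least
#' `min_prominence` times the maximum derivative, refined by parabolic
#' interpolation through each peak and its neighbours. A curve with no
#' qualifying peak yields zero transitions (not an error).
#'
#' @param curve A `melt_curve`.
#' @param min_prominence Minimum peak prominence as a fraction of the maximum
#'   derivative (default 0.2, which rejects baseline ripple at 1 degree
#'   sampling).
#' @param smoothing_window Passed to [melt_derivative()].
#' @return A `melt_result`: `tm_values` (degrees C, ascending),
#'   `n_transitions`, `derivative`, `temperature`.
#' @export
find_tm <- function(curve, min_prominence = 0.2, smoothing_window = 3L) {
  stopifnot(inherits(curve, "melt_curve"))
  d <- melt_derivative(curve, smoothing_window)
  t <- curve$temperature
  n <- length(d)
  res <- structure(list(tm_values = numeric(0), n_transitions = 0L,
                        derivative = d, temperature = t,
                        label = attr(curve, "label")),
                   class = "melt_result")
  if (max(d) <= 0) return(res)
  cand <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  cand <- cand[d[cand] > 0]
  if (length(cand) == 0L) return(res)
  prom <- peak_prominence(d, cand)
  keep <- cand[prom >= min_prominence * max(d)]
  if (length(keep) == 0L) return(res)
  tm <- vapply(keep, function(p) {
    y0 <- d[p - 1L]; y1 <- d[p]; y2 <- d[p + 1L]
    denom <- y0 - 2 * y1 + y2
    if (abs(denom) < 1e-12) return(t[p])
    # parabola through three points on a uniform local grid
    dt2 <- (t[p + 1L] - t[p - 1L]) / 2
    t[p] + 0.5 * (y0 - y2) / denom * dt2
  }, numeric(1))
  res$tm_values <- sort(tm)
  res$n_transitions <- length(tm)
  res
}

#' @export
print.melt_result <- function(x, ...) {
  if (x$n_transitions == 0L) {
    cat("No thermal unfolding transition detected\n")
  } else {
    cat(sprintf("%d thermal unfolding transition(s): Tm = %s degC\n",
                x$n_transitions,
                paste(sprintf("%.1f", x$tm_values), collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.melt_result <- function(x, ...) {
  graphics::plot(x$temperature, x$derivative, type = "l",
                 xlab = "temperature (degC)", ylab = "dF/dT", ...)
  graphics::abline(v = x$tm_values, lty = 2)
  invisible(x)
}
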