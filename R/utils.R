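# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG state, then restore the caller's state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sample standard deviation that tolerates length-1 input (returns 0)
#' @noRd
sd0 <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}

#' Wrap angles in degrees into (-180, 180]
#' @noRd
wrap180 <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y[y <= -180] <- y[y <= -180] + 360
  y
}

# Row-wise cross product for n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(a) sqrt(rowSums(a * a))
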