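# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a structured package error
#'
#' All anticipated failure modes raise conditions inheriting from
#' `"cmq_error"` plus a specific subclass so callers can handle them
#' programmatically (e.g. `cmq_no_reversal`, `cmq_fit_failure`).
#' @keywords internal
#' @noRd
cmq_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "cmq_error", "error", "condition")))
}

assert_num <- function(x, name, positive = FALSE, finite = TRUE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || (finite && any(!is.finite(x))))
    cmq_stop(sprintf("`%s` must be a finite numeric of length %d", name, len),
             "cmq_invalid_argument")
  if (positive && any(x <= 0))
    cmq_stop(sprintf("`%s` must be > 0", name), "cmq_invalid_argument")
  invisible(x)
}

#' First linear-interpolated crossing of a level
#'
#' @param t,y coordinates (uniform or not); `y` may cross `level` several
#'   times; the first crossing at `t >= after` wins (tie-break rule).
#' @param rising TRUE for upward crossings, FALSE for downward.
#' @return time of crossing, or `NA_real_` if none.
#' @keywords internal
#' @noRd
cross_time <- function(t, y, level, rising = TRUE, after = -Inf) {
  n <- length(y)
  if (n < 2L) return(NA_real_)
  y0 <- y[-n]; y1 <- y[-1L]
  idx <- if (rising) which(y0 < level & y1 >= level & t[-n] >= after)
         else        which(y0 > level & y1 <= level & t[-n] >= after)
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  if (y[i + 1L] == y[i]) return(t[i])
  t[i] + (level - y[i]) / (y[i + 1L] - y[i]) * (t[i + 1L] - t[i])
}

# centered moving average with edge replication (k odd)
moving_average <- function(y, k = 3L) {
  if (k <= 1L) return(y)
  half <- (k - 1L) %/% 2L
  yp <- c(rep(y[1L], half), y, rep(y[length(y)], half))
  as.numeric(stats::filter(yp, rep(1 / k, k), sides = 2L))[(half + 1L):(half + length(y))]
}

# Savitzky-Golay quadratic smoothing, 5-point window
sg5_smooth <- function(y) {
  if (length(y) < 5L) return(y)
  co <- c(-3, 12, 17, 12, -3) / 35
  yp <- c(y[1L], y[1L], y, y[length(y)], y[length(y)])
  as.numeric(stats::filter(yp, co, sides = 2L))[3:(length(y) + 2L)]
}

# Savitzky-Golay quadratic first derivative, 5-point window.
# stats::filter(sides = 2) is a convolution (coefficients applied in
# reverse sample order), so the antisymmetric slope kernel is written
# reversed here to yield the least-squares slope sum_j j*y[i+j]/10.
sg5_deriv <- function(y, dt) {
  n <- length(y)
  if (n < 5L) return(c(diff(y) / dt, NA_real_)[seq_len(n)])
  co <- c(2, 1, 0, -1, -2) / 10
  yp <- c(y[1L], y[1L], y, y[n], y[n])
  as.numeric(stats::filter(yp, co, sides = 2L))[3:(n + 2L)] / dt
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

#' Derive a per-cell seed from a master seed
#'
#' Splitting rule: `master + index` (documented contract, so cohorts are
#' reproducible cell-by-cell). Kept below 2^31.
#' @keywords internal
#' @noRd
derive_seed <- function(master, index) {
  s <- as.integer(master) + as.integer(index)
  if (s >= .Machine$integer.max) s <- s %% .Machine$integer.max
  s
}

is_uniform <- function(t, rel_tol = 1e-6) {
  if (length(t) < 3L) return(TRUE)
  d <- diff(t)
  max(abs(d - d[1L])) <= rel_tol * abs(d[1L])
}
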