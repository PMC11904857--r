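# Voltage-clamp sodium current analysis: peaks, I-V, conductance transform,
# Boltzmann fits of steady-state activation and inactivation.

window_idx <- function(time, window) which(time >= window[1L] & time < window[2L])

baseline_correct <- function(family, baseline_ms = 5) {
  t0 <- family$step_window[1L]
  pre <- which(family$time >= max(0, family$baseline_window[1L],
                                  family$baseline_window[2L] - baseline_ms) &
               family$time < family$baseline_window[2L])
  if (!length(pre)) return(family$sweeps)
  sweep_means <- colMeans(family$sweeps[pre, , drop = FALSE])
  sweep(family$sweeps, 2L, sweep_means, "-")
}

#' Extract peak currents and current densities (I-V curve)
#'
#' Per sweep: subtracts the mean of the 5 ms pre-step baseline window,
#' then returns the signed extremum of largest magnitude within the step
#' window. Densities are peaks divided by cell capacitance.
#'
#' @param family a `sweep_family` (from [simulate_vclamp_family()] or
#'   [read_trace_csv()]).
#' @return an `iv_curve`: step voltages (mV), signed peak currents (pA)
#'   and densities (pA/pF).
#' @export
peak_currents <- function(family) {
  stopifnot(inherits(family, "sweep_family"))
  idx <- window_idx(family$time, family$step_window)
  if (!length(idx)) cmq_stop("empty step window", "cmq_invalid_argument")
  sw <- baseline_correct(family)[idx, , drop = FALSE]
  peak <- apply(sw, 2L, function(y) y[which.max(abs(y))])
  structure(list(voltages = family$step_voltages, peak_current = peak,
                 density = peak / family$capacitance,
                 capacitance = family$capacitance),
            class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("<iv_curve> %d points, peak density %.1f pA/pF at %g mV\n",
              length(x$voltages), x$density[which.max(abs(x$density))],
              x$voltages[which.max(abs(x$density))]))
  invisible(x)
}

#' Estimate the reversal potential from the I-V curve
#'
#' Linear interpolation of the zero crossing on the positive-voltage limb
#' (voltages above the peak-current voltage, where the current changes
#' sign from inward to outward).
#'
#' @param iv an `iv_curve`.
#' @return reversal potential estimate, mV.
#' @export
estimate_reversal <- function(iv) {
  stopifnot(inherits(iv, "iv_curve"))
  v <- iv$voltages; i <- iv$peak_current
  start <- which.max(abs(i))                       # peak of the inward limb
  for (j in seq(start, length(v) - 1L)) {
    if (i[j] < 0 && i[j + 1L] >= 0) {
      if (i[j + 1L] == i[j]) return(v[j])
      return(v[j] + (0 - i[j]) / (i[j + 1L] - i[j]) * (v[j + 1L] - v[j]))
    }
  }
  cmq_stop("I-V curve does not cross zero on its positive-voltage limb; supply v_rev explicitly",
           "cmq_no_reversal")
}

#' Conductance transform of an I-V curve
#'
#' `G = I / (V - v_rev)`, excluding voltages within `exclusion` mV of the
#' reversal potential (where the division is ill-conditioned). Normalized
#' conductance is `G / max(G)`.
#'
#' @param iv an `iv_curve`.
#' @param v_rev reversal potential, mV.
#' @param exclusion half-width of the excluded voltage band around
#'   `v_rev`, mV (default half the standard 5 mV increment).
#' @return a `gv_curve`: retained voltages, conductance (nS), normalized
#'   conductance, excluded voltages and a `degenerate` flag (all-zero G).
#' @export
conductance_curve <- function(iv, v_rev, exclusion = 2.5) {
  stopifnot(inherits(iv, "iv_curve"))
  assert_num(v_rev, "v_rev")
  keep <- abs(iv$voltages - v_rev) > exclusion
  v <- iv$voltages[keep]
  g <- iv$peak_current[keep] / (v - v_rev)
  gmax <- max(g)
  degenerate <- !is.finite(gmax) || gmax <= 0
  structure(list(voltages = v, conductance = g,
                 normalized = if (degenerate) rep(NA_real_, length(g)) else g / gmax,
                 excluded_voltages = iv$voltages[!keep], v_rev = v_rev,
                 degenerate = degenerate),
            class = "gv_curve")
}

#' Steady-state availability curve from a two-pulse family
#'
#' Baseline-corrects each sweep, extracts the test-pulse peak magnitude
#' and normalizes by the largest magnitude across prepulse voltages.
#'
#' @param family a `sweep_family` with `modality = "inact"`.
#' @return an `availability_curve`: prepulse voltages and normalized
#'   availability in \[0, 1\].
#' @export
availability_curve <- function(family) {
  stopifnot(inherits(family, "sweep_family"))
  if (!identical(family$modality, "inact"))
    cmq_stop("availability_curve() expects an inactivation-protocol family",
             "cmq_invalid_argument")
  idx <- window_idx(family$time, family$step_window)
  if (!length(idx)) cmq_stop("empty test-pulse window", "cmq_invalid_argument")
  sw <- baseline_correct(family)[idx, , drop = FALSE]
  mag <- apply(sw, 2L, function(y) max(abs(y)))
  if (max(mag) == 0)
    cmq_stop("all test-pulse peaks are zero", "cmq_degenerate_input")
  structure(list(voltages = family$step_voltages,
                 availability = mag / max(mag)),
            class = "availability_curve")
}

# -- Boltzmann fitting ------------------------------------------------------

# Deterministic initialization: midpoint from the linearly interpolated
# half-maximum crossing, slope 6 mV; k bounded in (0.5, 30).
fit_boltzmann <- function(v, y, direction) {
  ok <- is.finite(y) & is.finite(v)
  v <- v[ok]; y <- y[ok]
  if (length(v) < 4L)
    cmq_stop("need at least 4 finite points for a Boltzmann fit",
             "cmq_fit_failure")
  rising <- direction == "activation"
  vh0 <- cross_time(v, y, 0.5, rising = rising)
  if (is.na(vh0)) vh0 <- stats::median(v)
  dat <- data.frame(v = v, y = y)
  fit <- tryCatch(
    stats::nls(
      y ~ boltzmann(v, v_half, k, direction = direction),
      data = dat, start = list(v_half = vh0, k = 6),
      algorithm = "port",
      lower = c(v_half = min(v) - 50, k = 0.5),
      upper = c(v_half = max(v) + 50, k = 30),
      control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                   minFactor = 1e-14, warnOnly = FALSE)),
    error = function(e)
      cmq_stop(sprintf("Boltzmann fit failed to converge: %s (init v_half=%.2f, k=6, n=%d)",
                       conditionMessage(e), vh0, length(v)),
               "cmq_fit_failure"))
  co <- stats::coef(fit)
  structure(list(v_half = unname(co["v_half"]), k = unname(co["k"]),
                 direction = direction,
                 rss = sum(stats::residuals(fit)^2),
                 n_points = length(v),
                 fitted = stats::fitted(fit), voltages = v, data = y),
            class = "boltzmann_fit")
}

#' Fit the Boltzmann steady-state activation curve
#'
#' Least-squares fit of `G/Gmax = 1 / (1 + exp((V1/2 - V)/k))` to the
#' normalized conductance (default) or, with `free_gmax = TRUE`, of
#' `Gmax / (1 + exp((V1/2 - V)/k))` to the raw conductance.
#' Initialization is deterministic (half-maximum crossing, k = 6 mV,
#' k bounded in (0.5, 30)), so the fit is reproducible for given data.
#'
#' @param gv a `gv_curve` from [conductance_curve()].
#' @param free_gmax fit the maximal conductance as a free parameter
#'   instead of normalizing to the per-cell maximum.
#' @return a `boltzmann_fit`: `v_half` (mV), `k` (mV, > 0), direction,
#'   residual sum of squares and number of points.
#' @export
fit_boltzmann_activation <- function(gv, free_gmax = FALSE) {
  stopifnot(inherits(gv, "gv_curve"))
  if (gv$degenerate)
    cmq_stop("degenerate conductance curve (all zero): nothing to fit",
             "cmq_degenerate_input")
  if (!free_gmax) return(fit_boltzmann(gv$voltages, gv$normalized, "activation"))
  v <- gv$voltages; g <- gv$conductance
  dat <- data.frame(v = v, g = g)
  vh0 <- cross_time(v, g / max(g), 0.5, rising = TRUE)
  if (is.na(vh0)) vh0 <- stats::median(v)
  fit <- tryCatch(
    stats::nls(g ~ gmax / (1 + exp((v_half - v) / k)), data = dat,
               start = list(gmax = max(g), v_half = vh0, k = 6),
               algorithm = "port",
               lower = c(gmax = 0, v_half = min(v) - 50, k = 0.5),
               upper = c(gmax = 10 * max(g), v_half = max(v) + 50, k = 30),
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            minFactor = 1e-14)),
    error = function(e) cmq_stop(paste("free-Gmax Boltzmann fit failed:",
                                       conditionMessage(e)), "cmq_fit_failure"))
  co <- stats::coef(fit)
  structure(list(v_half = unname(co["v_half"]), k = unname(co["k"]),
                 g_max = unname(co["gmax"]), direction = "activation",
                 rss = sum(stats::residuals(fit)^2), n_points = length(v),
                 fitted = stats::fitted(fit), voltages = v, data = g),
            class = "boltzmann_fit")
}

#' Fit the Boltzmann steady-state inactivation curve
#'
#' Descending convention `1 / (1 + exp((V - V1/2)/k))` with `k > 0`.
#'
#' @param avail an `availability_curve` (or any list with `voltages` and
#'   `availability`).
#' @return a `boltzmann_fit` with `direction = "inactivation"`.
#' @export
fit_boltzmann_inactivation <- function(avail) {
  v <- avail$voltages
  y <- avail$availability %||% avail$normalized
  fit_boltzmann(v, y, "inactivation")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit %s> V1/2 = %.2f mV, k = %.2f mV (n = %d, rss = %.3g)\n",
              x$direction, x$v_half, x$k, x$n_points, x$rss))
  invisible(x)
}

#' Peak sodium current density
#'
#' The signed current density of maximal magnitude across the I-V curve.
#'
#' @param iv an `iv_curve`.
#' @return density, pA/pF (negative for inward currents).
#' @export
peak_density <- function(iv) {
  stopifnot(inherits(iv, "iv_curve"))
  if (!length(iv$density)) cmq_stop("empty I-V curve", "cmq_invalid_argument")
  iv$density[which.max(abs(iv$density))]
}

# -- per-cohort driver ------------------------------------------------------

#' Analyze a sodium-current cohort
#'
#' Runs peak extraction, the conductance transform and the Boltzmann fit
#' on every cell of a voltage-clamp (`"na"`) or inactivation (`"inact"`)
#' cohort and returns one row per cell.
#'
#' @param cohort a `cohort` from [make_cohort()].
#' @param v_rev reversal potential override, mV. Default `NULL`: estimate
#'   from each cell's I-V zero crossing, falling back to the cell's
#'   ground-truth (configured) value when the protocol does not span the
#'   reversal.
#' @param fit_exclusion half-width of the voltage band around `v_rev`
#'   excluded from the activation fit, mV. The conductance transform
#'   amplifies peak-extraction noise by `1 / |V - v_rev|`, so points near
#'   the reversal are ill-conditioned under realistic noise; the default
#'   (20 mV, four step increments) keeps that amplification bounded while
#'   leaving the whole activation transition in the fit.
#' @return a data.frame with columns `cell`, `group`, and per-modality
#'   fit results (`v_half_act`/`k_act`/`peak_density`/`v_rev_used` or
#'   `v_half_inact`/`k_inact`).
#' @export
analyze_na_cohort <- function(cohort, v_rev = NULL, fit_exclusion = 20) {
  stopifnot(inherits(cohort, "cohort"))
  if (!cohort$modality %in% c("na", "inact"))
    cmq_stop("cohort modality must be 'na' or 'inact'", "cmq_invalid_argument")
  rows <- lapply(seq_along(cohort$cells), function(j) {
    fam <- cohort$cells[[j]]
    if (cohort$modality == "na") {
      iv <- peak_currents(fam)
      vr <- v_rev %||% tryCatch(estimate_reversal(iv),
                                cmq_no_reversal = function(e)
                                  fam$ground_truth$v_rev)
      fit <- fit_boltzmann_activation(
        conductance_curve(iv, vr, exclusion = fit_exclusion))
      data.frame(cell = j, group = cohort$group[j],
                 v_half_act = fit$v_half, k_act = fit$k,
                 peak_density = peak_density(iv), v_rev_used = vr)
    } else {
      fit <- fit_boltzmann_inactivation(availability_curve(fam))
      data.frame(cell = j, group = cohort$group[j],
                 v_half_inact = fit$v_half, k_inact = fit$k)
    }
  })
  do.call(rbind, rows)
}
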