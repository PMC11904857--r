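# Action potential parameterization from paced current-clamp traces.

#' Extract action potential parameters from a paced voltage trace
#'
#' Per beat window (stimulus to next stimulus): the resting potential is
#' the mean of the 50 ms pre-stimulus window; APA is peak voltage minus
#' resting potential; upstroke velocity is the maximum of the
#' Savitzky-Golay-smoothed dV/dt on the rising phase (V/s);
#' depolarization time is stimulus onset to peak; APDx is measured from
#' the maximum-dV/dt instant to the linearly interpolated downward
#' crossing of `peak - x% * APA`. Parameters are averaged across accepted
#' beats. Beats without a peak at least `min_amplitude` mV above rest are
#' rejected and logged in the result.
#'
#' @param trace a `voltage_trace`.
#' @param rest_window pre-stimulus window for the resting potential, ms.
#' @param min_amplitude rejection threshold above rest, mV.
#' @return an `ap_params` list: `apa`, `apd30`, `apd50`, `apd90` (ms),
#'   `upstroke_velocity` (V/s), `depolarization_time` (ms),
#'   `resting_potential` (mV), `n_beats_averaged`, `rejected_beats`.
#' @export
ap_parameters <- function(trace, rest_window = 50, min_amplitude = 10) {
  stopifnot(inherits(trace, "voltage_trace"))
  stim <- trace$stimulus_times
  if (!length(stim)) cmq_stop("no stimuli in trace", "cmq_invalid_argument")
  t <- trace$time; v <- trace$voltage
  dt <- t[2L] - t[1L]
  ends <- c(stim[-1L], max(t) + dt)

  beats <- list(); rejected <- 0L
  for (b in seq_along(stim)) {
    ts <- stim[b]
    pre <- which(t >= ts - rest_window & t < ts)
    win <- which(t >= ts & t < ends[b])
    if (!length(pre) || length(win) < 10L) { rejected <- rejected + 1L; next }
    rest <- mean(v[pre])
    pk <- which.max(v[win])
    peak_v <- v[win][pk]; t_peak <- t[win][pk]
    if (peak_v < rest + min_amplitude) { rejected <- rejected + 1L; next }
    apa <- peak_v - rest

    dvdt <- sg5_deriv(v[win], dt)                  # mV/ms == V/s
    rise <- seq_len(pk)
    iu <- rise[which.max(dvdt[rise])]
    upstroke <- dvdt[iu]
    t_up <- t[win][iu]

    lev <- peak_v - c(0.30, 0.50, 0.90) * apa
    apd <- vapply(lev, function(L) {
      tc <- cross_time(t[win], v[win], L, rising = FALSE, after = t_peak)
      if (is.na(tc)) NA_real_ else tc - t_up
    }, numeric(1L))

    beats[[length(beats) + 1L]] <- c(apa = apa, apd30 = apd[1L],
                                     apd50 = apd[2L], apd90 = apd[3L],
                                     upstroke_velocity = upstroke,
                                     depolarization_time = t_peak - ts,
                                     resting_potential = rest)
  }
  if (!length(beats))
    cmq_stop("no action potentials detected (all beats rejected)", "cmq_no_ap")
  m <- colMeans(do.call(rbind, beats), na.rm = TRUE)
  structure(c(as.list(m), list(n_beats_averaged = length(beats),
                               rejected_beats = rejected)),
            class = "ap_params")
}

#' @export
print.ap_params <- function(x, ...) {
  cat(sprintf("<ap_params> APA %.1f mV, APD30/50/90 %.1f/%.1f/%.1f ms, dV/dt_max %.1f V/s (%d beat(s))\n",
              x$apa, x$apd30, x$apd50, x$apd90, x$upstroke_velocity,
              x$n_beats_averaged))
  invisible(x)
}

#' Analyze an action-potential cohort
#'
#' @param cohort a `cohort` with `modality = "ap"`.
#' @return a data.frame, one row of [ap_parameters()] output per cell.
#' @export
analyze_ap_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"), cohort$modality == "ap")
  rows <- lapply(seq_along(cohort$cells), function(j) {
    p <- ap_parameters(cohort$cells[[j]])
    data.frame(cell = j, group = cohort$group[j], apa = p$apa,
               apd30 = p$apd30, apd50 = p$apd50, apd90 = p$apd90,
               upstroke_velocity = p$upstroke_velocity,
               depolarization_time = p$depolarization_time,
               resting_potential = p$resting_potential,
               n_beats_averaged = p$n_beats_averaged)
  })
  do.call(rbind, rows)
}
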