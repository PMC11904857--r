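# Paced calcium transient segmentation, averaging and parameterization.

#' Segment a paced recording and average the aligned transients
#'
#' Cuts a window of `[-pre, period - pre)` seconds around each stimulus,
#' keeps only complete windows, and averages them sample-wise. The
#' baseline is the mean of the pre-stimulus `baseline_window` seconds of
#' the averaged transient.
#'
#' @param trace a `fluorescence_trace`.
#' @param pre pre-stimulus margin, s.
#' @param baseline_window pre-stimulus span used for the baseline, s.
#' @return an `averaged_transient`: `rel_time` (s, 0 at stimulus),
#'   `mean_ratio`, `n_transients`, `baseline`.
#' @export
segment_and_average <- function(trace, pre = 0.5, baseline_window = 0.4) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  stim <- trace$stimulus_times
  if (length(stim) < 2L)
    cmq_stop("need at least 2 stimuli to segment and average",
             "cmq_insufficient_data")
  dt <- 1 / trace$sampling_rate
  period <- 1 / trace$pacing_hz
  n_pre <- round(pre / dt)
  n_win <- round(period / dt) + 1L    # [-pre, period - pre], endpoint inclusive
  n <- length(trace$time)
  t0 <- trace$time[1L]

  windows <- list()
  for (s in stim) {
    i0 <- round((s - t0) / dt) + 1L           # sample at the stimulus
    lo <- i0 - n_pre; hi <- i0 + (n_win - n_pre) - 1L
    if (lo >= 1L && hi <= n)
      windows[[length(windows) + 1L]] <- trace$ratio[lo:hi]
  }
  if (length(windows) < 2L)
    cmq_stop("fewer than 2 complete stimulus windows in the recording",
             "cmq_insufficient_data")
  avg <- Reduce(`+`, windows) / length(windows)
  rel_time <- (seq_len(n_win) - n_pre - 1L) * dt
  base_idx <- which(rel_time >= -baseline_window & rel_time < 0)
  structure(list(rel_time = rel_time, mean_ratio = avg,
                 n_transients = length(windows),
                 baseline = mean(avg[base_idx])),
            class = "averaged_transient")
}

#' Compute the calcium transient parameter set
#'
#' From an averaged transient: amplitude `A` (peak minus baseline);
#' pre-peak times Tp10/Tp50 (first upward crossing of baseline + 10%/50%
#' of A, linear interpolation) and Tp (time of peak); post-peak recovery
#' times measured from the peak -- with the default `"recovered"`
#' convention Tb10/Tb50 are the times until 10%/50% of the amplitude has
#' recovered (downward crossings of baseline + 90%/50% of A); transient
#' duration is stimulus to 90% recovery (downward crossing of
#' baseline + 10% of A) and time-to-baseline is duration minus Tp.
#' Release/return velocities are the extrema of the Savitzky-Golay
#' smoothed derivative on the rise/decay; AUCs are trapezoidal integrals
#' of the baseline-subtracted signal, stimulus-to-peak (release) and
#' peak-to-90%-recovery (recovery).
#'
#' @param avg an `averaged_transient`.
#' @param convention `"recovered"` (default; TbX = time to recover X% of
#'   the amplitude) or `"remaining"` (TbX = time until X% of the
#'   amplitude remains).
#' @return a `transient_params` list: `amplitude`, `tp10`, `tp50`, `tp`,
#'   `tb10`, `tb50`, `transient_duration`, `time_to_baseline`,
#'   `release_velocity`, `return_velocity`, `auc_release`,
#'   `auc_recovery`, `censored`.
#' @export
transient_parameters <- function(avg, convention = c("recovered", "remaining")) {
  stopifnot(inherits(avg, "averaged_transient"))
  convention <- match.arg(convention)
  post <- avg$rel_time >= 0
  t <- avg$rel_time[post]; y <- avg$mean_ratio[post]
  base <- avg$baseline
  dt <- t[2L] - t[1L]

  pk <- which.max(y)
  amplitude <- y[pk] - base
  if (amplitude <= 0)
    cmq_stop("no transient above baseline", "cmq_degenerate_input")
  tp <- t[pk]

  level_up <- function(frac) cross_time(t[seq_len(pk)], y[seq_len(pk)],
                                        base + frac * amplitude, rising = TRUE)
  tp10 <- level_up(0.10); tp50 <- level_up(0.50)
  # a transient starting at/above the threshold at the stimulus counts as 0
  if (is.na(tp10) && y[1L] >= base + 0.10 * amplitude) tp10 <- 0
  if (is.na(tp50) && y[1L] >= base + 0.50 * amplitude) tp50 <- 0

  rec_frac <- if (convention == "recovered") c(0.90, 0.50, 0.10)
              else                           c(0.10, 0.50, 0.90)
  down <- function(frac) cross_time(t, y, base + frac * amplitude,
                                    rising = FALSE, after = tp)
  t_tb10 <- down(rec_frac[1L]); t_tb50 <- down(rec_frac[2L])
  t_dur <- down(rec_frac[3L])                      # 90% recovery crossing
  censored <- is.na(t_dur)

  tb10 <- t_tb10 - tp; tb50 <- t_tb50 - tp
  transient_duration <- t_dur
  time_to_baseline <- t_dur - tp

  dydt <- sg5_deriv(y, dt)
  release_velocity <- max(dydt[seq_len(pk)])
  return_velocity <- max(-dydt[pk:length(y)])

  rise_idx <- seq_len(pk)
  auc_release <- trapz(t[rise_idx], y[rise_idx] - base)
  if (!censored) {
    dec_idx <- which(t >= tp & t <= t_dur)
    td <- t[dec_idx]; yd <- y[dec_idx] - base
    # close the integral exactly at the recovery crossing
    if (max(td) < t_dur) { td <- c(td, t_dur); yd <- c(yd, 0.10 * amplitude) }
    auc_recovery <- trapz(td, yd)
  } else auc_recovery <- NA_real_

  structure(list(amplitude = amplitude, tp10 = tp10, tp50 = tp50, tp = tp,
                 tb10 = tb10, tb50 = tb50,
                 transient_duration = transient_duration,
                 time_to_baseline = time_to_baseline,
                 release_velocity = release_velocity,
                 return_velocity = return_velocity,
                 auc_release = auc_release, auc_recovery = auc_recovery,
                 censored = censored, convention = convention,
                 n_transients = avg$n_transients, baseline = base),
            class = "transient_params")
}

#' @export
print.transient_params <- function(x, ...) {
  cat(sprintf("<transient_params> A %.3f, Tp %.3f s, duration %.3f s (%s convention, %d transients%s)\n",
              x$amplitude, x$tp, x$transient_duration, x$convention,
              x$n_transients, if (x$censored) ", CENSORED" else ""))
  invisible(x)
}

#' Analyze a calcium cohort
#'
#' @param cohort a `cohort` with `modality = "ca"`.
#' @param convention passed to [transient_parameters()].
#' @return a data.frame, one parameter row per cell.
#' @export
analyze_ca_cohort <- function(cohort, convention = "recovered") {
  stopifnot(inherits(cohort, "cohort"), cohort$modality == "ca")
  rows <- lapply(seq_along(cohort$cells), function(j) {
    p <- transient_parameters(segment_and_average(cohort$cells[[j]]),
                              convention = convention)
    data.frame(cell = j, group = cohort$group[j], amplitude = p$amplitude,
               tp10 = p$tp10, tp50 = p$tp50, tp = p$tp,
               tb10 = p$tb10, tb50 = p$tb50,
               transient_duration = p$transient_duration,
               time_to_baseline = p$time_to_baseline,
               release_velocity = p$release_velocity,
               return_velocity = p$return_velocity,
               auc_release = p$auc_release, auc_recovery = p$auc_recovery,
               censored = p$censored)
  })
  do.call(rbind, rows)
}
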