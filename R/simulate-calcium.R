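# Synthetic paced Fura-2 calcium recordings.

#' Calcium transient shape targets
#'
#' Ground-truth parameters for the paced transient generator. Ratio units
#' are unitless Fura-2 340/380 ratios; defaults (baseline 1.0, amplitude
#' 0.3, rise 50 ms, decay 400 ms) describe a healthy paced
#' stem-cell-derived cardiomyocyte.
#'
#' @param amplitude transient amplitude A above baseline (ratio units).
#' @param baseline diastolic ratio level.
#' @param tau_rise,tau_decay rise and decay time constants, s (> 0).
#' @return an object of class `transient_targets`.
#' @export
transient_targets <- function(amplitude = 0.3, baseline = 1.0,
                              tau_rise = 0.05, tau_decay = 0.4) {
  assert_num(tau_rise, "tau_rise", positive = TRUE)
  assert_num(tau_decay, "tau_decay", positive = TRUE)
  if (amplitude < 0) cmq_stop("`amplitude` must be >= 0", "cmq_invalid_target")
  structure(list(amplitude = amplitude, baseline = baseline,
                 tau_rise = tau_rise, tau_decay = tau_decay),
            class = "transient_targets")
}

#' Normalized rise-times-decay transient kernel
#'
#' `K(t) = A * c * (1 - exp(-t/tau_rise)) * exp(-t/tau_decay)` with `c`
#' chosen so the kernel maximum equals `A`. The peak occurs at the
#' closed-form time `t* = tau_rise * log(1 + tau_decay/tau_rise)`.
#'
#' @param t time since stimulus, s (values < 0 give 0).
#' @param amplitude,tau_rise,tau_decay kernel parameters.
#' @return kernel values; `attr(, "peak_time")` carries t*.
#' @export
calcium_kernel <- function(t, amplitude = 0.3, tau_rise = 0.05, tau_decay = 0.4) {
  t_star <- tau_rise * log(1 + tau_decay / tau_rise)
  raw <- function(u) (1 - exp(-u / tau_rise)) * exp(-u / tau_decay)
  k <- ifelse(t < 0, 0, amplitude * raw(pmax(t, 0)) / raw(t_star))
  attr(k, "peak_time") <- t_star
  k
}

#' Simulate a paced Fura-2 ratio recording
#'
#' Superimposes identical transient kernels at regular stimulus times on
#' a constant baseline. Stimulus times are stored in the trace metadata;
#' the first stimulus is placed 0.5 s after recording onset so that every
#' stimulus except the last has a complete analysis window.
#'
#' @param targets a [transient_targets()].
#' @param pacing_hz field-stimulation frequency, Hz.
#' @param duration recording length, s.
#' @param noise_sd Gaussian noise as a fraction of the amplitude.
#' @param seed integer seed for the noise.
#' @param sampling_rate acquisition rate, Hz.
#' @return a `fluorescence_trace`: time (s), ratio, stimulus times,
#'   pacing rate and the generating targets.
#' @export
simulate_calcium_recording <- function(targets = transient_targets(),
                                       pacing_hz = 0.2, duration = 150,
                                       noise_sd = 0, seed = NULL,
                                       sampling_rate = 1000) {
  stopifnot(inherits(targets, "transient_targets"))
  assert_num(pacing_hz, "pacing_hz", positive = TRUE)
  assert_num(duration, "duration", positive = TRUE)
  period <- 1 / pacing_hz
  t_star <- targets$tau_rise * log(1 + targets$tau_decay / targets$tau_rise)
  if (period < t_star + 5 * targets$tau_decay)
    cmq_stop("pacing period shorter than the transient duration: transients would overlap",
             "cmq_overlapping_transients")
  dt <- 1 / sampling_rate
  time <- seq(0, duration - dt, by = dt)
  stim <- seq(0.5, duration - 1e-9, by = period)
  ratio <- rep(targets$baseline, length(time))
  for (s in stim) {
    idx <- which(time >= s)
    ratio[idx] <- ratio[idx] + as.numeric(
      calcium_kernel(time[idx] - s, targets$amplitude,
                     targets$tau_rise, targets$tau_decay))
  }
  if (noise_sd > 0) {
    if (is.null(seed)) cmq_stop("`seed` is required when noise_sd > 0",
                                "cmq_invalid_argument")
    set.seed(seed)
    ratio <- ratio + stats::rnorm(length(ratio),
                                  sd = noise_sd * max(targets$amplitude, .Machine$double.eps))
  }
  structure(list(time = time, ratio = ratio, stimulus_times = stim,
                 pacing_hz = pacing_hz, sampling_rate = sampling_rate,
                 targets = targets, seed = seed),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %.0f s at %g Hz, %d stimuli at %g Hz pacing\n",
              max(x$time), x$sampling_rate, length(x$stimulus_times), x$pacing_hz))
  invisible(x)
}
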