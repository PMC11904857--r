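# Synthetic electrophysiology generators: m3h voltage-clamp families,
# two-pulse inactivation families, and parametric paced action potentials.

# -- gating model primitives ------------------------------------------------

m_inf <- function(preset, v) boltzmann(v, preset$v_half_act, preset$k_act)
h_inf <- function(preset, v) boltzmann(v, preset$v_half_inact, preset$k_inact,
                                       direction = "inactivation")

# Bell-shaped activation time constant centered on v_half_act (fixed
# 15 mV half-width, 0.1 ms floor). Centering on v_half_act makes every
# voltage-dependent term of the m gate translate rigidly with the
# activation midpoint.
tau_m <- function(preset, v) {
  0.1 + (preset$tau_m_max - 0.1) / cosh((v - preset$v_half_act) / 15)
}

# Inactivation time constant: voltage-independent by design so that the
# fitted steady-state midpoints inherit rigid preset translations exactly
# (see methods vignette).
tau_h <- function(preset, v) rep(preset$tau_h_max, length(v))

# single-exponential relaxation of a gate from g0 toward its steady state
relax <- function(g0, ginf, tau, t) ginf + (g0 - ginf) * exp(-t / tau)

# current in pA from conductance (nS) and driving force (mV)
mh_current <- function(preset, m, h, v) preset$g_max * m^3 * h * (v - preset$v_rev)

# -- voltage-clamp I-V family ----------------------------------------------

#' Simulate a voltage-clamp sodium current family
#'
#' Generates one current sweep per depolarizing step using an m3h gating
#' model: `I(t, V) = g_max * m(t)^3 * h(t) * (V - v_rev)`, with `m` and `h`
#' relaxing mono-exponentially from their holding-potential steady states
#' toward Boltzmann-shaped steady states at the step voltage. Gaussian
#' noise with standard deviation `noise_sd * |global peak|` is added when
#' `noise_sd > 0`.
#'
#' @param preset a [gating_preset()].
#' @param protocol a [vclamp_protocol()].
#' @param noise_sd noise standard deviation as a fraction of the noiseless
#'   global peak magnitude (>= 0).
#' @param seed integer seed for the noise (required when `noise_sd > 0`).
#' @return a `sweep_family`: time axis (ms), a samples-by-sweeps current
#'   matrix (pA), step voltages (mV), capacitance (pF), the protocol, the
#'   step search window and the generating preset as ground truth.
#' @seealso [peak_currents()], [simulate_inactivation_family()]
#' @export
simulate_vclamp_family <- function(preset, protocol = vclamp_protocol(),
                                   noise_sd = 0, seed = NULL) {
  stopifnot(inherits(preset, "gating_preset"), inherits(protocol, "vclamp_protocol"))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    cmq_stop("`noise_sd` must be >= 0", "cmq_invalid_argument")
  dt <- 1 / protocol$sampling_rate
  n_pre <- round(protocol$pre_duration / dt)
  n_step <- round(protocol$step_duration / dt)
  time <- (seq_len(n_pre + n_step) - 1L) * dt
  t_on <- n_pre * dt
  volts <- seq(protocol$step_start, protocol$step_stop, by = protocol$step_increment)

  m0 <- m_inf(preset, protocol$holding)
  h0 <- h_inf(preset, protocol$holding)
  i_hold <- mh_current(preset, m0, h0, protocol$holding)
  ts <- time[(n_pre + 1L):(n_pre + n_step)] - t_on

  sweeps <- vapply(volts, function(v) {
    m <- relax(m0, m_inf(preset, v), tau_m(preset, v), ts)
    h <- relax(h0, h_inf(preset, v), tau_h(preset, v)[1L], ts)
    c(rep(i_hold, n_pre), mh_current(preset, m, h, v))
  }, numeric(length(time)))

  if (noise_sd > 0) {
    if (is.null(seed)) cmq_stop("`seed` is required when noise_sd > 0",
                                "cmq_invalid_argument")
    set.seed(seed)
    sweeps <- sweeps + stats::rnorm(length(sweeps),
                                    sd = noise_sd * max(abs(sweeps)))
  }
  structure(list(time = time, sweeps = sweeps, step_voltages = volts,
                 capacitance = preset$capacitance, protocol = protocol,
                 step_window = c(t_on, t_on + protocol$step_duration),
                 baseline_window = c(0, t_on), modality = "na",
                 ground_truth = preset, seed = seed),
            class = "sweep_family")
}

#' @export
print.sweep_family <- function(x, ...) {
  cat(sprintf("<sweep_family '%s'> %d sweeps x %d samples, steps %g..%g mV, Cm %.0f pF\n",
              x$modality, ncol(x$sweeps), nrow(x$sweeps),
              min(x$step_voltages), max(x$step_voltages), x$capacitance))
  invisible(x)
}

# -- steady-state inactivation family --------------------------------------

#' Simulate a two-pulse steady-state inactivation family
#'
#' For each prepulse voltage the h gate relaxes toward its steady state
#' during the conditioning prepulse; the subsequent fixed test pulse
#' elicits a transient current whose peak scales with the channel
#' availability at prepulse end. The noiseless test-pulse peak magnitude
#' is non-increasing in prepulse voltage.
#'
#' @inheritParams simulate_vclamp_family
#' @param protocol an [inact_protocol()].
#' @return a `sweep_family` with `modality = "inact"`, prepulse voltages
#'   as `step_voltages`, and the test-pulse window in `step_window`.
#' @export
simulate_inactivation_family <- function(preset, protocol = inact_protocol(),
                                         noise_sd = 0, seed = NULL) {
  stopifnot(inherits(preset, "gating_preset"), inherits(protocol, "inact_protocol"))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    cmq_stop("`noise_sd` must be >= 0", "cmq_invalid_argument")
  dt <- 1 / protocol$sampling_rate
  n_pre <- round(protocol$pre_duration / dt)
  n_cond <- round(protocol$prepulse_duration / dt)
  n_test <- round(protocol$test_duration / dt)
  time <- (seq_len(n_pre + n_cond + n_test) - 1L) * dt
  t_cond_on <- n_pre * dt
  t_test_on <- (n_pre + n_cond) * dt
  volts <- seq(protocol$prepulse_start, protocol$prepulse_stop,
               by = protocol$prepulse_increment)
  vt <- protocol$test_voltage

  m0 <- m_inf(preset, protocol$holding)
  h0 <- h_inf(preset, protocol$holding)
  i_hold <- mh_current(preset, m0, h0, protocol$holding)
  t_cond <- time[(n_pre + 1L):(n_pre + n_cond)] - t_cond_on
  t_test <- time[(n_pre + n_cond + 1L):length(time)] - t_test_on

  sweeps <- vapply(volts, function(vp) {
    m_c <- relax(m0, m_inf(preset, vp), tau_m(preset, vp), t_cond)
    h_c <- relax(h0, h_inf(preset, vp), tau_h(preset, vp)[1L], t_cond)
    m_end <- m_c[length(m_c)]; h_end <- h_c[length(h_c)]
    m_t <- relax(m_end, m_inf(preset, vt), tau_m(preset, vt), t_test)
    h_t <- relax(h_end, h_inf(preset, vt), tau_h(preset, vt)[1L], t_test)
    c(rep(i_hold, n_pre), mh_current(preset, m_c, h_c, vp),
      mh_current(preset, m_t, h_t, vt))
  }, numeric(length(time)))

  if (noise_sd > 0) {
    if (is.null(seed)) cmq_stop("`seed` is required when noise_sd > 0",
                                "cmq_invalid_argument")
    set.seed(seed)
    # noise scaled to the test-window peak so availability SNR is controlled
    test_rows <- (n_pre + n_cond + 1L):length(time)
    sweeps <- sweeps + stats::rnorm(length(sweeps),
                                    sd = noise_sd * max(abs(sweeps[test_rows, ])))
  }
  structure(list(time = time, sweeps = sweeps, step_voltages = volts,
                 capacitance = preset$capacitance, protocol = protocol,
                 step_window = c(t_test_on, t_test_on + protocol$test_duration),
                 baseline_window = c(0, t_cond_on), modality = "inact",
                 ground_truth = preset, seed = seed),
            class = "sweep_family")
}

# -- paced action potentials -----------------------------------------------

#' Action potential shape targets
#'
#' Target parameters for the parametric paced action potential generator.
#' APDs are measured from the maximum-upstroke-velocity instant, matching
#' the extraction convention of [ap_parameters()], so round-trips are
#' exact up to sampling resolution. Defaults describe a ventricular-like
#' stem-cell-derived cardiomyocyte paced at 1 Hz.
#'
#' @param apa action potential amplitude, mV (> 0).
#' @param apd30,apd50,apd90 durations at 30/50/90% repolarization, ms;
#'   must be strictly increasing.
#' @param resting resting membrane potential, mV.
#' @param rise_time upstroke duration, ms.
#' @return an object of class `ap_targets`.
#' @export
ap_targets <- function(apa = 100, apd30 = 150, apd50 = 220, apd90 = 320,
                       resting = -75, rise_time = 2) {
  if (!(apd30 < apd50 && apd50 < apd90))
    cmq_stop("APD targets must satisfy apd30 < apd50 < apd90",
             "cmq_invalid_target")
  if (apa <= 0) cmq_stop("`apa` must be > 0", "cmq_invalid_target")
  assert_num(rise_time, "rise_time", positive = TRUE)
  structure(list(apa = apa, apd30 = apd30, apd50 = apd50, apd90 = apd90,
                 resting = resting, rise_time = rise_time),
            class = "ap_targets")
}

#' Simulate a paced current-clamp voltage trace
#'
#' Parametric waveform (not an ionic model): a half-cosine upstroke from
#' rest to peak over `rise_time`, then a monotone repolarization built by
#' monotone cubic interpolation through the (APDx, repolarization level)
#' anchors, measured from the maximum-dV/dt instant. APD targets are
#' therefore exactly recoverable by [ap_parameters()] up to sampling
#' resolution.
#'
#' @param targets an [ap_targets()].
#' @param n_beats number of paced beats.
#' @param pacing_hz pacing frequency, Hz.
#' @param noise_sd additive Gaussian noise, mV.
#' @param seed integer seed for the noise.
#' @param sampling_rate acquisition rate, kHz.
#' @return a `voltage_trace`: time (ms), voltage (mV), stimulus times and
#'   the generating targets.
#' @export
simulate_ap_trace <- function(targets = ap_targets(), n_beats = 5,
                              pacing_hz = 1, noise_sd = 0, seed = NULL,
                              sampling_rate = 20) {
  stopifnot(inherits(targets, "ap_targets"))
  assert_num(pacing_hz, "pacing_hz", positive = TRUE)
  if (n_beats < 1) cmq_stop("`n_beats` must be >= 1", "cmq_invalid_argument")
  period <- 1000 / pacing_hz
  if (targets$apd90 + 80 > period)
    cmq_stop("pacing period too short for the APD90 target",
             "cmq_invalid_target")
  dt <- 1 / sampling_rate
  first_stim <- 100
  total <- first_stim + n_beats * period
  time <- seq(0, total, by = dt)
  stim <- first_stim + (seq_len(n_beats) - 1L) * period

  rest <- targets$resting
  peak <- rest + targets$apa
  rise <- targets$rise_time
  # repolarization anchors relative to the max-dV/dt instant (rise midpoint)
  tail_len <- 0.25 * (targets$apd90 - targets$apd50) + 20
  kt <- c(rise / 2, targets$apd30, targets$apd50, targets$apd90,
          targets$apd90 + tail_len)
  kv <- c(peak, peak - 0.30 * targets$apa, peak - 0.50 * targets$apa,
          peak - 0.90 * targets$apa, rest)
  repol <- stats::splinefun(kt, kv, method = "hyman")

  v <- rep(rest, length(time))
  for (ts in stim) {
    rel <- time - ts                     # relative to stimulus onset
    up <- rel >= 0 & rel < rise
    v[up] <- rest + targets$apa * (1 - cos(pi * rel[up] / rise)) / 2
    tu <- rel - rise / 2                 # relative to max dV/dt
    dn <- tu >= rise / 2 & tu <= kt[length(kt)]
    v[dn] <- repol(tu[dn])
  }
  if (noise_sd > 0) {
    if (is.null(seed)) cmq_stop("`seed` is required when noise_sd > 0",
                                "cmq_invalid_argument")
    set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  structure(list(time = time, voltage = v, stimulus_times = stim,
                 sampling_rate = sampling_rate, targets = targets,
                 seed = seed),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples at %g kHz, %d stimuli\n",
              length(x$time), x$sampling_rate, length(x$stimulus_times)))
  invisible(x)
}
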