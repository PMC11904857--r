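#' Boltzmann sigmoid for steady-state gating
#'
#' Ascending (activation) form `1 / (1 + exp((v_half - v) / k))` or
#' descending (inactivation/availability) form
#' `1 / (1 + exp((v - v_half) / k))`, both with slope factor `k > 0`.
#'
#' @param v membrane potential(s), mV.
#' @param v_half midpoint, mV; the curve equals 0.5 there.
#' @param k slope factor, mV, must be positive.
#' @param direction `"activation"` (ascending) or `"inactivation"`
#'   (descending).
#' @return numeric vector of fractions in (0, 1).
#' @export
#' @examples
#' boltzmann(-35, v_half = -35, k = 6)            # 0.5
#' boltzmann(0, -78, 6, direction = "inactivation")
boltzmann <- function(v, v_half, k, direction = c("activation", "inactivation")) {
  direction <- match.arg(direction)
  assert_num(k, "k", positive = TRUE)
  if (direction == "activation") 1 / (1 + exp((v_half - v) / k))
  else                           1 / (1 + exp((v - v_half) / k))
}

#' Sodium-channel gating preset
#'
#' Parameter set for the m3h voltage-gated sodium current generator:
#' steady-state activation/inactivation midpoints and slopes, maximal
#' conductance, reversal potential, relaxation time constants and cell
#' capacitance. Presets are the ground truth that synthetic voltage-clamp
#' families are generated from and that the analysis pipeline is expected
#' to recover.
#'
#' The absolute default values are plausible for heterologously measured
#' Nav1.5-like currents in immature stem-cell-derived cardiomyocytes; only
#' the *between-group differences* encoded by [r1267q_preset()] (+5 mV
#' activation shift, reduced g_max) and [v2264m_preset()] (-11 mV
#' inactivation shift) are study-derived effects.
#'
#' @param v_half_act,k_act steady-state activation midpoint and slope, mV.
#' @param v_half_inact,k_inact steady-state inactivation midpoint and
#'   slope, mV.
#' @param g_max maximal conductance, nS.
#' @param v_rev reversal potential, mV.
#' @param tau_m_max peak of the bell-shaped activation time constant, ms.
#'   The bell is centered on `v_half_act` so that a rigid voltage
#'   translation of activation gating translates every voltage-dependent
#'   term of the m gate.
#' @param tau_h_max inactivation time constant, ms. Voltage-independent by
#'   design (see the methods vignette): this preserves the rigid
#'   translation property of the downstream fitted midpoints.
#' @param capacitance cell capacitance, pF.
#' @param label free-text group label.
#' @return an object of class `gating_preset`.
#' @export
gating_preset <- function(v_half_act = -35, k_act = 6,
                          v_half_inact = -78, k_inact = 6,
                          g_max = 20, v_rev = 65,
                          tau_m_max = 0.5, tau_h_max = 8,
                          capacitance = 30, label = "preset") {
  assert_num(k_act, "k_act", positive = TRUE)
  assert_num(k_inact, "k_inact", positive = TRUE)
  assert_num(g_max, "g_max", positive = TRUE)
  assert_num(tau_m_max, "tau_m_max", positive = TRUE)
  assert_num(tau_h_max, "tau_h_max", positive = TRUE)
  assert_num(capacitance, "capacitance", positive = TRUE)
  assert_num(v_half_act, "v_half_act")
  assert_num(v_half_inact, "v_half_inact")
  assert_num(v_rev, "v_rev")
  structure(list(v_half_act = v_half_act, k_act = k_act,
                 v_half_inact = v_half_inact, k_inact = k_inact,
                 g_max = g_max, v_rev = v_rev,
                 tau_m_max = tau_m_max, tau_h_max = tau_h_max,
                 capacitance = capacitance, label = label),
            class = "gating_preset")
}

#' @export
print.gating_preset <- function(x, ...) {
  cat(sprintf(
    "<gating_preset '%s'> act: V1/2 %.1f mV, k %.1f | inact: V1/2 %.1f mV, k %.1f | g_max %.1f nS, Vrev %.0f mV, Cm %.0f pF\n",
    x$label, x$v_half_act, x$k_act, x$v_half_inact, x$k_inact,
    x$g_max, x$v_rev, x$capacitance))
  invisible(x)
}

#' Group presets: healthy donor and the two FLNC variant lines
#'
#' `donor_preset()` carries the package's reference gating parameters.
#' `r1267q_preset()` applies the arrhythmogenic-cardiomyopathy-variant
#' phenotype: a rigid +5 mV depolarizing translation of steady-state
#' activation (midpoint and the voltage dependence of tau_m move
#' together) plus a reduction of maximal conductance (direction
#' study-derived; the 30% magnitude is an invented plausible value).
#' `v2264m_preset()` applies the restrictive-cardiomyopathy-variant
#' phenotype: a rigid -11 mV hyperpolarizing translation of steady-state
#' inactivation.
#'
#' @return a `gating_preset`.
#' @export
donor_preset <- function() gating_preset(label = "Donor")

#' @rdname donor_preset
#' @export
r1267q_preset <- function() {
  p <- donor_preset()
  p$v_half_act <- p$v_half_act + 5
  p$g_max <- p$g_max * 0.7
  p$label <- "R1267Q"
  p
}

#' @rdname donor_preset
#' @export
v2264m_preset <- function() {
  p <- donor_preset()
  p$v_half_inact <- p$v_half_inact - 11
  p$label <- "V2264M"
  p
}

#' Voltage-clamp step protocol for the current-voltage relation
#'
#' Depolarizing steps from a fixed holding potential; defaults follow the
#' standard sodium I-V protocol: holding -100 mV, 40 ms steps from -80 to
#' +60 mV in 5 mV increments, 20 kHz acquisition.
#'
#' @param holding holding potential, mV.
#' @param step_start,step_stop,step_increment step voltage range, mV.
#' @param step_duration step length, ms.
#' @param sampling_rate acquisition rate, kHz; must lie in \[20, 50\].
#' @param pre_duration pre-step baseline segment at holding, ms (used for
#'   per-sweep baseline correction).
#' @return an object of class `vclamp_protocol`.
#' @export
vclamp_protocol <- function(holding = -100, step_start = -80, step_stop = 60,
                            step_increment = 5, step_duration = 40,
                            sampling_rate = 20, pre_duration = 5) {
  if (!is.numeric(step_increment) || step_increment <= 0 ||
      !is.numeric(step_duration) || step_duration <= 0 ||
      !is.numeric(pre_duration) || pre_duration <= 0 ||
      step_start >= step_stop ||
      !is.numeric(sampling_rate) || sampling_rate < 20 || sampling_rate > 50)
    cmq_stop("invalid voltage-clamp protocol: need step_increment > 0, step_start < step_stop, durations > 0, sampling_rate in [20, 50] kHz",
             "cmq_invalid_protocol")
  structure(list(holding = holding, step_start = step_start,
                 step_stop = step_stop, step_increment = step_increment,
                 step_duration = step_duration, sampling_rate = sampling_rate,
                 pre_duration = pre_duration),
            class = "vclamp_protocol")
}

#' Steady-state inactivation (availability) protocol
#'
#' Two-pulse protocol: a long conditioning prepulse followed by a fixed
#' test pulse. Defaults: 500 ms prepulses from -120 to 0 mV in 5 mV steps
#' from holding -100 mV, then a 20 ms test step to -15 mV.
#'
#' @param prepulse_start,prepulse_stop,prepulse_increment prepulse voltage
#'   range, mV.
#' @param prepulse_duration prepulse length, ms.
#' @param test_voltage,test_duration test pulse, mV / ms.
#' @param holding holding potential, mV.
#' @param sampling_rate acquisition rate, kHz in \[20, 50\].
#' @param pre_duration baseline segment at holding before the prepulse, ms.
#' @return an object of class `inact_protocol`.
#' @export
inact_protocol <- function(prepulse_start = -120, prepulse_stop = 0,
                           prepulse_increment = 5, prepulse_duration = 500,
                           test_voltage = -15, test_duration = 20,
                           holding = -100, sampling_rate = 20,
                           pre_duration = 5) {
  if (!is.numeric(prepulse_increment) || prepulse_increment <= 0 ||
      prepulse_start >= prepulse_stop ||
      !is.numeric(prepulse_duration) || prepulse_duration <= 0 ||
      !is.numeric(test_duration) || test_duration <= 0 ||
      !is.numeric(sampling_rate) || sampling_rate < 20 || sampling_rate > 50)
    cmq_stop("invalid inactivation protocol: increments and durations must be > 0, sampling_rate in [20, 50] kHz",
             "cmq_invalid_protocol")
  structure(list(prepulse_start = prepulse_start, prepulse_stop = prepulse_stop,
                 prepulse_increment = prepulse_increment,
                 prepulse_duration = prepulse_duration,
                 test_voltage = test_voltage, test_duration = test_duration,
                 holding = holding, sampling_rate = sampling_rate,
                 pre_duration = pre_duration),
            class = "inact_protocol")
}
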