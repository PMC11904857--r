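# Sodium-current analysis: peaks, reversal, conductance, Boltzmann fits.

make_family <- function(sweeps, voltages, time, capacitance = 25,
                        step_window = range(time), modality = "na") {
  structure(list(time = time, sweeps = sweeps, step_voltages = voltages,
                 capacitance = capacitance, protocol = vclamp_protocol(),
                 step_window = step_window, baseline_window = c(0, 0),
                 modality = modality, ground_truth = NULL),
            class = "sweep_family")
}

test_that("peak extraction returns the signed extremum and density", {
  t <- seq(0, 40, by = 0.05)
  zero <- matrix(0, length(t), 1L)
  rect <- matrix(ifelse(t >= 10 & t < 20, -500, 0), ncol = 1L)
  fam <- make_family(cbind(zero, rect), c(-40, -20), t)
  iv <- peak_currents(fam)
  expect_equal(iv$peak_current, c(0, -500))
  expect_equal(iv$density, c(0, -20))               # -500 pA / 25 pF

  # oracle equivalence: brute-force scan over all samples
  set.seed(42)
  noisy <- matrix(rnorm(3 * length(t)), ncol = 3L)
  fam2 <- make_family(noisy, c(-30, -20, -10), t)
  iv2 <- peak_currents(fam2)
  brute <- apply(noisy, 2L, function(y) y[which.max(abs(y))])
  expect_identical(iv2$peak_current, brute)
})

test_that("reversal potential is interpolated from the zero crossing", {
  iv <- structure(list(voltages = c(35, 45, 55, 65),
                       peak_current = c(-400, -200, -50, 50),
                       density = c(-16, -8, -2, 2), capacitance = 25),
                  class = "iv_curve")
  expect_equal(estimate_reversal(iv), 60)           # midpoint of (-50, +50)

  mono <- structure(list(voltages = c(-40, -20, 0),
                         peak_current = c(-100, -300, -200),
                         density = c(-4, -12, -8), capacitance = 25),
                    class = "iv_curve")
  expect_error(estimate_reversal(mono), class = "cmq_no_reversal")

  # noiseless simulation spanning the reversal: estimate within half a step
  fam <- simulate_vclamp_family(donor_preset(),
                                vclamp_protocol(step_stop = 80))
  expect_equal(estimate_reversal(peak_currents(fam)), 65, tolerance = 2.5 / 65)
})

test_that("conductance transform: arithmetic, exclusion band, degenerate input", {
  iv <- structure(list(voltages = c(-20, 68, 70),
                       peak_current = c(-900, 10, 0),
                       density = c(-36, 0.4, 0), capacitance = 25),
                  class = "iv_curve")
  gv <- conductance_curve(iv, v_rev = 70)
  expect_equal(gv$voltages, -20)                    # +-2.5 mV of v_rev excluded
  expect_equal(gv$conductance, 10)                  # -900 / (-90) nS
  expect_equal(gv$excluded_voltages, c(68, 70))

  iv0 <- structure(list(voltages = c(-40, -20, 0), peak_current = c(0, 0, 0),
                        density = c(0, 0, 0), capacitance = 25),
                   class = "iv_curve")
  gv0 <- conductance_curve(iv0, v_rev = 65)
  expect_true(gv0$degenerate)
  expect_true(all(is.na(gv0$normalized)))
  expect_error(fit_boltzmann_activation(gv0), class = "cmq_degenerate_input")

  # noiseless conductance is non-negative at all retained voltages
  fam <- simulate_vclamp_family(donor_preset())
  gv1 <- conductance_curve(peak_currents(fam), 65)
  expect_true(all(gv1$conductance >= -1e-12))
})

test_that("Boltzmann fit recovers exact samples to 1e-6 and is translation-equivariant", {
  v <- seq(-80, 0, by = 5)
  y <- boltzmann(v, -35, 6)
  gv <- structure(list(voltages = v, conductance = y, normalized = y,
                       v_rev = 65, degenerate = FALSE), class = "gv_curve")
  fit <- fit_boltzmann_activation(gv)
  expect_lt(abs(fit$v_half - -35), 1e-6)
  expect_lt(abs(fit$k - 6), 1e-6)
  expect_equal(boltzmann(fit$v_half, fit$v_half, fit$k), 0.5)  # midpoint identity

  # translation equivariance: shifted data shifts v_half by delta, k unchanged
  for (delta in c(5, -11, 2.5)) {
    y2 <- boltzmann(v, -35 + delta, 6)
    gv2 <- structure(list(voltages = v, conductance = y2, normalized = y2,
                          v_rev = 65, degenerate = FALSE), class = "gv_curve")
    fit2 <- fit_boltzmann_activation(gv2)
    expect_equal(fit2$v_half - fit$v_half, delta, tolerance = 1e-8)
    expect_equal(fit2$k, fit$k, tolerance = 1e-8)
  }

  # descending (inactivation) form
  vi <- seq(-120, 0, by = 5)
  avail <- list(voltages = vi,
                availability = boltzmann(vi, -78, 6, "inactivation"))
  fi <- fit_boltzmann_inactivation(avail)
  expect_lt(abs(fi$v_half - -78), 1e-6)
  expect_lt(abs(fi$k - 6), 1e-6)
  avail2 <- list(voltages = vi,
                 availability = boltzmann(vi, -89, 6, "inactivation"))
  expect_equal(fit_boltzmann_inactivation(avail2)$v_half - fi$v_half, -11,
               tolerance = 1e-8)
})

test_that("noiseless apparent G-V is near-Boltzmann with the oracle-frozen residual", {
  # the m3h apparent activation curve is not exactly Boltzmann: fitting
  # exact m_inf^3 samples (fast-m/slow-h limit) leaves rss = 0.0026, and
  # the kinetic generator leaves rss ~ 0.013 on 29 normalized points
  v <- seq(-80, 60, by = 5)
  y3 <- boltzmann(v, -35, 6)^3; y3 <- y3 / max(y3)
  gv3 <- structure(list(voltages = v, conductance = y3, normalized = y3,
                        v_rev = 100, degenerate = FALSE), class = "gv_curve")
  expect_equal(fit_boltzmann_activation(gv3)$rss, 0.00262, tolerance = 0.05)

  fam <- simulate_vclamp_family(donor_preset())
  fit <- fit_boltzmann_activation(conductance_curve(peak_currents(fam), 65))
  expect_lt(fit$rss, 0.02)
  expect_gt(fit$k, 0)
})

test_that("availability curve: anchors, flat input, degenerate error", {
  fam <- simulate_inactivation_family(donor_preset())
  av <- availability_curve(fam)
  expect_equal(max(av$availability), 1.0)
  expect_equal(av$availability[av$voltages == -120], 1.0)

  t <- seq(0, 20, by = 0.05)
  flat <- matrix(-100, length(t), 3L)
  famf <- make_family(flat, c(-120, -60, 0), t, modality = "inact")
  avf <- availability_curve(famf)
  expect_equal(avf$availability, rep(1, 3L))

  zero <- make_family(matrix(0, length(t), 3L), c(-120, -60, 0), t,
                      modality = "inact")
  expect_error(availability_curve(zero), class = "cmq_degenerate_input")
})

test_that("peak density picks the extremum of the density curve", {
  iv <- structure(list(voltages = c(-40, -20, 0),
                       peak_current = c(-250, -1250, -500),
                       density = c(-10, -50, -20), capacitance = 25),
                  class = "iv_curve")
  expect_equal(peak_density(iv), -50)
  iv0 <- structure(list(voltages = 0, peak_current = 0, density = 0,
                        capacitance = 25), class = "iv_curve")
  expect_equal(peak_density(iv0), 0)
})

test_that("rigid preset translations are recovered end-to-end (noiseless)", {
  fit_act <- function(preset) {
    fam <- simulate_vclamp_family(preset)
    fit_boltzmann_activation(conductance_curve(peak_currents(fam), preset$v_rev))
  }
  d <- fit_act(donor_preset()); r <- fit_act(r1267q_preset())
  expect_equal(r$v_half - d$v_half, 5, tolerance = 0.1 / 5)

  fit_inact <- function(preset)
    fit_boltzmann_inactivation(availability_curve(
      simulate_inactivation_family(preset)))
  di <- fit_inact(donor_preset()); vi <- fit_inact(v2264m_preset())
  expect_equal(vi$v_half - di$v_half, -11, tolerance = 0.1 / 11)
})
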