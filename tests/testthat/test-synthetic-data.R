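# Generators: protocol validation, trivial limits, oracle agreement,
# determinism.

test_that("voltage-clamp generator obeys its physical limits", {
  p <- donor_preset()
  proto <- vclamp_protocol(step_start = -120, step_stop = 70, step_increment = 5)
  fam <- simulate_vclamp_family(p, proto)

  # step exactly at v_rev: zero driving force, identically zero current
  i_rev <- which(fam$step_voltages == p$v_rev)
  expect_length(i_rev, 1L)
  expect_equal(max(abs(fam$sweeps[, i_rev])), 0)

  # far below activation threshold: peak negligible vs g_max * |V - v_rev|
  i_lo <- which(fam$step_voltages == -120)
  expect_lt(max(abs(fam$sweeps[, i_lo])), 1e-3 * p$g_max * abs(-120 - p$v_rev))

  # inward current between threshold and reversal
  i_mid <- which(fam$step_voltages == -20)
  expect_lt(min(fam$sweeps[, i_mid]), 0)
})

test_that("noiseless peak currents match the dense time-stepping oracle", {
  p <- donor_preset()
  fam <- simulate_vclamp_family(p)
  iv <- peak_currents(fam)
  for (v in c(-40, -30, -20, -10, 0, 20)) {
    oracle <- ode_step_peak(p, v)
    got <- iv$peak_current[iv$voltages == v]
    expect_equal(got, oracle, tolerance = 0.005)
  }
  # spec'd spot value: signed peak at -20 mV equals g_max * max_t(m^3 h) * (V - v_rev)
  expect_lt(abs(iv$peak_current[iv$voltages == -20] / ode_step_peak(p, -20) - 1),
            0.005)
})

test_that("inactivation generator: saturation, full inactivation, midpoint", {
  p <- donor_preset()
  fam <- simulate_inactivation_family(p)
  av <- availability_curve(fam)

  expect_equal(av$availability[av$voltages == -120], 1.0)
  expect_gt(ode_prepulse_h(p, -120), 0.99)          # full availability
  expect_lt(av$availability[av$voltages == 0], 1e-3) # fully inactivated

  # prepulse at v_half_inact with 500 ms >> tau_h: half availability
  proto <- inact_protocol(prepulse_start = -120, prepulse_stop = 0,
                          prepulse_increment = 1)
  fam2 <- simulate_inactivation_family(p, proto)
  av2 <- availability_curve(fam2)
  mid <- av2$availability[av2$voltages == p$v_half_inact]
  expect_equal(mid, 0.5, tolerance = 0.01)

  # noiseless test-pulse peak magnitude is non-increasing in prepulse voltage
  idx <- which(fam$time >= fam$step_window[1L] & fam$time < fam$step_window[2L])
  mag <- apply(fam$sweeps[idx, ], 2L, function(y) max(abs(y)))
  expect_true(all(diff(mag) <= 1e-9))
})

test_that("AP generator paces correctly and honors target validation", {
  tr <- simulate_ap_trace(ap_targets(), n_beats = 5, pacing_hz = 1)
  expect_length(tr$stimulus_times, 5L)
  expect_equal(unique(diff(tr$stimulus_times)), 1000)
  # pre-stimulus segment rests exactly at the target resting potential
  pre <- tr$voltage[tr$time < tr$stimulus_times[1L]]
  expect_equal(unique(pre), -75)
  expect_error(ap_targets(apd30 = 200, apd50 = 150, apd90 = 300),
               class = "cmq_invalid_target")
})

test_that("calcium generator: kernel peak time, flat limit, stimulus count", {
  k <- calcium_kernel(seq(0, 2, by = 1e-4), amplitude = 1,
                      tau_rise = 0.05, tau_decay = 0.4)
  expect_equal(attr(k, "peak_time"), 0.05 * log(9))
  expect_equal(max(k), 1, tolerance = 1e-6)

  tr0 <- simulate_calcium_recording(transient_targets(amplitude = 0))
  expect_equal(unique(tr0$ratio), tr0$targets$baseline)

  tr <- simulate_calcium_recording(duration = 150, pacing_hz = 0.2)
  expect_length(tr$stimulus_times, 30L)

  expect_error(simulate_calcium_recording(
    transient_targets(tau_decay = 3), pacing_hz = 1),
    class = "cmq_overlapping_transients")
})

test_that("striation generator: ridge count, alignment, undersampling guard", {
  g <- striation_geometry(period = 1.9, actin_shift = 0,
                          image_size = c(32, 190), pixel_size = 0.1)
  img <- simulate_striation_image(g)
  pr <- extract_profile(img)
  maxima <- detect_extrema(pr, 1L, "max")
  expect_length(maxima, 10L)                        # 19 um / 1.9 um
  # zero shift: channel-2 minima coincide with channel-1 maxima
  minima <- detect_extrema(pr, 2L, "min")
  d <- vapply(as.numeric(maxima), function(m) min(abs(minima - m)), numeric(1L))
  expect_lt(max(d), 0.25 * g$pixel_size)

  expect_error(simulate_striation_image(striation_geometry(pixel_size = 0.6)),
               class = "cmq_undersampling")
})

test_that("protocol validation rejects malformed settings", {
  expect_error(vclamp_protocol(sampling_rate = 10), class = "cmq_invalid_protocol")
  expect_error(vclamp_protocol(step_increment = -5), class = "cmq_invalid_protocol")
  expect_error(vclamp_protocol(step_duration = 0), class = "cmq_invalid_protocol")
  expect_error(inact_protocol(prepulse_increment = 0), class = "cmq_invalid_protocol")
})

test_that("all generators are deterministic given (parameters, seed)", {
  p <- donor_preset()
  expect_identical(simulate_vclamp_family(p, noise_sd = 0.02, seed = 7),
                   simulate_vclamp_family(p, noise_sd = 0.02, seed = 7))
  expect_identical(simulate_ap_trace(noise_sd = 1, seed = 7),
                   simulate_ap_trace(noise_sd = 1, seed = 7))
  expect_identical(simulate_calcium_recording(noise_sd = 0.02, seed = 7),
                   simulate_calcium_recording(noise_sd = 0.02, seed = 7))
  expect_identical(simulate_striation_image(photons = 200, seed = 7),
                   simulate_striation_image(photons = 200, seed = 7))
})

test_that("make_cohort stores ground truth and is bit-reproducible", {
  presets <- list(Donor = donor_preset(), R1267Q = r1267q_preset())
  co <- make_cohort(presets, n_cells = 3, modality = "na", seed = 11,
                    noise_sd = 0.01)
  expect_length(co$cells, 6L)
  expect_equal(table(co$group)[["Donor"]], 3L)
  expect_identical(co, make_cohort(presets, n_cells = 3, modality = "na",
                                   seed = 11, noise_sd = 0.01))

  # zero variability: cell parameters equal the preset exactly
  co0 <- make_cohort(presets["Donor"], n_cells = 1, modality = "na", seed = 1,
                     noise_sd = 0, cv_amplitude = 0, sd_voltage = 0)
  expect_identical(co0$ground_truth[[1L]], presets$Donor)

  expect_error(make_cohort(list(), 5), class = "cmq_invalid_argument")
})
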