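# Synthetic cohorts: groups of per-cell recordings with stored ground truth.

perturb_preset <- function(preset, cv_amplitude, sd_voltage) {
  p <- preset
  if (inherits(preset, "gating_preset")) {
    p$g_max <- preset$g_max * stats::rlnorm(1L, sdlog = sqrt(log(1 + cv_amplitude^2)))
    p$v_half_act <- preset$v_half_act + stats::rnorm(1L, sd = sd_voltage)
    p$v_half_inact <- preset$v_half_inact + stats::rnorm(1L, sd = sd_voltage)
  } else if (inherits(preset, "ap_targets")) {
    p$apa <- preset$apa * stats::rlnorm(1L, sdlog = sqrt(log(1 + cv_amplitude^2)))
    f <- stats::rlnorm(1L, sdlog = sqrt(log(1 + cv_amplitude^2)))
    p$apd30 <- preset$apd30 * f; p$apd50 <- preset$apd50 * f
    p$apd90 <- preset$apd90 * f  # shared factor keeps APD ordering
  } else if (inherits(preset, "transient_targets")) {
    p$amplitude <- preset$amplitude * stats::rlnorm(1L, sdlog = sqrt(log(1 + cv_amplitude^2)))
    f <- stats::rlnorm(1L, sdlog = sqrt(log(1 + cv_amplitude^2)))
    p$tau_rise <- preset$tau_rise * f; p$tau_decay <- preset$tau_decay * f
  } else if (inherits(preset, "striation_geometry")) {
    p$actin_shift <- preset$actin_shift + stats::rnorm(1L, sd = 0.01)
    p$zdisk_sigma <- preset$zdisk_sigma * stats::rlnorm(1L, sdlog = sqrt(log(1 + cv_amplitude^2)))
  } else {
    cmq_stop("unsupported preset class", "cmq_invalid_argument")
  }
  p
}

simulate_cell <- function(preset, modality, noise_sd, seed, protocol = NULL) {
  switch(modality,
    na    = simulate_vclamp_family(preset, protocol %||% vclamp_protocol(),
                                   noise_sd = noise_sd, seed = seed),
    inact = simulate_inactivation_family(preset, protocol %||% inact_protocol(),
                                         noise_sd = noise_sd, seed = seed),
    ap    = simulate_ap_trace(preset, noise_sd = noise_sd, seed = seed),
    ca    = simulate_calcium_recording(preset, noise_sd = noise_sd, seed = seed),
    image = simulate_striation_image(preset,
                                     photons = if (noise_sd > 0) 1 / noise_sd^2 else Inf,
                                     seed = seed),
    cmq_stop(sprintf("unknown modality '%s'", modality), "cmq_invalid_argument"))
}

#' Generate a synthetic multi-group cohort
#'
#' Draws `n_cells` cells per group preset, perturbing each preset with
#' small inter-cell variability (multiplicative log-normal on amplitudes,
#' additive Gaussian on voltages), simulates one recording per cell and
#' stores the exact per-cell generator parameters as ground truth.
#' Cohorts are deterministic given `(presets, parameters, seed)`: per-cell
#' simulation seeds are `seed + cell index`.
#'
#' @param group_presets named list of presets (one per group); classes
#'   must match `modality` ([gating_preset()] for `"na"`/`"inact"`,
#'   [ap_targets()] for `"ap"`, [transient_targets()] for `"ca"`,
#'   [striation_geometry()] for `"image"`).
#' @param n_cells cells per group (>= 1).
#' @param modality one of `"na"`, `"inact"`, `"ap"`, `"ca"`, `"image"`.
#' @param seed master integer seed.
#' @param noise_sd per-recording noise level (fraction of peak for
#'   voltage-clamp/calcium, mV for APs, shot-noise scale for images).
#' @param cv_amplitude coefficient of variation of amplitude-like
#'   parameters across cells (default 5%).
#' @param sd_voltage inter-cell standard deviation of gating midpoints, mV.
#' @param protocol optional protocol override for `"na"`/`"inact"`.
#' @return a `cohort`: per-cell recordings, group labels, ground-truth
#'   parameter list and the master seed.
#' @export
make_cohort <- function(group_presets, n_cells, modality = "na", seed = 1,
                        noise_sd = 0.02, cv_amplitude = 0.05, sd_voltage = 1,
                        protocol = NULL) {
  if (!length(group_presets))
    cmq_stop("`group_presets` must be a non-empty list", "cmq_invalid_argument")
  if (n_cells < 1) cmq_stop("`n_cells` must be >= 1", "cmq_invalid_argument")
  labels <- names(group_presets) %||%
    vapply(group_presets, function(p) p$label %||% "group", character(1L))
  if (is.null(names(group_presets))) names(group_presets) <- labels

  set.seed(seed)
  cells <- list(); truth <- list(); group <- character(0L)
  idx <- 0L
  for (g in seq_along(group_presets)) {
    for (i in seq_len(n_cells)) {
      idx <- idx + 1L
      cell_preset <- if (cv_amplitude == 0 && sd_voltage == 0) group_presets[[g]]
                     else perturb_preset(group_presets[[g]], cv_amplitude, sd_voltage)
      truth[[idx]] <- cell_preset
      group[idx] <- labels[g]
    }
  }
  for (j in seq_along(truth)) {
    cells[[j]] <- simulate_cell(truth[[j]], modality, noise_sd,
                                seed = derive_seed(seed, j), protocol = protocol)
  }
  structure(list(cells = cells, group = group, ground_truth = truth,
                 modality = modality, seed = seed, n_cells = n_cells,
                 noise_sd = noise_sd),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s'> %d cells in %d group(s): %s (seed %d)\n",
              x$modality, length(x$cells), length(unique(x$group)),
              paste(unique(x$group), collapse = ", "), x$seed))
  invisible(x)
}
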