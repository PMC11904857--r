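# Independent oracles used to freeze expected values. These deliberately
# avoid the analytic relaxation code path of the generators: the step
# response is integrated by dense explicit time stepping, calcium
# parameters are measured by brute-force sample search on a 10 kHz grid,
# and Mann-Whitney p-values come from counting pairwise wins over every
# group labeling.

# dense Euler integration of the m3h step response; returns the signed
# peak current (pA) during the step
ode_step_peak <- function(preset, v_step, holding = -100, duration = 40,
                          dt = 2e-4) {
  minf <- function(v) 1 / (1 + exp((preset$v_half_act - v) / preset$k_act))
  hinf <- function(v) 1 / (1 + exp((v - preset$v_half_inact) / preset$k_inact))
  taum <- function(v) 0.1 + (preset$tau_m_max - 0.1) / cosh((v - preset$v_half_act) / 15)
  m <- minf(holding); h <- hinf(holding)
  mi <- minf(v_step); hi <- hinf(v_step)
  tm <- taum(v_step); th <- preset$tau_h_max
  drive <- preset$g_max * (v_step - preset$v_rev)
  peak <- 0
  for (i in seq_len(round(duration / dt))) {
    m <- m + dt * (mi - m) / tm
    h <- h + dt * (hi - h) / th
    cur <- m^3 * h * drive
    if (abs(cur) > abs(peak)) peak <- cur
  }
  peak
}

# availability at prepulse end by dense Euler integration of h
ode_prepulse_h <- function(preset, v_pre, holding = -100, duration = 500,
                           dt = 0.01) {
  hinf <- function(v) 1 / (1 + exp((v - preset$v_half_inact) / preset$k_inact))
  h <- hinf(holding); hi <- hinf(v_pre)
  for (i in seq_len(round(duration / dt)))
    h <- h + dt * (hi - h) / preset$tau_h_max
  h
}

# brute-force calcium parameter oracle: kernel sampled at 10 kHz,
# crossings by first-sample search (no interpolation), AUC by rectangle sum
ca_oracle <- function(targets, horizon = 4.5, fs = 1e4,
                      convention = "recovered") {
  dt <- 1 / fs
  t <- seq(0, horizon, by = dt)
  y <- as.numeric(calcium_kernel(t, targets$amplitude, targets$tau_rise,
                                 targets$tau_decay))
  A <- max(y)
  pk <- which.max(y)
  tp <- t[pk]
  up <- function(frac) t[which(y >= frac * A)[1L]]
  dn <- function(frac) { i <- which(y <= frac * A & t > tp)[1L]; t[i] }
  rec <- if (convention == "recovered") c(0.90, 0.50, 0.10) else c(0.10, 0.50, 0.90)
  t_dur <- dn(rec[3L])
  list(amplitude = A, tp10 = up(0.10), tp50 = up(0.50), tp = tp,
       tb10 = dn(rec[1L]) - tp, tb50 = dn(rec[2L]) - tp,
       transient_duration = t_dur, time_to_baseline = t_dur - tp,
       release_velocity = max(diff(y) / dt),
       return_velocity = max(-diff(y) / dt),
       auc_release = sum(y[t <= tp]) * dt,
       auc_recovery = sum(y[t > tp & t <= t_dur]) * dt)
}

# full-permutation Mann-Whitney oracle: U counted as pairwise wins,
# two-sided p by doubling the smaller tail over all labelings
mw_perm_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  u_null <- apply(utils::combn(n1 + n2, n1), 2L, u_of)
  list(u1 = u_obs,
       p = min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs))))
}

# triangular action potential with linear rise and fall, for closed-form
# APD checks
triangle_ap_trace <- function(rest = -80, peak = 20, rise_ms = 2,
                              fall_ms = 200, fs_khz = 20, stim_ms = 100,
                              total_ms = 500) {
  dt <- 1 / fs_khz
  t <- seq(0, total_ms, by = dt)
  v <- rep(rest, length(t))
  r <- t >= stim_ms & t < stim_ms + rise_ms
  v[r] <- rest + (peak - rest) * (t[r] - stim_ms) / rise_ms
  f <- t >= stim_ms + rise_ms & t < stim_ms + rise_ms + fall_ms
  v[f] <- peak - (peak - rest) * (t[f] - stim_ms - rise_ms) / fall_ms
  structure(list(time = t, voltage = v, stimulus_times = stim_ms,
                 sampling_rate = fs_khz, targets = NULL, seed = NULL),
            class = "voltage_trace")
}

# synthetic single-row profile from a function of position (um)
profile_from_function <- function(f1, f2 = NULL, length_um = 20,
                                  pixel_size = 0.05) {
  x <- seq(0, length_um, by = pixel_size)
  ch <- list(matrix(f1(x), nrow = 3, ncol = length(x), byrow = TRUE))
  labels <- "ch1"
  if (!is.null(f2)) {
    ch <- c(ch, list(matrix(f2(x), nrow = 3, ncol = length(x), byrow = TRUE)))
    labels <- c(labels, "ch2")
  }
  img <- multichannel_image(ch, pixel_size = pixel_size, channel_labels = labels)
  extract_profile(img)
}
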