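---
title: "Models, conventions and design decisions in cmquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design decisions in cmquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmquant)
```

cmquant quantifies four readouts of iPSC-derived cardiomyocyte
physiology — sodium-current gating, action potentials, paced calcium
transients, and striation morphometry — plus two-group nonparametric
statistics. Because raw patch-clamp, photometry and imaging data for
the phenotypes it targets are not publicly available at trace level,
every analysis stage is paired with a synthetic generator whose
parameters are the ground truth. This vignette explains the models,
the measurement conventions, the numerical choices, and what a passing
test does and does not establish.

## The sodium-current generator

Voltage-clamp families are produced by a Hodgkin–Huxley-style m³h
model:

$$ I(t, V) = g_\max\, m(t)^3\, h(t)\, (V - V_{rev}), $$

with both gates relaxing mono-exponentially from their
holding-potential steady states toward Boltzmann-shaped steady states
at the step voltage:

* $m_\infty(V) = 1/(1 + e^{(V_{1/2,act} - V)/k_{act}})$, ascending;
* $h_\infty(V) = 1/(1 + e^{(V - V_{1/2,inact})/k_{inact}})$, descending.

**Time constants.** $\tau_m(V)$ is bell-shaped
($0.1 + (\tau_{m,\max} - 0.1)/\cosh((V - V_{1/2,act})/15)$ ms) and
*centered on the activation midpoint*, so that a rigid voltage
translation of activation gating translates every voltage-dependent
term of the m gate. $\tau_h$ is **voltage-independent** by design
(default 8 ms). This is a deliberate deviation from the more realistic
bell-shaped inactivation time constant: the package's central
validation property is that a rigid translation of one gate's voltage
dependence translates the downstream *fitted* midpoint by exactly the
same amount, and a voltage-dependent $\tau_h$ breaks that property for
the activation pathway (the peak of $m^3 h$ mixes the two gates'
kinetics; numerically, a bell-shaped $\tau_h$ inflated a +5 mV preset
translation to 5.3–5.7 mV, while the constant-$\tau_h$ model recovers
4.99 mV). Realism was traded for an exactly testable invariant; the
generator is a validation instrument, not an ionic model.

**Apparent vs generator parameters.** The fitted activation midpoint
(≈ −24 mV for the default donor preset) is depolarized relative to the
generator's $V_{1/2,act} = -35$ mV because peak conductance of an m³h
model is approximately $m_\infty^3$ sharpened by kinetics. The apparent
G–V curve is consequently *not* an exact Boltzmann: fitting exact
$m_\infty^3$ samples leaves a residual sum of squares of 0.0026, and
the kinetic generator about 0.013 on 29 unit-normalized points. Tests
therefore validate (a) exact-sample fits to machine precision and
(b) between-preset *shifts*, never absolute apparent midpoints.

**Preset values.** The donor preset ($V_{1/2,act} = -35$,
$k_{act} = 6$, $V_{1/2,inact} = -78$, $k_{inact} = 6$ mV,
$g_\max = 20$ nS, $V_{rev} = +65$ mV, $C_m = 30$ pF) uses invented but
plausible values for an immature Nav1.5-dominated cardiomyocyte; the
study the package targets reports only relative effects. Only the
between-group differences are study-derived: R1267Q = donor with
activation translated +5 mV and $g_\max$ reduced (direction reported;
the 30% magnitude is a choice), V2264M = donor with inactivation
translated −11 mV.

## Sodium-current analysis conventions

* **Baseline correction**: per sweep, the mean of the 5 ms pre-step
  window is subtracted (the source protocol is silent; this is the
  standard minimal leak handling).
* **Peak**: signed extremum of largest magnitude in the step window;
  inward currents are negative.
* **Reversal potential**: linearly interpolated zero crossing of the
  I–V's positive limb when the protocol spans it; otherwise a
  configured value (the default protocol stops at +60 mV, below the
  +65 mV preset reversal, so cohort analysis falls back to the
  configured value). The source describes the conductance equation but
  not where $V_{rev}$ comes from.
* **Conductance exclusion bands**: `conductance_curve()` drops points
  within ±2.5 mV of $V_{rev}$ (half the step increment) where the
  division is singular. Cohort-level *fitting* additionally excludes
  $|V - V_{rev}| < 20$ mV by default (`fit_exclusion`): the transform
  amplifies peak-extraction noise by $1/|V - V_{rev}|$, and under the
  2% noise used for validation the near-reversal points are pure noise
  amplified 10–30-fold — with only the ±2.5 mV band excluded, fits
  pegged at the slope bound and the recovered +5 mV shift collapsed to
  ~1 mV. The 20 mV default (four step increments) keeps the whole
  activation transition (−60…0 mV) in the fit. The noiseless recovered
  shift is 4.97 mV with the guard band and 4.99 mV without; both are
  within the 0.1 mV invariant tolerance.
* **Boltzmann fitting**: `stats::nls` (port algorithm), deterministic
  initialization ($V_{1/2}$ from the interpolated half-maximum
  crossing, $k = 6$ mV), $k$ bounded in (0.5, 30) mV. Activation uses
  the ascending form on per-cell-maximum-normalized conductance by
  default (`free_gmax = TRUE` fits $G_\max$ instead; the source's
  equation admits both). Inactivation uses the descending form with
  $k > 0$, the standard availability convention.

## Action potentials

The generator is a parametric waveform, not an ionic model: a
half-cosine upstroke (default 2 ms) from rest to peak, then a monotone
repolarization built by Hyman-monotone cubic interpolation through the
(APDx, repolarization level) anchors measured from the maximum-dV/dt
instant. This makes APD targets exactly recoverable, which is the point:
round-trip tests then certify the *extractor* to 0.5 mV / 1 ms.

Extraction conventions: resting potential = mean of the 50 ms
pre-stimulus window; APA = peak − rest; APDx measured **from the
maximum-dV/dt instant** (robust to stimulus-artifact latency) to the
linearly interpolated downward crossing of peak − x%·APA, with
repolarization levels referenced to the single beat's APA rather than a
train MDP; depolarization time = stimulus onset → peak (the source
names but does not define it; threshold-to-peak would be the
alternative); dV/dt from a 5-point Savitzky–Golay quadratic derivative
(noise robustness without biasing the peak location at 20–50 kHz).
Beats lacking a peak 10 mV above rest are rejected and logged;
parameters, not traces, are averaged across beats (robust to beat-time
jitter).

## Calcium transients

The generator superimposes identical kernels

$$ F(t) = \text{baseline} + A\,c\,(1 - e^{-t/\tau_{rise}})\,e^{-t/\tau_{decay}}, $$

$c$ chosen so the maximum equals $A$; the peak time has the closed form
$t^* = \tau_{rise}\ln(1 + \tau_{decay}/\tau_{rise})$, used directly in
tests. Defaults (baseline 1.0, $A = 0.3$ ratio units,
$\tau_{rise} = 50$ ms, $\tau_{decay} = 400$ ms, 0.2 Hz pacing, 150 s
recordings, 1 kHz sampling) describe a healthy paced hiPSC-CMC on a
ratiometric photometry rig. The first stimulus sits 0.5 s after
recording onset; analysis windows span $[-0.5, \text{period} - 0.5]$ s
around each stimulus, endpoint inclusive, so a 150 s recording at
0.2 Hz holds 30 stimuli of which the last window is truncated,
leaving 29 averaged transients.

Parameter conventions: baseline = pre-stimulus 0.4 s mean of the
*averaged* transient (robust to drift, unlike a global minimum);
threshold crossings by linear interpolation, first crossing wins.
The recovery-time convention is **"recovered"**: Tb10 is the time from
peak until 10% of the amplitude has recovered (descending crossing of
baseline + 90%·A), transient duration is stimulus → 90% recovery, and
time-to-baseline = duration − Tp. The alternative "remaining" reading
(time until X% of amplitude remains) is a monotone relabeling and is
available via `convention = "remaining"`. AUCs are trapezoidal
integrals of the baseline-subtracted signal: release from stimulus to
peak, recovery from peak to the 90%-recovery crossing (the source
names AUC recovery without bounds; peak-to-90%-recovery was chosen to
match the duration definition). Velocities are extrema of the 5-point
quadratic-smoothed derivative; at 1 kHz the smoothing window biases the
release velocity of a 50 ms-rise kernel by a few percent, so oracle
comparisons at 0.5% run at the oracle's 10 kHz resolution.

## Striation morphometry

The generator draws parallel Gaussian Z-disk ridges (period 1.9 µm,
σ = 0.15 µm by default) in channel 1 and a complementary Gaussian band
comb in channel 2 whose *minima* sit at the ridge positions translated
by the configured actin shift; Poisson photon noise gives
SNR = $\sqrt{\text{photons} \times I}$. An earlier one-minus-valley
construction was discarded because valley overlap distorted band FWHM
by ~15%; with the band-comb design both the shift and the band length
are exact ground truth.

Measurement conventions: profiles are bilinearly sampled at one-pixel
spacing along a user-supplied line (auto-orientation is a non-goal);
extrema are detected on a 3-point moving average with a topographic
prominence threshold of 10% of the channel range and refined by
3-point parabolic interpolation (sub-pixel); widths are **FWHM above
the local trough level**, with crossings searched outward from each
peak on the *raw* profile (smoothing-free, hence unbiased and
offset-invariant; the source never defines where width is read).
Actin-shift ties (nearest minimum ambiguous because the shift is half a
period) are flagged and excluded rather than averaged — the measurement
is undefined there. Intensity ratios subtract a per-channel 5th
percentile background and are invariant to a global gain.

## Statistics

Mann–Whitney U with midrank ties, reported as min(U₁, U₂), two-sided
throughout. Exact p by full enumeration of the null distribution for
tie-free samples with combined n ≤ 12; otherwise the normal
approximation with tie correction and continuity correction. The
exact/approximate cross-validation property (agreement within 0.02)
holds when both groups have at least 5 observations — an exhaustive
sweep shows worst-case deviations of 0.0172 (5+5), 0.0155 (6+6) and
0.0150 (5+7), but 0.0375 at 3+3 — so the property test covers the
min-group-≥5 configurations exhaustively. Summaries report mean, SD
(n−1) and SEM, since published figure panels use both conventions.
Stars follow the half-open bins \*<0.05, \*\*<0.01, \*\*\*<0.001,
\*\*\*\*<0.0001; no multiple-testing correction is applied by default
(mirroring common practice in the source domain), with a Holm option
available.

## What a green test establishes — and what it does not

The synthetic cohorts demonstrate that the *pipeline* recovers encoded
effects: rigid gating translations survive peak extraction, the
conductance transform and fitting to within 1 mV at 2% noise and 20
cells/group. They do not validate the generator against real
recordings: real sodium currents have voltage-dependent inactivation
kinetics, series-resistance and space-clamp artifacts; real calcium
transients show beat-to-beat variability and drift; real striations
are curved and heterogeneous. Absolute preset values are plausible
inventions, so only between-group contrasts are meaningful.

## Determinism and provenance

All generators are deterministic given (parameters, seed); cohorts
derive per-cell seeds as master + cell index, so any cell can be
regenerated in isolation. `run_pipeline()` writes CSVs with fixed
formatting and a manifest (package version, seed, config, 31-bit
polynomial config hash); identical config + seed yields byte-identical
outputs.
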