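---
title: "Quantifying periodicity in RR-interval series: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying periodicity in RR-interval series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvper)
```

## Why periodicity, and what is being modelled

An RR-interval series is the sequence of times between successive heart
beats. Classical HRV indices describe its dispersion (SDNN, RMSSD), its
spectral band content (LF/HF), or its complexity (DFA, sample entropy), but
none of them asks directly whether the series *oscillates regularly*. Under
fixed-rate mechanical ventilation the heart can entrain to the ventilator,
producing an RR series that is nearly a pure oscillation at the ventilator
frequency; under variable ventilation the same coupling produces a broadband,
irregular modulation. Both situations can have identical variance, so the
dispersion indices are blind to the difference, and because the entrained
frequency moves with the ventilator, fixed-band spectral ratios are also
unreliable.

`hrvper` therefore treats *periodicity* as the object of measurement, with
two complementary views:

* **Spectral view.** A periodic series concentrates power in a narrow band;
  an aperiodic one spreads it. We estimate the spectrum with the
  Lomb-Scargle periodogram, which is a least-squares estimator valid for
  unevenly sampled data — RR values sit at their own beat times, so no
  resampling onto a uniform grid is needed (and none is performed). Power
  below 0.3 Hz is excluded as drift, the 0.3–2 Hz band is normalized to a
  probability distribution over frequency, and two statistics summarise it:
  the peak (`maxPER`) and the transformed Relative Shannon Entropy (`trse`),
  `1 + sum(P * log(P)) / log(M)` over `M = 20` equal-width bins. The entropy
  view is the more robust of the two because it uses the whole distribution
  rather than one ordinate.
* **Autocorrelation view.** The lag-domain signature of periodicity is an
  autocorrelation function (ACF) that itself oscillates; broadband series
  have a rapidly decaying, irregular ACF. Lags count beats, not seconds,
  because beats are unevenly spaced. Before the ACF is computed the series
  is detrended piecewise-linearly (below), and `R(d)` follows the
  `1/(N - d)` estimator on the population-standardized residuals, so
  `R(0) = 1` exactly. `max_acf`/`mean_acf` summarise `|R(d)|` over
  d = 25–50 beats, and `se_acf` is the sample entropy of the ACF values —
  low when the autocorrelogram is regular and predictable.

The assumptions are mild but worth stating: epochs are treated as
quasi-stationary after piecewise-linear detrending; periodicity in the
0.3–2 Hz band is the phenomenon of interest (appropriate for rodent
ventilation and heart rates); and artifacts are rare enough that exclusion,
rather than interpolation, is the right repair.

## The tunable parameters

All constants live in one `run_config()` object.

| Parameter | Default | Units | Role |
|---|---|---|---|
| `epoch_length` | 150 | s | analysis epoch (2.5 min) |
| `spectral_band` | 0.3–2.0 | Hz | periodicity band; below 0.3 Hz treated as drift |
| `trse_bins` | 20 | — | entropy bins `M` |
| `acf_d_range` | 25–50 | beats | lag window for maxACF/meanACF (inclusive: 26 lags) |
| `acf_max_lag` | 200 | beats | ACF ceiling; effective max is `min(floor(N/2), 200)` |
| `se_acf_tolerance_factor` | 0.4 | ×SD of ACF | SampEn tolerance for SE.ACF |
| `sampen_m`, `sampen_r_factor` | 2, 0.2 | —, ×SDNN | SampEn settings for the RR series |
| `lf_band`, `hf_band` | 0.1–1, 1–3.5 | Hz | rodent LF/HF conventions |
| `oversample` | 4 | — | Lomb-Scargle grid spacing `1/(oversample × duration)` |
| `min_segment` | 30 | beats | smallest detrending segment |
| `fnn_threshold`, `fnn_fraction`, `max_m` | 10, 0.05, 10 | — | false-nearest-neighbour selection of the SE.ACF pattern length |
| `mi_bins` | 10 | — | histogram bins per axis for the mutual information |

The 0.3–2 Hz band contains both the rodent ventilator frequency (~1 Hz) and
the oscillator used for validation (natural frequency `sqrt(40)/2π ≈ 1.007`
Hz). The lag window 25–50 covers several oscillation periods at rodent heart
rates. The ACF ceiling of 200 lags comfortably contains the 25–50 window
and many periods; it is configurable because the entropy of a shorter ACF is
estimated from fewer templates and is noticeably noisier.

## Numerical and design choices

**Relative-spectrum denominator.** "Relative" power could be normalized by
the total over the whole spectrum or by the in-band total. We normalize by
the in-band total so the relative spectrum is a probability distribution on
the band and the entropy argument is exact: a uniform distribution gives
tRSE = 0, a single loaded bin gives 1. `normalization = "full_spectrum"` is
available for sensitivity analysis; `trse()` re-normalizes bin masses, so
its value is unchanged, while `max_per` then reflects in-band fraction as
well as concentration. Empty bins contribute `0·log 0 := 0` (the continuity
limit); a spectrum with zero in-band power is a degenerate-input error
rather than a silent 0/0.

**Detrending.** Change points come from binary segmentation over a
piecewise-linear model: a split is accepted when it reduces the residual sum
of squares by more than a BIC-style penalty `3·log(n)·σ²`, with `σ²`
estimated from first differences (robust to the trend itself), and segments
are at least 30 beats. An exactly linear input therefore stays one segment
with ~0 residuals, and white noise is left essentially untouched, while
piecewise trends are removed before they can masquerade as low-frequency
periodicity in the ACF.

**SE.ACF embedding.** The delay is the first local minimum of the
histogram-based mutual information between `R(d)` and `R(d+τ)`; 10 bins per
axis resolve the minimum (wider histograms wash it out on the
arcsine-distributed values of an oscillatory ACF, pushing the minimum past
the quarter period). If no local minimum exists, τ = 1 is used and logged.
The pattern length is the smallest dimension with a false-nearest-neighbour
fraction below 5% (distance-ratio threshold 10), capped at 10. Two guards
matter in practice: temporal neighbours within τ samples are excluded from
the nearest-neighbour search, and the added-coordinate separation must
exceed a noise floor (10⁻⁸ of the value range) before a neighbour counts as
false — otherwise the near-duplicate templates of a periodic ACF produce
ratios of floating-point rounding errors and a spurious FNN fraction at
every dimension.

**Sample entropy conventions.** `sample_entropy()` follows the standard
equal-count convention: the `m`- and `(m+1)`-length templates share the same
start indices, so a constant series gives exactly 0 and `A ≤ B` always. The
price is that time reversal is only symmetric up to an O(1/n) edge effect
(one window at the opposite end changes). When no template pair matches, the
result is `NA` with a reason attribute — undefined, never infinite, and
never a silent NaN.

**Oscillator integration.** The validation oscillator is
`x'' = (1 − x²)·x' − (ω + C·z)·x` with `z ~ N(0, 1)` redrawn once per 0.2 s
step and held constant within the step — a stochastically forced ODE is only
well defined under a classical solver with piecewise-constant forcing. Each
0.2 s interval is integrated with classical RK4 *sub-steps* (8, retried at
32/128/512 if the state goes non-finite). The sub-steps are not optional at
large `C`: when `ω + C·z` is transiently negative the amplitude inflates
until the stiff `(1 − x²)·x'` damping pulls it back, and one 0.2 s RK4 step
is unstable through that excursion even though the true trajectory is
bounded. The initial state (2, 0) lies on the noise-free limit cycle, so no
burn-in is discarded; at `C = 0` the noise term vanishes and the output is
seed-independent.

**Ensemble protocol.** The benchmark uses 21 noise levels in steps of 2.5
(C = 0–50) with 20 realizations each. The number of levels (r = 21 enters
the monotonicity normalization, 210 pairs) and the 2.5 step are both fixed
by the validation design; per-cell child seeds are drawn from the master
seed so any cell is reproducible in isolation.

**Monotonicity statistic.** Pairs of noise levels are compared with
two-sided Wilcoxon rank-sum tests at α = 0.05 (exact for groups up to 25
without ties), signed by the rank statistic; no multiple-testing correction
is applied across the 210 pairs, matching the single stated α. M is
rank-based, hence invariant under strictly monotone transforms of the
measure, and the absolute value makes increasing and decreasing measures
score identically. Identical constant rows (which occur at C = 0, where the
ensemble is deterministic) are defined as h = 0. A measure that fails on any
cell invalidates its whole noise level — failed cells are excluded wholesale
and logged, never imputed.

## What the synthetic generators emulate — and what they do not

`generate_ensemble()` produces oscillations of controlled bandwidth: the
ideal test bed for a bandwidth-tracking measure, but *not* a cardiovascular
model. `generate_rr_cmv()`/`generate_rr_bvv()` emulate the two ventilation
signatures — a single sinusoidal RR modulation near 1 Hz versus band-limited
(0.5–1.5 Hz) Gaussian modulation of matched power, with beat times
accumulated self-consistently. `generate_synthetic_ecg()` (Gaussian QRS
bumps plus drift and noise) exists as ground truth for the R-peak detector.
None of these reproduce ectopy, detection artifacts, non-stationary
coupling strength, or autonomic drift; passing the synthetic-data tests
demonstrates that the measures track periodicity and bandwidth as designed,
not that they are artifact-proof on clinical recordings.

## Known limitations

* **SE.ACF at long artificial periods.** With the tolerance fixed at 0.4×SD,
  the sample entropy of a *clean sinusoidal* ACF is near zero only when the
  embedding delay lands at the exact quarter period; at long periods
  (≳14 lags) mirror-proximal template pairs inflate it to ~0.2. Oscillator
  and rodent ACF periods (~5 lags) are unaffected, but SE.ACF values on
  slowly modulated series should be compared only within a protocol.
* **Monotonicity of SE.ACF.** Across master seeds the benchmark yields
  M(SE.ACF) around 0.90: the measure rises smoothly with `C` and with small
  inter-realization spread, so the rank-sum test separates even low-noise
  levels. A SampEn implementation with coarser conventions (e.g. a much
  shorter ACF span) saturates near zero at low `C` and scores lower; this
  sensitivity to convention is inherent to the statistic, which is why the
  package reports it as computed instead of adopting a convention chosen for
  its output.
* **DFA at small boxes.** Over boxes 4–16 the log–log slope of white noise
  is biased above the asymptotic 0.5 (the exact finite-size fluctuation is
  `E[F²(s)] = σ²(s²−4)/(15 s)`, slope ≈ 0.59 over those scales); α₁ values
  should be compared against this finite-size behaviour, not against 0.5.
* **Peak detection** assumes a dominant, upright R wave; the adaptive
  threshold (8× rolling median of the squared band-passed signal, floored at
  5% of the global maximum) is designed for clean rodent leads, not for
  morphology classification.

## Problem sizes used in the test suite

The shipped tests validate oracle equivalences at n ≤ 500 (double-loop ACF,
O(n²) SampEn, direct Lomb-Scargle evaluation), run the full ensemble
benchmark once (21 × 20 signals of 500 samples, ~20 s), calibrate the
rank-sum type-I rate on 2000 null pairs, and contrast 20 seeded pairs of
matched narrowband/broadband fixtures of 600 beats each. These sizes were
chosen so the whole suite completes in well under a minute while every
statistical bound retains comfortable margins.
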