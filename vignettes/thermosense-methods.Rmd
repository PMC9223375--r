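---
title: "Modelling thermal sensation from physiological signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thermal sensation from physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermosense)
```

## The problem

Indoor climate control traditionally predicts occupants' thermal comfort
with Fanger's predicted mean vote (PMV), a steady-state heat-balance index
computed from four environmental quantities (air temperature, radiant
temperature, air speed, humidity) and two personal ones (metabolic rate,
clothing insulation). PMV describes the *average* vote of a population;
it knows nothing about the individual in the room. Wearable sensors make
an alternative possible: predict an individual's thermal sensation (TS,
the ASHRAE 7-point scale from -3 cold to +3 hot) directly from
physiological signals — ECG, EMG, EEG, skin conductance and skin
temperatures — together with the measured environment.

`thermosense` implements that modelling pipeline end to end: a seeded
simulator of a climate-chamber cohort, extraction of a 22-feature set from
raw traces, a two-stage greedy wrapper that selects a predictive feature
subset for an interchangeable regression backend, and an evaluation suite
that scores the fitted model against a from-scratch PMV baseline.

## The synthetic cohort

No public dataset exists for this class of chamber study, so the package
ships a generative model of one, used both as the test bed for every
downstream stage and as the default input of the pipeline.

**Design.** Twenty subjects (9 male, 11 female), each exposed once to all
eight cells of a 2x2x2 factorial: air temperature 23/27 degC, relative
humidity 60/80 %, ceiling-fan level breeze/strong. Fan levels map to air
speeds of 0.3 and 0.9 m/s — values in the typical ceiling-fan range and
inside the PMV formula's validity domain. Each trial yields 6 minutes of
raw traces (the final 5 minutes are analysed; the acclimatisation period
of a real protocol is not simulated because the generated signals are
stationary conditional on the sensation state, so extra unanalysed
minutes would add runtime and nothing else — a 15-minute protocol is
available via `duration`).

**Latent sensation.** Each trial's latent TS is linear in the environment
with a Gaussian subject offset and trial noise:

$$\mathrm{ts} = 0.35\,(T_a - 25) + 0.6\,(v - 0.6) + \beta_\mathrm{rh}\,(\mathrm{RH} - 70)
  + b_\mathrm{subject} + \varepsilon,$$

with $b \sim N(0, 0.5^2)$ and $\varepsilon$ of total SD about 0.7. The
reported vote rounds the latent value half-away-from-zero and clips it to
\[-3, 3\]. The coefficient signs follow the associations such chamber data
show; notably the wind coefficient is *positive*, reproducing the observed
(counter-intuitive, likely confounded) positive wind-TS association in
this study class rather than the heat-balance expectation. The humidity
coefficient defaults to zero: a 60 vs 80 %RH contrast at these
temperatures is below sensation resolution, which is also what the
emulated study class concludes about its own RH setpoints.

**Pathway decomposition.** A single shared latent factor would make every
physiological feature a redundant readout of the same quantity, which is
not how multi-signal sensation models behave: each modality indexes a
distinct part of the response (shivering and postural muscle activity,
autonomic balance, central arousal). The generator therefore splits
$\varepsilon$ into three pathway components plus a residual
($\mathrm{SD}s$ 0.45 EMG, 0.35 ECG, 0.35 EEG, 0.25 residual). The EMG
responds to the core state plus its own pathway, the HRV features to the
core plus the autonomic pathway, the EEG beta band to the core plus the
arousal pathway, while skin temperatures and GSR read only the core
state. Each informative signal class therefore carries information no
other class can substitute, while GSR remains a noisy, redundant readout
— matching its observed dispensability in sedentary conditions.

**Signal synthesis.** All traces are phenomenological:

* **RR series** — `RR(t) = m + A_LF sin(2*pi*0.10 t) + A_HF sin(2*pi*0.30 t) + jitter`,
  amplitudes solved so the SD equals the prescribed SDNN (50 ms at
  neutral, falling 4 ms per TS unit) and the LF/HF band-power ratio
  equals the "smile curve" `1 + 0.4 ts^2` — low when neutral, high when
  hot or cold, the canonical nonlinearity of thermally stressed HRV.
* **EMG** — zero-mean noise with amplitude `0.05 * exp(-0.3 ts)` mV:
  more muscle activity when cold (shivering, posture adjustment).
* **EEG** — band-limited alpha (8-13 Hz, fixed RMS 10 uV), beta
  (13-30 Hz, RMS `6 * (1 + 0.15 ts)` uV) and a 1-40 Hz broadband floor.
* **GSR** — tonic level `4 - 0.3 ts` uS plus slow (<0.5 Hz) drift.
* **Temperatures** — site baselines 36.0/34.0/33.5 degC with TS slopes
  0.10/0.20/0.25 degC per unit (chest least environmentally exposed,
  calf most) plus a slow AR(1) wander.

Per-subject log-normal gains and per-trial level noise keep features
realistically noisy; the per-trial SDs were chosen once so that the
feature-TS correlation magnitudes fall in the weak-to-moderate range such
studies report, with the EMG the strongest physiological readout.

**Attrition.** Real chamber data lose many trials to sensor artefacts,
and one impaired signal voids the whole trial. With probability 0.4375 a
trial has one modality corrupted (flatline, clipping, or added broadband
noise at 0 dB), so about 90 of 160 trials survive — the attrition level
the emulated study class reports. The quality screen must *detect* these
corruptions; nothing downstream reads the generator's flags.

**What the simulator does not capture.** Responses are phenomenological,
not thermoregulatory physiology: no real ECG morphology (the RR series is
generated directly), no EEG artefact taxonomy, no slow adaptation within
a trial, no inter-feature correlations beyond the latent structure.
Passing tests on this cohort demonstrate that the pipeline recovers
planted structure faithfully; they cannot certify performance on human
data.

## Feature extraction

All features are computed on the trailing 5-minute window. Band edges the
study class leaves unstated use conventional definitions: EEG alpha 8-13,
beta 13-30, broadband 1-40 Hz; EMG band-pass 20-450 Hz (high-pass only
when the sampling rate cannot support the upper edge); HRV LF
0.04-0.15, HF 0.15-0.4 Hz with total power over 0.003-0.4 Hz, so the
relative LF and HF powers sum to at most 1 without being trivially
complementary. Filters are zero-phase (forward-backward Butterworth),
and one second is trimmed from each end of filtered windows before
statistics to suppress edge transients.

The HRV spectrum comes from the RR tachogram cubic-spline resampled to
4 Hz, then a Hann-windowed averaged periodogram with 120-s segments and
50 % overlap — standard short-term HRV practice. EEG band "averages" are
mean absolute amplitudes of the band-pass filtered window; the broadband
mean absolute amplitude (`EEG_AVG`) is used rather than a raw mean, which
would be ~0 after any high-pass filter and could not carry information.
Degenerate inputs are signalled, not silently imputed: a constant RR
series yields `SDNN = 0` with the spectral fields `NA`; a zero EEG window
yields zero amplitudes and `NA` relative powers.

The quality screen applies three per-modality checks: *flatline*
(variance below 1e-12 in at least half of the 1-s chunks), *clipping* (at
least 10 % of samples within 0.1 % of the range from either extreme), and
*low SNR* (power outside the modality's physiological band exceeding 25 %
of in-band power — calibrated so clean synthetic traces sit well below
and 0 dB broadband corruption well above the threshold). Any failing
modality fails the trial, as in the emulated protocol; failed trials are
dropped, never repaired.

## The selection engine

The wrapper has two stages operating on cross-validated RMSE:

1. **Feature increment.** Starting from empty overall-best (`S_best`) and
   stepwise-best (`T_best`) sets, each round evaluates `T_best + {f}` for
   every unselected feature, moves `T_best` to the best candidate, and
   accepts it as the new `S_best` while it *strictly* improves; the first
   non-improving round ends the stage.
2. **Redundant-feature removal.** Starting from `T_best = S_best`, each
   round evaluates all single-feature deletions and moves to the best;
   improvements update `S_best` and reset a worse-step counter, while a
   non-improving round increments it and the search continues once from
   the worse `T_best` — the second consecutive non-improving step since
   the last update terminates. The grace-step round re-expands from the
   *current* (worse) `T_best`, not from `S_best`.

The inner performance estimate — unstated in the study class this
reproduces and therefore the largest open design choice — is 5-fold
cross-validation with 3 repeats under a fixed seed, pooled per-repeat
RMSE averaged over repeats, with out-of-fold R² reported alongside. Fold
assignments depend only on the protocol seed, so all candidate subsets in
a round are compared on identical splits (paired comparisons). Ties
break toward the earlier candidate in the declared feature order, making
the whole procedure bit-reproducible. The protocol object is pluggable
for anyone wanting alternatives.

Backends: ordinary least squares; Gaussian process regression with a
squared-exponential kernel (median-heuristic width) and a noise term
chosen by maximising the log marginal likelihood over a variance grid;
epsilon-SVM regression with a radial kernel (epsilon 0.1); and a
depth-5 regression tree. Kernel methods standardise features with
training-fold statistics; tree and linear fits see raw values. The empty
feature set is always evaluated as the mean predictor and anchors the
selection baseline.

A caveat worth stating plainly: with ~90 samples and 22 candidate
features, greedy wrapper selection overfits the selection criterion.
Adding an uninformative feature changes the cross-validated estimate by a
small, data-dependent amount whose sign is close to a coin flip, and a
round only stops when *no* candidate improves, so spurious late
acceptances (most often the near-null humidity factor) occur in a
substantial fraction of simulated cohorts. This is a property of the
procedure at this sample size, not of the implementation; the stability
checks in the test suite measure it rather than hide it.

## The PMV baseline

`pmv()` implements the Fanger heat-balance equation set directly: water
vapour pressure from the standard saturation formula, clothing-surface
temperature solved by damped fixed-point iteration (averaged consecutive
iterates, tolerance 1e-4 degC, at most 150 iterations, iteration counts
reported), then the six heat-loss components and the sensation
coefficient. Values are deliberately *not* clipped to the nominal ±3
scale: clipping would silently shrink the baseline's error in the cold
chamber cells and flatter the comparison. `pmv_for_trial()` applies the
benchmarking conventions: radiant temperature equal to air temperature
(uniform chamber), 1.0 met, 0.5 clo.

The implementation agrees with an independently written reference
implementation of the same standard to within ±0.01 PMV over a 405-point
grid spanning 18-32 degC, 30-70 % RH, 0.1-0.9 m/s, 0.5-1.0 clo and
1.0-1.6 met (frozen in the test suite).

## Evaluation protocols

* `correlation_table()` — Pearson r of every feature against reported
  TS with exact two-tailed t-distribution p-values and 0.05/0.01 stars.
* `compare_with_pmv()` — repeated random 72/18 train/test splits (three
  by default); the backend is retrained per split on the selected
  features, PMV is scored untrained on the same test rows, and
  out-of-sample RMSE and R² (`1 - SS_res/SS_tot`, possibly negative) are
  averaged.
* `gender_error_test()` — gender-stratified split, signed test-set
  errors, pooled-variance two-sample t-test (Welch behind a flag) and
  Mann-Whitney U with tie-corrected normal-approximation Z (exact
  enumeration behind a flag for small untied samples). When a cohort
  cannot supply the classic 40/32 + 10/8 split, 20 % of each gender is
  held out.
* `rank_signals()` — greedy forward addition of whole signal-wise
  feature groups starting from the environment-only model, ranking
  signals by their marginal value; ties resolve in declared group order.

## Problem sizes and reproducibility

Every stochastic step descends from one root seed through named child
streams (per subject, trial, modality), so any modality can be
regenerated independently and equal seeds give byte-identical cohorts.
The test suite exercises the full default cohort (20x8 trials at
1 kHz EMG / 256 Hz EEG) once; multi-seed stability checks use a reduced
profile (330-s traces, 500 Hz EMG, 128 Hz EEG, 16 Hz GSR) that preserves
the statistical structure of every feature while keeping ten full
pipeline replicates tractable on a single CPU. The vignette and README
report only quantities the tests and `scripts/acceptance.R` actually
compute.

## Known limitations

* The generator's response shapes are linear (quadratic for LF/HF) and
  stationary; real signals drift, adapt and interact.
* The wrapper's stopping rules are faithful to the two-stage design but
  statistically fragile at n = 90 (see above); selected sets vary across
  cohorts, and occasional retention of near-null features is expected.
* PMV is implemented in its plain form; tool dialects with
  elevated-air-speed adjustments will differ slightly for the strong-fan
  cells.
* The Mann-Whitney normal approximation is reported for consistency with
  common statistical-software output even at test-set sizes (10 + 8)
  where the exact test would be preferable; the exact flag exists.
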