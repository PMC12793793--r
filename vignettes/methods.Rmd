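---
title: "Quantifying infant frontocentral band activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infant frontocentral band activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thetamod)
```

## The measurement problem

During the first year of life, frontocentral theta-band activity (3--6 Hz
in infants, lower than the adult 4--8 Hz convention) is thought to track
engagement of attention and memory systems. When an infant watches a
novel video, theta power tends to *rise* over the course of viewing.
`thetamod` quantifies this with three indices computed from continuous
EEG over the frontocentral region of interest (F3, Fz, F4, FC3, FCz,
FC4):

* **Absolute band power** --- the power spectral density (PSD) is
  log-transformed per channel and frequency bin, averaged over the ROI
  channels, and integrated over the band. Log-then-average ordering is
  deliberate: averaging log-spectra weights channels multiplicatively and
  is the convention in the infant-EEG literature this package follows. The result is in
  log-power units (the descriptive tables label it μV², but values near 9
  with an SD near 1 are only consistent with a log-domain band integral;
  both orders are implemented, log-then-integrate being the default).
* **Relative band power** --- linear ROI-averaged band power divided by
  linear total power over 1--45 Hz; a dimensionless fraction in (0, 1).
  No log transform enters this ratio.
* **Modulation index** --- the Pearson correlation between per-second
  band power (clean, non-overlapping 1-s segments) and time. Positive
  values mean power rose over stimulus viewing. The default time basis is
  each retained segment's chronological onset; a `retained_rank` mode
  numbers the retained segments consecutively instead, because "segment
  number" is ambiguous when segments have been rejected in between.

The same machinery is applied to the infant alpha band (6--9 Hz) as a
specificity control. Both bands include the shared 6 Hz bin under the
default inclusive-endpoint rule, following the printed band ranges
literally; a half-open mode drops the upper edge bin.

## Preprocessing

Only the stages the indices depend on are implemented:

1. **Band-pass filter**: zero-phase Hamming-windowed sinc FIR, cut-offs 1
   and 100 Hz. The convention fixes the window and cut-offs but not
   the order; we use transition widths of 1 Hz (low edge) and 10 Hz (high
   edge), giving an order of ~1650 at 500 Hz, applied by FFT convolution
   with the group delay compensated. Passband ripple is below 0.5 dB
   between 2 and 90 Hz (verified by test).
2. **Segmentation**: 1-s epochs; a non-overlapping stream for the
   modulation path and a 50%-overlap stream for the Welch PSD path.
3. **Amplitude rejection**: any epoch with any sample outside ±150 μV on
   any channel.
4. **Gaze rejection**: any epoch whose `[onset, onset+1)` window overlaps
   a coded look-away interval. Interval files use half-open second-based
   semantics, so boundaries are never double-counted. The strictest
   reading ("any overlap rejects") is the default; a minimum-overlap
   fraction is configurable.
5. **Inclusion gate**: at least 10 clean non-overlapping segments, or the
   recording contributes no indices.

Upstream artifact-correction stages of full preprocessing suites (wavelet
thresholding, bad-channel interpolation, joint-probability rejection,
line-noise regression) are intentionally out of scope; synthetic inputs
are clean apart from threshold-detectable transients, so amplitude
rejection carries the full load. Average re-referencing is exposed as an
optional flag (`average_reference`) but is a near no-op for ROI-mean band
contrasts and defaults to off.

A design point published pipelines leave open: how 50%-overlap PSD epochs
interact with rejection. We cut overlap windows only *within contiguous
runs* of kept non-overlapping segments, so no Welch window spans a splice
discontinuity (a run of m clean seconds yields 2m−1 windows). The
alternative order --- cut all overlap windows first, then reject --- is
available behind `overlap_after_selection = FALSE`.

## Spectral estimation

`compute_psd()` averages Hamming-windowed one-sided periodograms over the
kept epochs (Welch). With 1-s windows the grid is 1 Hz. Scaling is
density (μV²/Hz) with window-energy correction, so the integrated PSD of
a stationary signal equals its variance; a 60-s, 10 μV tone at 4.5 Hz
integrates to A²/2 = 50 μV² over 3--6 Hz within 5% (the trapezoid rule
on the 1-Hz grid loses about 1% to half-weighted edge bins; a
rectangular-sum mode exists and the difference on constant spectra is a
fixed known factor). "Integrating" the PSD is read as the trapezoid rule;
this is a convention, and every acceptance property is stated so that it
holds for either rule.

Degenerate inputs are errors, not silent values: zero kept epochs, zero
PSD inside a band under the log transform, zero total power in the
relative-power ratio, constant series or fewer than 3 segments for the
modulation correlation.

## Reliability and stability

* **Split-half reliability**: the retained clean segments are split by
  the *parity of their position in the retained sequence* (not the
  original second number), which guarantees near-equal half sizes under
  arbitrary rejection patterns. Each half's modulation index uses each
  segment's own time value. Halves need ≥3 segments each.
* **ICC**: two-way single-measure intraclass correlation from the
  classical mean-squares decomposition, with F-based 95% confidence
  intervals (Shrout--Fleiss / McGraw--Wong construction). Reliability reports in this literature often omit the ICC form, so the
  form is a configuration enum; the default is absolute agreement, with consistency available.
  No Spearman--Brown step-up by default (raw ICC CIs are reported);
  the correction is available as an option. No bootstrap CIs --- F-based
  only, matching the cited approach.
* **Stability**: Pearson correlations between 6- and 12-month indices on
  complete pairs (df = n−2), paired t-tests for group-level change, and a
  mixed-model ICC: a random-intercept model `value ~ timepoint +
  (1 | subject)` fitted by REML (lme4), with ICC =
  σ²_subject/(σ²_subject + σ²_residual). Timepoint enters as a fixed
  effect so systematic 6→12-month growth does not deflate the ICC; on
  balanced data this reproduces the consistency-form pairwise ICC, which
  is how the two stability numbers (Pearson r ≈ mixed ICC) can agree.
  Boundary variance estimates (σ²_subject → 0) are reported as ICC 0
  with a `boundary` flag, never hidden.

## Outcome prediction

Composite standardized scores average each subject's within-timepoint
z-scores over the timepoints with valid EEG; a subject with one valid
timepoint keeps that timepoint's z-score, and a subject with none gets a
missing composite. The language outcome is the mean of the available
z-scored questionnaire subscales (expressive vocabulary, syntax,
morphology).

Model selection is stepwise (both directions) on AIC with
`AIC = n·ln(RSS/n) + 2(k+1)` --- the same convention as `stepAIC`'s
`extractAIC`, against which the implementation is cross-checked, along
with an exhaustive all-subsets oracle. The search starts from the full
model (age at outcome plus the three band composites), evaluates every
single-predictor addition and deletion at each step, takes the lowest
AIC, and stops when no move lowers it. Listwise deletion is fixed at the
full candidate set *before* the search so every visited model shares the
same n. Exact ties prefer deletion (parsimony), and among tied deletions
the largest-p predictor is dropped --- under continuous data exact ties
have probability zero, so this matters only for pathological inputs.
Standardized β, t-based 95% CIs, F, R², adjusted R² and VIFs
(1/(1−R²_j)) are reported numerically, with no significance labels: significance labels
for p ≈ 0.04--0.06 vary by author, so labeling is left to the reader. A separate-timepoint variant (6- and
12-month predictors instead of composites) is available via
`use_composites = FALSE`. Demographic covariates are not modeled.

## What the generator emulates --- and what it does not

`simulate_recording()` builds: a 1/f^χ Gaussian background (synthesized
in the frequency domain, χ = 1, 15 μV RMS by default); narrowband
oscillations as band-limited Gaussian noise multiplied by a linear
envelope `base + slope·t` (a pure-sinusoid carrier is retained for
closed-form oracles); and Poisson-placed 200-ms raised-cosine transients
(2/min, 300 μV) guaranteed to trip the ±150 μV rule. Defaults emulate
a typical infant viewing study: 134-s viewing at 500 Hz, theta at 4.5 ± 1.5 Hz
with a 6 μV envelope rising 0.03 μV/s, weaker alpha at 7.5 Hz, the
six-channel ROI plus two occipital distractor channels. Artifact
parameters are conventions, not calibrated to any cohort: recorded artifact mixes are not
characterized quantitatively in this literature.

`simulate_gaze()` alternates look/look-away bouts with exponential
lengths (3-s mean away bouts; the look-bout mean is set so the long-run
away fraction hits its target, 0.2 by default), starting from the
stationary state distribution so realized fractions are unbiased.

`simulate_cohort()` draws, per subject and index,
`z_t = √ρ·trait + √(1−ρ)·ε_t`, so the complete-case cross-age
correlation of every index equals ρ (0.4) exactly in expectation --- the
√ρ loading makes the stability tests analytic. The cognitive outcome is
`β_comp·composite + β_age·age_z + noise` on the standardized scale
(β_comp = 0.2, β_age = 0.2 by default, matching effect sizes reported for comparable cohorts);
selective attention is pure noise and language loads only on age, which
mirrors the reported selection results structurally. Index means and SDs
default to descriptives published for comparable infant cohorts for theta, with analogous
invented values for alpha. Per-stage missingness (30% 6-month EEG, 35%
12-month EEG, 17% outcomes) reproduces the attrition pattern. Every
subject's draws come from an id-keyed substream, so enlarging a cohort
never changes existing subjects.

`simulate_study()` ties the two levels together so the raw-signal
pipeline can recover cohort-level effects. Each index receives its own
physical handle: an overall EEG gain `G = exp(0.35·z_abs)` multiplies
oscillation and background alike (as overall scalp-EEG amplitude
differences do) and therefore moves absolute power without moving the
relative-power ratio; the oscillation-to-background amplitude ratio
`R = exp(0.3·z_rel)` carries relative power and cancels out of `G`; and
the envelope ramp scales with the modulation z. With these choices the
derived composites inherit approximately the independent-trait structure
the prediction stage assumes (a residual correlation of ~0.6 between
derived absolute- and relative-power composites remains, because the
log-domain band integral cannot fully separate the two axes). The
between-subject spread this produces (absolute-power SD ≈ 0.9 log units)
matches those published descriptives.

What the generator does **not** emulate: volume conduction or any head
model, event-locked responses, line noise, slow drifts, channel-specific
artifacts, non-Gaussian background, or aperiodic-exponent differences
between subjects. Passing tests therefore show that the *estimators and
statistics* behave as specified under their stated assumptions --- not
that real infant EEG satisfies those assumptions.

## Problem sizes and numerical choices

The verification suite uses the scales the analyses themselves imply:
spectral oracles on 60--100 s of signal; modulation sign recovery over
100 simulated recordings (plus 200 flat-envelope controls); split-half
CI coverage over 500 replicates at n = 98; mixed-model ICC recovery over
200 replicates at 68 × 2; stability recovery over 500 cohorts at n = 68;
stepwise-vs-exhaustive agreement over 200 random datasets with four
candidates; and the end-to-end detection check over 20 seeded studies of
30 subjects × 2 timepoints with β_comp = 0.5 and no attrition, each a
complete simulate → EDF → preprocess → index → predict run.

Numerical conventions collected in one place: log base 10 (natural log
configurable; all acceptance properties are base-invariant); trapezoid
band integration with inclusive endpoints; Hamming windows on both the
PSD and the per-segment path; EDF samples quantized to 16 bits over each
channel's observed range; FIR filtering at an FFT length padded to a
highly composite size; REML with singular-fit checks relaxed and
boundary estimates flagged rather than suppressed.

## Known limitations

* The absolute-power unit question (log-domain integral labeled μV²) is
  resolved by implementing both orders and defaulting to the one
  consistent with the printed descriptives; no ground truth exists.
* Mixed-model ICC confidence intervals are not provided (the pairwise
  F-based intervals are); profile-likelihood intervals for variance
  ratios would be the natural extension.
* The end-to-end detection check at n = 30 sits near the power boundary
  of its own design (a cohort-level ceiling of ~0.86 at β = 0.5), so it
  is the least robust of the acceptance properties by construction.
* BrainVision support covers the Core subset (binary float/int16 and
  ASCII, multiplexed or vectorized); exotic dialects are rejected with
  explicit format errors rather than guessed at.
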