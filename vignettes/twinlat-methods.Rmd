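---
title: "twinlat: models, pipeline and design choices"
author: "twinlat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{twinlat: models, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinlat)
```

This vignette is the package's own account of its science: the signal
pipeline that turns bilateral Doppler velocity recordings into laterality
phenotypes, the twin variance-decomposition models fitted to them, and the
choices made where the methodology is genuinely open.

## 1. The fTCD laterality pipeline

A functional transcranial Doppler (fTCD) session records blood-flow
velocity in the left and right middle cerebral arteries while the
participant repeatedly performs a language task. Each trial has a silent
viewing period (about 12 s), a cue to speak, and a speaking period (about
10 s). The laterality index (LI) summarises how much flow increases on the
left relative to the right during speech.

### Preprocessing (`preprocessRecording`)

1. **Brief dropout interpolation.** A sample is a dropout when its value is
   at or below the dropout threshold (default 0 cm/s: velocity is strictly
   positive physiologically). An isolated dropout is replaced by the mean
   of its flanking samples. Runs of two or more dropout samples cannot be
   repaired credibly; they are flagged, and any trial whose epoch contains
   one is later rejected with reason `prolonged_dropout`.
2. **Heart-cycle integration.** Cardiac pulsatility dominates the raw
   trace. Heartbeats are detected as peaks of the summed left+right
   channel with a minimum inter-beat interval of 0.33 s (admits heart
   rates up to ~180 bpm — a single robust knob for child recordings).
   Peak positions are refined to sub-sample precision by parabolic
   interpolation, so each cycle spans one full cardiac period regardless
   of sampling phase. Each cycle is replaced by its time-weighted
   (trapezoidal) mean, assigned to the cycle midpoint, and resampled to
   the original grid with a natural cubic spline. Cubic rather than
   linear resampling matters: linear interpolation systematically shaves
   the curvature of the slow evoked response and biases the
   period-of-interest mean by a couple of percent. Integration preserves
   each channel's overall mean to within 0.5%.
3. **Normalisation.** Each channel is rescaled so its recording-wide mean
   is 100; all later quantities are in percent units, making recordings
   comparable across probe gain and insonation angle (the pipeline is
   exactly invariant to channel gain, and a test asserts this).

### Epoching, rejection, baseline correction (`epochAndReject`)

One epoch per cue, spanning `epochWindow` (default −12 to +18 s; wide
enough for the viewing and speaking periods with margin — the study
design does not fix these limits, so they are configurable and recorded
in the output provenance). Trials are rejected, with a reason, when they
contain a prolonged dropout, any normalised sample outside
`artifactBounds` (default 60–140%, conventional fTCD practice), or a
behavioural invalidity flag supplied by the examiner (the pipeline takes
this as a per-trial boolean; it does not score speech itself). Accepted
epochs are baseline-corrected per channel by subtracting the channel mean
over `baselineWindow` (default −5 to 0 s, the late silent-viewing
interval), making each accepted channel's baseline mean exactly zero.

### Laterality indices (`computeTrialLI`, `summarizeSubject`)

For each accepted trial, the difference wave is left minus right. The
**mean-based LI** is its mean over the period of interest (POI, default
4–14 s after the cue). The **peak-based LI** finds the sample in the POI
with the largest |difference| (exact ties go to the earliest sample — a
deterministic, order-independent rule) and averages the difference over a
2 s window around it, truncated at the POI edges. Both share the sign
convention positive = left-lateralised.

The subject's LI is the mean of accepted per-trial LIs; its standard
error is the trial SD divided by √n, and the confidence interval uses the
Student-t quantile with n−1 df (trial counts are small, 12–30, so a
normal quantile would be anticonservative). Because each trial LI is the
POI mean of that trial's own baseline-corrected difference, the subject
LI equals, by linearity, the LI of the averaged difference wave whenever
all trials are accepted — both views are therefore available and their
equivalence is a documented identity rather than a choice.

Categories: `left` when the CI lies above zero, `right` below,
`bilateral` when it spans zero. The binary `typical`/`atypical` code uses
the **peak-based** CI: typical only when it lies entirely above zero
(atypical collects CIs spanning or falling below zero). Subjects with
fewer than 12 accepted trials are excluded (`too_few_trials`); a
single-pass 5 SD rule flags sample-level outliers on the mean-based LI
(single-pass, not iterated, mirroring how such screens are applied in
practice; pair-level propagation is done when the twin table is built).
Odd/even half-sample LIs (accepted trials in presentation order) feed the
split-half reliability, reported both raw and Spearman–Brown corrected —
the corrected value is labelled, never silently substituted.

## 2. Handedness phenotypes

The Edinburgh Handedness Inventory is scored over 10 demonstrated
actions: 1 point for exclusive right-hand use, ½ for either hand, 0 for
left (range 0–10). The Quantification of Hand Preference task is scored
over 21 card trials (3 at each of 7 positions): 2 points for right-handed
use, 1 for a between-hand transfer, 0 for left (range 0–42). Missing
items are prorated to the full scale and flagged — proration keeps the
scale range comparable while marking the score as partly imputed.

## 3. Twin variance decomposition

For a pair with phenotypes \((x_1, x_2)\), the ACE model implies a
bivariate normal with common mean \(\mu\) and variance \(v\), and
within-pair correlation \(a^2 + c^2\) (MZ) or \(\tfrac12 a^2 + c^2\)
(DZ). `fitUnivariate` maximises the exact bivariate-normal log-likelihood
with a single mean and variance across twin order, zygosity and sex (the
study-style means model; age/sex effects can be residualised upstream).
The familial parameterisation \(p = a^2+c^2\), \(q = a^2/p\) with box
constraints keeps all components non-negative and their sum at most one
without penalties, and lets boundary estimates land exactly on 0 — which
is common in laterality data and is reported as exactly 0, not 1e-9. The
bounded quasi-Newton optimiser runs from five fixed start points to guard
against boundary-induced local optima; this is deterministic, with no
RNG involvement.

- **Model comparison** uses the likelihood-ratio chi-square with df equal
  to the parameter-count difference. The null value of a variance
  component sits on the boundary of its space, so the asymptotic null is
  really a 50:50 mixture of \(\chi^2_0\) and \(\chi^2_1\); the standard
  \(\chi^2_1\) reference is the default (the convention of mainstream
  twin software), with the mixture behind `mixture = TRUE`.
- **Profile-likelihood intervals** collect all component values whose
  profile deviance is within the \(\chi^2_1\) quantile, truncated to
  [0, 1]; when the boundary is inside the interval the lower limit is
  reported as 0. Simulated coverage at the study's sample sizes is close
  to nominal (a test asserts 92–98% at n = 96/98, a² = 0.25).
- **Twin correlations** are reported three ways: the ML intraclass
  correlation under the equal-means bivariate normal (primary, with a
  profile CI), and double-entry Pearson and Spearman correlations,
  each labelled. Which convention published tables use is often unstated;
  emitting all three makes comparisons explicit.

### Trivariate Cholesky AE model

For three phenotypes per twin, `fitCholeskyTrivariate` fits
lower-triangular A and E path matrices; the cross-twin A covariance is
scaled 1 (MZ) / 0.5 (DZ). Pairs with partly missing phenotypes contribute
their observed blocks (full-information likelihood, grouped by
missingness pattern for speed). Phenotypes are standardized internally,
so reported paths are unsquared standardized estimates with the identity
\(\sum_j A_{ij}^2 + \sum_j E_{ij}^2 = 1\) per trait (enforced by the
class validity check). Standard errors come from the observed information
matrix by the delta method; factor signs are normalized so diagonal paths
are non-negative (paths are otherwise identified only up to column
sign). Opposite-sex DZ pairs are pooled with same-sex DZ pairs.

## 4. Extremes analysis

`extremesTTest` selects probands past a cutoff and compares cotwin scores
between MZ and DZ groups with a Welch t-test (Satterthwaite df). Under a
genetic aetiology of the extreme, MZ cotwins regress less to the
population mean. Cutoffs are caller-supplied parameters
(`extremesDefaultCutoffs()` suggests EHI ≤ 4/10, QHP ≤ 14/42, LI < 0) and
are always echoed in the result — they are conventions, not estimates.

Two proband conventions are provided. Under **double entry** (default), a
pair in which both members qualify contributes both as probands. This
matches the symmetric treatment of twin data, but it has a measurable
cost for inference: the two cotwin values contributed by a both-extreme
pair are mutually conditioned (each appears because its partner scored
past the cutoff, and in a both-extreme pair the partner is itself
extreme), giving a positive within-pair covariance and an
anticonservative Welch test — simulation at a² = 0 puts the type-I error
near 10% rather than 5% at moderate cutoffs. The **single-entry**
variant (`singleEntry = TRUE`, keeping each pair's more extreme member)
has nominal size (a test asserts ~5% over 1000 null replicates).
Descriptive tables are fine under either convention; p-values should be
read from the single-entry variant or interpreted cautiously.

## 5. Power analysis

`powerAE` computes the power of the AE-vs-E likelihood-ratio test. For
the noncentral-χ² method, the implied MZ and DZ covariance matrices are
built under the generating model (standardized, since power depends only
on the variance proportions), the E-only model is fitted to them by
minimising the combined ML discrepancy
\(F_g = \ln|\Sigma_0| - \ln|\Sigma_g| + \mathrm{tr}(\Sigma_g
\Sigma_0^{-1}) - 2\), and the noncentrality is \(\lambda = n_{MZ} F_{MZ}
+ n_{DZ} F_{DZ}\) (for this model the best-fitting E variance is exactly
the population variance, so \(\lambda = \sum_g n_g \{-\ln(1-r_g^2)\}\)).
Power is the upper-tail probability of \(\chi^2_1(\lambda)\) beyond the
central 95% point. The Monte-Carlo method simulates twin samples, runs
the LRT, and counts rejections; both methods agree within Monte-Carlo
error (tested), and at a² = 0 the ncp method returns exactly the nominal
size. The standard \(\chi^2_1\) reference is the default; the boundary
mixture (`mixture = TRUE`) lowers the critical value and raises reported
power, and under the null its size remains at the nominal level because
the halved tail mass compensates the lowered critical value.

## 6. The synthetic-data generators

The generators define the conditions under which the pipeline and models
are validated; they are first-class, tested code.

**Twin phenotypes** (`simulateTwinPhenotypes`): per pair, an additive
genetic factor correlated 1 (MZ) / 0.5 (DZ) across twins, a fully shared
C factor, independent E; the phenotype is \(\sqrt{a^2}A + \sqrt{c^2}C +
\sqrt{e^2}E\) on a unit-variance latent scale. The `jshape` marginal maps
the latent value through a fixed, strictly monotone quantile map
\(y = 10\,F^{-1}_{Beta(4,\,0.8)}(\Phi(z))\) onto a 0–10 handedness-like
scale with most mass near the right-handed end. The map's constants are
frozen (changing them is a versioned change) and, being strictly
monotone, it preserves all rank-based familial structure — tested via
Spearman twin correlations.

**fTCD sessions** (`simulateDopplerSession`): a continuous two-channel
trace with cardiac pulsatility (sharp systolic peak plus diastolic
shoulder, beat-to-beat heart-rate jitter around 95 ± 8 bpm, the child
range), slow AR(1) drift, white noise, and a per-trial evoked response: a
gamma-shaped activation curve rising after the cue, peaking near 7 s and
returning to baseline by 17 s — a shape on which the mean- and peak-based
LIs genuinely differ — scaled so its mean over the 4–14 s POI is exactly
one. The response enters as a bilateral flow increase common to both
channels plus a lateralised differential. Because the true LI is defined
on the pipeline's *normalised* scale, the generator solves for the raw
modulation coefficient \(u = w/(1 - w\bar g)\) that makes the normalised,
baseline-corrected response coefficient exactly \(w\); without this
correction the bilateral component couples with mean-100 normalisation
and biases the recovered LI by about 2%. Noise-free sessions recover the
injected LI within 1% (tested), the residual coming from cycle
integration acting as a mild low-pass filter.

Dropouts (runs of zeroed samples), high-amplitude artifacts (a 1 s ×1.65
excursion — long enough to survive cycle integration and exceed the 140%
bound) and behaviourally invalid trials are injected with per-trial
probabilities, mutually exclusive per trial, and logged; tests assert
that pipeline rejections match the log exactly, reason by reason. Trials
are spaced 33 s apart so that −12..+18 s epochs never overlap; the
generator refuses closer spacing.

**What the generators do not emulate:** physiologic vasomotion
oscillations and respiratory coupling, probe-motion transients with
realistic spectra, asymmetric insonation quality between channels,
heart-rate responses to task engagement, and any dependence of signal
quality on age or behaviour. Passing tests therefore demonstrate
correctness of the computations under a faithful but idealised signal
model, not robustness to every artefact of real paediatric recordings.

## 7. Numerical choices and degenerate inputs

- Flat (pulseless) signals are rejected as unusable rather than
  producing NaNs; non-uniform time grids are rejected at construction.
- Markers whose epochs extend past the recording edge reject that trial
  with a warning rather than failing the session.
- Zero-variance phenotypes, empty proband groups, and zero-variance
  reliability halves raise informative errors; no silent NA statistics.
- Subjects with one accepted trial have no defined SE and are excluded.
- `a2 = 1` in the power analysis implies a singular DZ model and is
  refused.
- Boundary estimates are snapped to exactly 0/1 only within 1e-8.

## 8. Problem sizes used by the test suite

Simulation sizes were chosen so the full suite exercises every claim at
meaningful precision: 500 replicates for unbiasedness and profile-CI
coverage at the study's own group sizes (96/98 pairs), 1000 null
replicates for the extremes size calibration, 5000 for the power
Monte-Carlo cross-check, 280 subjects for the reliability design, and
cohorts of 25–40 full synthetic sessions for pipeline-level properties.

## 9. Known limitations

- The continuous ML treatment of the bounded, J-shaped handedness scores
  follows the primary analyses of this study design; an ordinal
  liability-threshold model is out of scope.
- No sex-limitation or opposite-sex-specific models; opposite-sex pairs
  are pooled with DZ.
- The double-entry extremes p-value is anticonservative (see section 4);
  this is a property of the convention, reported rather than corrected.
- Power analysis covers the univariate AE design only (no c² > 0 designs,
  multivariate or binary-trait power).
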