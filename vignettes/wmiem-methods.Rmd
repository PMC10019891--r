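---
title: "Methods: inverted encoding analysis of delay-period working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverted encoding analysis of delay-period working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmiem)
```

`wmiem` analyzes a retro-cue continuous-report working-memory
experiment: two orientation gratings are studied sequentially, a
retro-cue selects one for retention across a 5-TR delay, and the cued
orientation is reproduced by continuous adjustment. The package asks
whether delay-period multi-voxel patterns carry cued-item information,
whether they track stimulus similarity structure, and whether
reconstruction quality predicts recall precision. This vignette
documents the model, the synthetic-data generator, and the numerical
and design choices.

## The encoding model

Voxel responses are modeled as a linear mixture of `k = 9` idealized
orientation channels, `B = W C + N`. The channel tuning function is a
half-wave rectified sinusoid over the 180° orientation space,

$$f_k(\theta) = \max\big(0, \cos(\pi d_k / 180)\big)^p,$$

with $d_k$ the signed circular difference to the channel center mapped
to $[-90, 90)$. The centers default to the nine base stimulus
orientations (0–160° in 20° steps).

**The exponent `p`.** The default is `p = 8`, exposed as
configuration. The choice is not cosmetic: the shifted family of
rectified cosines to the power `p` spans `p + 1` independent
harmonics, so a 9-channel design is full rank only for `p >= 8`. At
`p = 2` the design has rank 3 and at `p = 6` rank 7, in which case the
least-squares weights are not unique and the package falls back to a
pseudo-inverse with a warning. The tests assert this rank law
directly. A second property of evenly spaced centers is exact tiling:
the summed channel response is constant in $\theta$ to machine
precision (harmonic cancellation), measured by a grid scan in the test
suite.

**Training labels.** Channel responses are evaluated at the jittered
(actual) stimulus orientations by default. The jitter (≤5°) is small
against the 20° channel spacing; a configuration switch allows binned
base-orientation labels instead by passing those labels to the
decoder.

## Filters, shrinkage, inversion

Weights are estimated per voxel by ordinary least squares,
`W = B1 C1' (C1 C1')^-1`. Decoding uses per-channel optimal filters

$$V_i = \frac{\Sigma_i^{-1} W_i}{W_i^\top \Sigma_i^{-1} W_i},$$

where $\Sigma_i$ is a regularized covariance of the training residual
$\varepsilon_i = B_1 - W_i C_{1,i}$ (uncentered, normalized by
$n_1 - 1$). The normalizing denominator enforces unit gain
($V_i^\top W_i = 1$) on the filter's own channel.

**Shrinkage.** $\Sigma_i$ is shrunk toward a scaled identity
$\mu I$ ($\mu$ = mean residual variance) with an analytic
Ledoit–Wolf-style coefficient computed from the residual columns:
the ratio of the estimated sampling variance of the covariance entries
to the observed distance between the sample covariance and the target,
clipped to $[0, 1]$. Two limiting behaviors are worth knowing. For
anisotropic residuals the coefficient vanishes as $n_1$ grows and
$\Sigma_i$ converges to the sample covariance. For exactly isotropic
residuals the target coincides with the truth and the coefficient
approaches 1 — full shrinkage is then the correct answer, not a
failure mode. Degenerate all-zero residuals fall back to
$\Sigma_i = \delta I$ with $\delta = 10^{-6}$, with a warning, so that
decoding still returns finite values.

**Crosstalk.** The per-channel unit-gain construction does not make
$V^\top W$ the identity: with correlated voxel tuning the off-diagonal
crosstalk is substantial, and on noiseless data a minority of
single-trial reconstruction peaks can sit one channel spacing away
from the true orientation even though the trial-mean curve peaks at
0° and the per-trial information metric stays positive. Exact
single-trial inversion holds when the weight columns are orthogonal
(e.g. the generator's `one_hot` tuning mode), which is what the
forward/backward consistency tests use. An identity-covariance path
(`cov = "identity"`, giving $V_i = W_i / W_i^\top W_i$) is available
for diagnostics.

## Alignment and the information metric

Held-out channel responses `C2 = V' B2` are estimated with
leave-one-block-out cross-validation (every trial decoded exactly
once; the trialwise variant re-blocks trials by a seeded permutation
into groups of 18). Each trial's nine responses are placed at the
channel centers, interpolated to a 1°, 180-point grid by linear
interpolation on the wrapped domain (the first channel is appended at
center + 180° to close the circle; the linear-interpolation error for
a unit cosine is bounded by $h^2 |f''|/8 \approx 0.061$ at h = 20°),
and rotated so the trial's label sits at 0°. Because linear
interpolation attains its maximum at a knot, an off-grid label aligns
its peak to the offset of the nearest channel center — exactly 0 only
for on-grid labels.

The scalar information metric doubles orientations to angles,

$$R = \mathrm{Re}\Big(\tfrac{1}{k}\sum_k C_k e^{2 i \psi_k}\Big),$$

computed directly from the nine channel responses at label-relative
angles (no interpolation involved), so $R = 0$ for a uniform profile,
$1/9$ for a unit delta at the correct channel, and negative for
profiles concentrated at the orthogonal orientation. Averaging per
trial and then across trials is the default (`mean_R`); the metric of
the averaged curve is also reported (`R_of_mean_curve`) since the two
orders differ for asymmetric curves.

## Representational similarity analysis

Neural similarity is the trial-pair cosine of delay patterns; stimulus
similarity is `180 - d(theta_i, theta_j)` with `d` the circular
orientation distance in `[0, 90]` — the only reading consistent with
orientation stimuli, and immaterial to the rank correlation up to
monotone transforms. The association is a Spearman correlation of the
lower triangles with average ranks for ties, Fisher-transformed with
`|rho|` clipped at `1 - 1e-7`. The cross-region variant correlates two
regions' similarity structures (second order), and can be applied to
baseline-epoch versus delay-epoch patterns.

## Behavior

Recall error is the signed circular difference between report and
target on the half-open interval `[-90, 90)`; the boundary case maps
to −90 (reports exactly orthogonal to the target are never observed in
practice). The pooled "empirical SD" is the ordinary linear SD of the
signed errors across all subjects and trials — the raw distribution
lives on a bounded interval, so a linear SD is well defined — and the
3-SD rule uses this pooled value by default (a per-subject option
exists). Categories are `small` (< 20°), `larger` (20° ≤ e ≤ upper,
upper bound inclusive) and `excluded`; the fixed-cut-off variant uses
45°.

The balanced-resampling contrast draws, per iteration, as many
small-error trials as there are larger-error trials *without
replacement*, averages the trialwise measure, and averages over 5000
iterations; the estimate is unbiased for the all-small-trials mean
(verified against the exhaustive subset enumeration on a tiny
instance). Subjects with fewer than 2 larger-error trials are excluded
with a log entry.

## Group statistics

Paired two-tailed t-tests with Cohen's d = mean(diff)/sd(diff); a
subject-level bootstrap (resampling subjects with replacement,
1000 iterations, two-tailed empirical p floored at 1/n_iter and
reported as "<0.001" below the floor); Bonferroni correction with an
*explicit* family size (the family of comparisons is configuration,
never inferred); and a 2×2 within-subject cue-by-region interaction
computed from the per-subject interaction contrast, whose
`F(1, n-1)` equals the squared paired t — verified against a
repeated-measures ANOVA oracle.

## The synthetic-data generator

The generator emulates the study conditions: 16 subjects, 10 blocks of
18 trials, two items drawn from the nine base orientations with
circular separation strictly greater than 20° (enforced pre-jitter, on
the base orientations, so the feasible separations are ≥ 40° on the
20° grid), jitter of uniform magnitude 1–5° with independent random
sign per item, and a balanced retro-cue within each block. Voxel
tuning weights give every channel at least one preferring voxel, with
graded rectified-cosine profiles and random gains (`one_hot` mode
yields orthogonal weights for exact-inversion tests). Runs are laid
out on a fixed TR grid per trial — 5 baseline TRs, encoding, cue, 5
delay TRs, response — with the cued item's signal (scaled `snr_cued`)
in every delay TR, both items at `snr_encoding` during encoding, and
spatially correlated Gaussian noise
`noise_sd^2 (I + c A A'/m)` throughout. Hemodynamic convolution is
deliberately not simulated: the analysis consumes raw delay TRs, and
the TENT weighting (below) is the only temporal model.

Defaults were chosen once as plausible study conditions: `n_voxels =
40` (a small anatomically defined ROI at high resolution), `snr_cued =
0.3` and `snr_encoding = 0.3` against unit noise (modest single-trial
signal that still yields clearly positive subject-level information),
`snr_uncued = 0` (the central claim is cued-specific delay
information; leakage is configurable to explore alternatives), and a
behavioral mixture of wrapped-Gaussian recall noise (`recall_sd =
14.5°`) with a 3% uniform lapse rate, calibrated so the pooled error
profile reproduces the reported group-level recall statistics (mean
absolute error ≈ 12°, pooled SD ≈ 17°, ~97–98% of trials within 45°,
≈ 149 small-error and ≈ 27–31 larger-error trials per subject).

One structural subtlety: because the two items are constrained to be
separated, the uncued label is statistically dependent on the cued
label, so a decoder trained on uncued labels can pick up a small
positive information residue from cued-item signal alone. The null
calibration tests therefore use label-shuffled decoding and zero-SNR
data, where the expectation is exactly zero.

For analyses coupling neural quality to behavior, `trial_gain_sd`
draws per-trial log-normal delay-signal gains and
`precision_coupling = kappa` scales recall noise as
`recall_sd / gain^kappa`; both default to 0 because the coupling is a
simulated hypothesis, not a design fact.

**What the generator does not emulate:** hemodynamic response shapes,
scanner drift, motion, physiological noise, temporal autocorrelation,
or volumetric geometry. Passing tests therefore demonstrate the
correctness and calibration of the estimators under the assumed
generative model, not robustness to every artifact of real fMRI data.

## Delay-pattern extraction

Each run is z-scored per voxel across its TRs (population SD
convention, dividing by n; configurable, and immaterial downstream up
to uniform scaling), zero-variance voxels being zeroed with a warning.
The 5 delay TRs are then collapsed by a normalized TENT-weighted mean
with weights `(0, 1, 2, 1, 0)` — equivalent to averaging the middle 3
TRs with the midpoint double-weighted, which emphasizes mid-delay
signal without fitting a hemodynamic model. Normalizing by the weight
sum keeps patterns on the scale of the input signal; it rescales all
patterns uniformly and cannot change correlations or decoding.
`peak_shift` slides the window across TRs for the time-varying
variant, with out-of-run windows raising a per-trial error.

## Problem sizes and determinism

The validation suite runs the study-scale design (16 subjects,
180 trials) throughout: 200 replicate experiments for the null
calibration (false-positive rate and zero-centering checks), 20
replicates for the signal-recovery power property, 10 for the
interaction detection, and 5000 resampling iterations per subject for
the error-linked contrast — sizes chosen so the full suite completes
in a few minutes on one CPU while leaving the binomial error bands
tight. Every stochastic stage takes an explicit seed; generator
outputs are pure functions of (config, seed), and the pipeline's
provenance sidecars record config hashes and seeds so identical
configurations reproduce identical artifacts bit for bit.

## Known limitations

- The information metric is interpretable only within the assumed
  channel basis; it does not estimate neuronal tuning, and comparisons
  of R across regions with different voxel counts or noise levels are
  not meaningful (only within-region contrasts are computed).
- With graded, correlated voxel tuning, per-channel filters leave
  crosstalk in single-trial reconstructions (see above); inference is
  therefore built on trial-averaged and subject-level statistics.
- The bootstrap p floor (1/n_iter) and the Fisher-z clip are reporting
  conventions, not statistical corrections.
- `p < 8` bases are rank deficient for 9 channels and are supported
  only through the pseudo-inverse path.
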