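# wmiem

Decoding item-specific working-memory content from delay-period fMRI
voxel patterns in retro-cue continuous-report experiments.

## The problem

In a retro-cue orientation task, an observer studies two orientation
gratings, is cued after encoding to retain only one of them across a
short delay (5 TRs), and then reproduces the cued orientation by
continuous adjustment. The scientific question is whether a brain
region's delay-period multi-voxel activity carries information about
the *cued* item specifically — more than about the uncued item — and
whether the quality of that neural representation predicts the
precision of the subsequent recall. `wmiem` implements the full
analysis chain for this question, plus a synthetic-data generator that
emulates the task (16 subjects, 10 blocks × 18 trials, nine base
orientations 0–160° in 20° steps with ±1–5° jitter and >20° separation
between items), so that every stage can be validated without scanner
data.

## The model

**Inverted encoding model (IEM).** Voxel patterns are modeled as a
linear mixture of k = 9 idealized orientation channels — half-wave
rectified sinusoids `max(0, cos(pi d / 180))^p` (default p = 8)
centered on the nine base orientations:

    B = W C + N

with `B` (m voxels × n trials), `C` (k channels × n trials) and weights
`W` fit by ordinary least squares, `W = B1 C1' (C1 C1')^-1`. Decoding
uses noise-covariance-regularized *optimal filters*: for each channel
i, the training residual `eps_i = B1 - W_i C1_i` yields a covariance
estimate shrunk analytically (Ledoit–Wolf-style) toward a scaled
identity, and

    V_i = Sigma_i^-1 W_i / (W_i' Sigma_i^-1 W_i),

which has unit gain on its own channel. Held-out channel responses are
`C2 = V' B2`, estimated by leave-one-block-out cross-validation,
interpolated to a 1° grid, aligned so the trial's orientation label
sits at 0°, and reduced to a scalar information metric

    R = Re( mean_k C_k exp(2 i psi_k) ),

the real part of the mean orientation-doubled phasor: 0 for a uniform
(information-free) reconstruction, positive when the reconstruction
peaks at the correct orientation.

**Stimulus-based RSA.** Trial-pair cosine similarity of delay patterns
is rank-correlated (Spearman, then Fisher z) against a stimulus
similarity model, `180 - d(theta_i, theta_j)` with `d` the circular
orientation distance.

**Behavior linkage.** Circular recall errors (`[-90, 90)°`) categorize
trials into small (<20°) and larger (20° to 3 SD of the pooled error
distribution, or a fixed 45° cut-off); reconstruction quality is
compared between categories with a balanced resampling scheme (5000
draws of |larger| trials from the small pool) and subject-level paired
statistics: paired t, Cohen's d, 1000-iteration subject bootstrap,
Bonferroni correction, and a 2×2 cue-by-region interaction.

## Worked example

```r
library(wmiem)

cfg   <- sim_config(seed = 7)          # the task at its default scale
basis <- channel_basis()               # 9 channels, p = 8

sub <- simulate_subject(cfg, 1)        # design + behavior + BOLD runs
pat <- extract_delay_patterns(sub$runs, subject_id = 1)

lobo_cv(pat, sub$trials, basis, "cued")
#> iem_reconstruction (cued): 180 trials, mean R = 0.1275
lobo_cv(pat, sub$trials, basis, "uncued")
#> iem_reconstruction (uncued): 180 trials, mean R = 0.0188
lobo_cv(pat, sub$trials, basis, "shuffled", seed = 1)
#> iem_reconstruction (shuffled): 180 trials, mean R = -0.0006

ns <- neural_similarity(pat)
similarity_association(ns, stimulus_similarity(sub$trials$theta_cued))
#> similarity_association: rho = 0.2794, Fisher z = 0.2870 (16110 pairs)

err <- recall_error(sub$trials$reported, sub$trials$theta_cued)
categorize_trials(err, upper_rule = "three_sd", sd_pooled = sd(err))
#> trial_categorization: 145 small, 31 larger, 4 excluded (<20 / <=50.6142 deg)
```

The cued reconstruction carries clearly positive information
(R = 0.13), the uncued and label-shuffled decodes sit at chance, and
the RSA association is positive for the cued item — the qualitative
pattern the pipeline is built to detect. Behavior shows the expected
profile: mean absolute error ≈ 12.7°, pooled SD ≈ 16.9°, and the
small/larger-error split retains ~98% of trials.

A full multi-subject run with artifacts on disk:

```r
run_pipeline(run_config(), "out/")    # writes CSV tables + provenance JSON
```

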