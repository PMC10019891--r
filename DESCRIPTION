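Package: wmiem
Title: Inverted Encoding Model Analysis of Delay-Period Working Memory fMRI
    Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding item-specific working-memory content from
    delay-period multi-voxel fMRI patterns in a retro-cue continuous
    orientation-reproduction task. Implements an inverted encoding model
    with noise-covariance-regularized optimal filters (shrinkage
    covariance estimation), leave-one-block-out cross-validation, aligned
    channel-response reconstructions and a scalar information metric;
    stimulus-based representational similarity analysis with rank-order
    association; circular recall-error quantification and trial
    categorization; subject-level group statistics (paired tests, Cohen's
    d, subject bootstrap, Bonferroni correction, cue-by-region
    interaction, balanced-resampling error-linked contrasts); and a
    synthetic-data generator that emulates the task design and the
    statistical structure of tuned voxel patterns so the full pipeline is
    testable without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
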