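Package: iastates
Title: Decoding Internal-Attention Brain States from Multivoxel fMRI Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-subject multivoxel decoding of internal-attention brain
    states (breath focus, mind wandering, self-referential processing, and
    control states) from block-design fMRI task data, using one-vs-rest
    L2-penalized logistic classifiers with leave-one-block-out
    cross-validation. Trained patterns are applied across task to an
    independent meditation run to segment it into mental-state events, from
    which per-subject attention metrics (percentage time engaged, event
    counts, event durations) and group-level contrasts are computed.
    Includes classifier importance maps (weight x z-scored activation) and a
    synthetic-data generator with known ground truth (condition patterns
    with hemodynamic lag, autocorrelated noise, drift, hidden-state
    meditation runs, and attention ratings) so the whole pipeline is
    testable end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
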