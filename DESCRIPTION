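Package: stepsynergy
Title: Muscle Synergy Analysis of Voluntary and Reactive Backward Stepping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts and compares muscle synergies from multi-channel surface
    EMG recorded during voluntary and perturbation-evoked (reactive) backward
    stepping. Implements EMG conditioning (high-pass, rectification, low-pass
    envelope), time-bin averaging and normalization with reversible scaling,
    non-negative matrix factorization with a dual variance-accounted-for
    model-order rule, cross-subject hierarchical clustering of synergy vectors
    under a subject-uniqueness cut, similarity and merging analyses
    (correlation threshold, non-negative least squares), 80% subset
    cross-validation, supporting statistics (critical correlation,
    Benjamini-Yekutieli corrected level, effect sizes), gait event detection
    and treadmill perturbation-profile arithmetic. A synthetic-cohort
    generator with known ground-truth synergy structure makes the full
    pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
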