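# Shared fixtures, built in code.

# Small noiseless cohort with planted rank-2 structure.
noiseless_spec_k2 <- function(seed = 3) {
  synthetic_spec(n_subjects = 2,
                 true_synergies = default_voluntary_templates()[, 1:2],
                 noise_sd = 0, subject_jitter_sd = 0, seed = seed)
}

# One subject's three recordings from a cohort.
subject_recs <- function(cohort, sid) {
  cohort$recordings[grep(paste0("^", sid, "_"), names(cohort$recordings))]
}

# Deterministic non-negative test matrix.
random_nonneg <- function(nrow, ncol, seed = 42) {
  set.seed(seed)
  matrix(runif(nrow * ncol), nrow, ncol)
}

# Per-subject voluntary fits with weights on the envelope scale, as used
# for pooling/clustering against generator ground truth.
envelope_fits <- function(cohort, config = pipeline_config(),
                          task = "voluntary") {
  sids <- names(cohort$ground_truth)
  fits <- lapply(sids, function(sid) {
    r <- extract_subject(subject_recs(cohort, sid), config)
    fit <- r[[task]]$fit
    fit$W <- r[[task]]$W_envelope
    fit
  })
  names(fits) <- sids
  fits
}
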