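test_that("synergy similarity is Pearson r with its invariances", {
  w <- c(0.2, 0.9, 0.1, 1, 0.5, 0, 0.3, 0.7)
  expect_equal(synergy_similarity(w, w), 1)
  expect_equal(synergy_similarity(w, 3.7 * w), 1)
  # hand-computed covariance ratio
  a <- c(1, 0, 0.5, 0.25, 0, 1, 0.75, 0.5)
  b <- c(0.9, 0.1, 0.4, 0.3, 0.2, 0.8, 0.6, 0.55)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(synergy_similarity(a, b), manual, tolerance = 1e-12)
  # symmetry
  expect_equal(synergy_similarity(a, b), synergy_similarity(b, a))
  expect_error(synergy_similarity(rep(1, 8), w), "zero-variance")
})

test_that("critical r reproduces the 8-point p<0.01 threshold and its limits", {
  expect_equal(round(critical_r(8, 0.01), 3), 0.834)
  # closed form against the t quantile it is built from
  tc <- qt(1 - 0.05 / 2, 10)
  expect_equal(critical_r(12, 0.05), tc / sqrt(10 + tc^2), tolerance = 1e-12)
  # alpha -> 1 drives the threshold to 0
  expect_lt(critical_r(8, 0.9999), 0.001)
  # strictly decreasing in n and alpha
  expect_gt(critical_r(8, 0.01), critical_r(9, 0.01))
  expect_gt(critical_r(8, 0.01), critical_r(8, 0.05))
  expect_error(critical_r(2), "at least 3")
})

test_that("Benjamini-Yekutieli corrected level reproduces 0.024 for m = 4", {
  expect_equal(round(by_corrected_alpha(0.05, 4), 3), 0.024)
  expect_equal(by_corrected_alpha(0.05, 1), 0.05)
  expect_equal(by_corrected_alpha(0.06, 3), 0.06 / (1 + 1/2 + 1/3))
})

test_that("NNLS merging recovers exact mixtures and honors its bound", {
  W <- default_voluntary_templates()
  # target is an exact 50/50 mixture of the first two sources
  target <- 0.5 * W[, 1] + 0.5 * W[, 2]
  mr <- merge_synergies(W[, 1:3], target)
  expect_equal(mr$r, 1, tolerance = 1e-9)
  expect_equal(mr$weights[1] / mr$weights[2], 1, tolerance = 1e-6)
  expect_lt(mr$weights[3], 1e-8)

  # sources include the target itself
  mr2 <- merge_synergies(cbind(W[, 3], W[, 1]), W[, 1])
  expect_equal(mr2$r, 1, tolerance = 1e-9)

  # NNLS objective dominance: the multi-source residual never exceeds the
  # best single-source residual (larger feasible set)
  set.seed(9)
  tgt <- runif(8)
  multi_resid <- pracma::lsqnonneg(W[, 1:3], tgt)$resid.norm
  single_resids <- apply(W[, 1:3], 2, function(s) {
    pracma::lsqnonneg(cbind(s), tgt)$resid.norm
  })
  expect_lte(multi_resid, min(single_resids) + 1e-12)
  expect_error(merge_synergies(matrix(0, 8, 2), tgt), "zero")
  expect_error(merge_synergies(W[, 1, drop = FALSE], tgt), "two source")
})

test_that("merging can report failure (r <= 0) without clamping", {
  sources <- cbind(c(1, 1, 0, 0, 0, 0, 0, 0.2), c(1, 0.8, 0.1, 0, 0, 0, 0, 0))
  target <- c(0, 0, 0, 0, 1, 1, 1, 0)
  mr <- merge_synergies(sources, target)
  expect_lte(mr$r, 0)
  expect_true(mr$degenerate)
})

test_that("exact centroid matching beats greedy on an adversarial case", {
  # greedy grabs the single largest r and strands the remaining pair
  A <- cbind(c(1, 0.8, 0, 0, 0, 0, 0, 0), c(0.9, 1, 0.1, 0, 0, 0, 0, 0))
  B <- cbind(c(0.95, 1, 0.05, 0, 0, 0, 0, 0), c(1, 0.85, 0, 0, 0.05, 0, 0, 0))
  ex <- match_synergies(A, B, method = "exact")
  gr <- match_synergies(A, B, method = "greedy")
  expect_gte(sum(ex$r), sum(gr$r) - 1e-12)
  # each column matched at most once
  expect_false(anyDuplicated(ex$idx_b) > 0)
})

test_that("cross-validation at fraction 1 reproduces the full clustering", {
  coh <- generate_cohort(synthetic_spec(n_subjects = 6, seed = 41))
  fits <- envelope_fits(coh, pipeline_config(restarts = 5))
  rep1 <- cross_validate(fits, fraction = 1, seed = 2)
  expect_true(all(abs(rep1$pairs$r - 1) < 1e-12))
  expect_error(cross_validate(fits, fraction = 0), "fraction")
  expect_error(cross_validate(fits[1:3], fraction = 0.8), "5 subjects")
})

test_that("cross-validation subset membership is seed-reproducible", {
  coh <- generate_cohort(synthetic_spec(n_subjects = 6, seed = 43))
  fits <- envelope_fits(coh, pipeline_config(restarts = 5))
  r1 <- cross_validate(fits, 0.8, seed = 4)
  r2 <- cross_validate(fits, 0.8, seed = 4)
  expect_identical(attr(r1, "subset"), attr(r2, "subset"))
  expect_identical(r1$pairs, r2$pairs)
})

test_that("similar repertoires across bin widths are detected", {
  spec <- synthetic_spec(n_subjects = 6, noise_sd = 0, subject_jitter_sd = 0,
                         seed = 47)
  coh <- generate_cohort(spec)
  cfg <- pipeline_config(restarts = 5)
  fits_by_bin <- lapply(c("15", "28"), function(b) {
    sids <- names(coh$ground_truth)
    fits <- lapply(sids, function(sid) {
      r <- extract_subject(subject_recs(coh, sid), cfg, bin_ms = as.numeric(b))
      fit <- r$voluntary$fit
      fit$W <- r$voluntary$W_envelope
      fit
    })
    names(fits) <- sids
    fits
  })
  names(fits_by_bin) <- c("15", "28")
  rep <- compare_bin_widths(fits_by_bin)
  expect_true(all(rep$pairs$r >= 0.99))
})

test_that("synergy-count statistics wrap the standard tests", {
  kv <- c(4, 4, 5, 4, 6, 5, 4, 5, 4, 5)
  kr <- c(3, 4, 4, 3, 4, 4, 3, 4, 3, 4)
  out <- compare_synergy_counts(kv, kr, groups = rep(c("young", "older"), each = 5))
  expect_s3_class(out$wilcoxon, "htest")
  expect_s3_class(out$kruskal, "htest")
  expect_gt(out$cohens_d, 0)
  # Cohen's d pooled-SD form against direct arithmetic
  sp <- sqrt((9 * var(kv) + 9 * var(kr)) / 18)
  expect_equal(out$cohens_d, (mean(kv) - mean(kr)) / sp, tolerance = 1e-12)
})
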