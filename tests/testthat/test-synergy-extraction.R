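test_that("VAF matches an independent residual computation", {
  M <- random_nonneg(8, 50, 7)
  f <- nnmf(M, 1, seed = 2, n_restarts = 3)
  v <- vaf(M, f$W, f$C)
  # brute-force recomputation, element loops instead of matrix algebra
  R <- M - f$W %*% f$C
  sse <- 0; ss <- 0
  per <- numeric(8)
  for (i in 1:8) {
    sse_i <- sum(R[i, ]^2); ss_i <- sum(M[i, ]^2)
    per[i] <- 100 * (1 - sse_i / ss_i)
    sse <- sse + sse_i; ss <- ss + ss_i
  }
  expect_equal(v$overall, 100 * (1 - sse / ss), tolerance = 1e-9)
  expect_equal(unname(v$per_muscle), per, tolerance = 1e-9)
})

test_that("VAF edge cases follow the definition", {
  M <- random_nonneg(8, 10, 8)
  W <- diag(8); C <- M
  v <- vaf(M, W, C)
  expect_equal(v$overall, 100)
  expect_equal(unname(v$per_muscle), rep(100, 8))
  v0 <- vaf(M, matrix(0, 8, 1), matrix(0, 1, 10))
  expect_equal(v0$overall, 0)
  expect_error(vaf(matrix(0, 8, 5), W, C), "all-zero")
})

test_that("full-order factorization reconstructs almost perfectly", {
  M <- random_nonneg(8, 20, 9)
  f <- nnmf(M, 8, seed = 1, n_restarts = 3)
  expect_gte(f$vaf_overall, 99.9)
})

test_that("nnmf is deterministic for a fixed seed and validates input", {
  M <- random_nonneg(8, 30, 10)
  f1 <- nnmf(M, 3, seed = 5)
  f2 <- nnmf(M, 3, seed = 5)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$C, f2$C)
  expect_error(nnmf(M - 1, 3), "non-negative")
  expect_error(nnmf(M, 9), "1..8")
  expect_error(nnmf(M[, 1:2], 3), "time bins")
})

test_that("weight columns are max-normalized with the scale folded into C", {
  M <- random_nonneg(8, 30, 11)
  f <- nnmf(M, 3, seed = 2)
  expect_equal(unname(apply(f$W, 2, max)), rep(1, 3), tolerance = 1e-9)
  # reconstruction VAF as reported must hold when recomputed
  v <- vaf(M, f$W, f$C)
  expect_equal(v$overall, f$vaf_overall, tolerance = 1e-9)
})

test_that("noiseless planted rank-2 data is recovered exactly", {
  spec <- noiseless_spec_k2()
  coh <- generate_cohort(spec)
  rec <- coh$recordings[["S01_voluntary_right"]]
  M <- bin_average(rec$samples, rec$sampling_rate,
                   c(rec$events$PON, rec$events$TD), 15)
  f <- nnmf(M, 2, seed = 1)
  expect_gte(f$vaf_overall, 99.99)
  m <- match_synergies(f$W, spec$true_synergies)
  expect_true(all(m$r >= 0.999))
})

test_that("the dual VAF rule selects the planted synergy number", {
  spec <- synthetic_spec(n_subjects = 1, noise_sd = 0, subject_jitter_sd = 0,
                         seed = 23,
                         true_synergies = default_voluntary_templates()[, 1:3])
  coh <- generate_cohort(spec)
  rec <- coh$recordings[["S01_voluntary_right"]]
  M <- bin_average(rec$samples, rec$sampling_rate,
                   c(rec$events$PON, rec$events$TD), 15)
  sel <- select_num_synergies(M, seed = 1)
  expect_equal(sel$k, 3L)
  expect_true(sel$fit$criteria_met)

  # vacuous thresholds select k = 1
  sel1 <- select_num_synergies(M, overall_thresh = 0,
                               per_muscle_thresh = 0, seed = 1)
  expect_equal(sel1$k, 1L)
})

test_that("raising the per-muscle threshold never lowers the selected k", {
  for (s in 1:8) {
    spec <- synthetic_spec(n_subjects = 1, seed = s)
    coh <- generate_cohort(spec)
    rec <- coh$recordings[["S01_voluntary_right"]]
    M <- bin_average(condition_emg(rec)$samples, rec$sampling_rate,
                     c(rec$events$PON, rec$events$TD), 15)
    k75 <- select_num_synergies(M, per_muscle_thresh = 75, seed = 1,
                                n_restarts = 3)$k
    k80 <- select_num_synergies(M, per_muscle_thresh = 80, seed = 1,
                                n_restarts = 3)$k
    expect_gte(k80, k75)
  }
})

test_that("best-of-restarts VAF is non-decreasing in k", {
  M <- random_nonneg(8, 40, 13)
  vafs <- vapply(1:6, function(k) {
    nnmf(M, k, seed = 3, n_restarts = 10)$vaf_overall
  }, numeric(1))
  expect_true(all(diff(vafs) >= -1e-6))
})

test_that("major contributors use a strict threshold on normalized weights", {
  W <- cbind(c(1, 0.41, 0.39, 0, 0, 0, 0, 0))
  expect_equal(major_contributors(W)[[1]], c(1L, 2L), ignore_attr = TRUE)
  expect_length(major_contributors(W, threshold = 1)[[1]], 0)
  W5 <- cbind(c(0.8, 0.7, 0.9, 0.6, 1, 0.1, 0.05, 0))
  expect_length(major_contributors(W5)[[1]], 5)
})

test_that("recruitment metrics report bin-center peak times and order", {
  # burst peaking in the 11th bin = bin index 10 (0-based): center 0.1575 s
  C <- rbind(exp(-((1:30) - 11)^2 / 8), exp(-((1:30) - 21)^2 / 8))
  rm <- recruitment_metrics(C, 15)
  expect_equal(rm$peak_time_s[1], (10 + 0.5) * 0.015)
  expect_equal(rm$order, c(1L, 2L))

  # ties break by synergy index; all-zero rows are ordered last
  C2 <- rbind(C[1, ], C[1, ], 0)
  rm2 <- recruitment_metrics(C2, 15)
  expect_equal(rm2$order, c(1L, 2L, 3L))
  expect_true(is.na(rm2$peak_time_s[3]))
})
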