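make_rec <- function(samples, fs = 1200, events = list(PON = 0.1, LO = 0.3, TD = 0.45)) {
  emg_recording("S01", "voluntary", "right", fs, samples, events)
}

test_that("conditioning preserves zero and returns non-negative envelopes", {
  rec <- make_rec(matrix(0, 8, 1200))
  out <- condition_emg(rec)
  expect_equal(unname(out$samples), matrix(0, 8, 1200))

  # impulse train: non-negative envelope with finite energy
  x <- matrix(0, 8, 1200)
  x[, seq(1, 1200, by = 6)] <- 1  # 200 Hz impulse train
  out2 <- condition_emg(make_rec(x))
  expect_true(all(out2$samples >= 0))
  expect_true(all(is.finite(out2$samples)))
})

test_that("the 35 Hz high-pass attenuates 10 Hz by >= 20 dB relative to 100 Hz", {
  fs <- 1200
  t <- (0:(4 * fs - 1)) / fs
  hp <- signal::butter(4, 35 / (fs / 2), type = "high")
  amp <- function(f) {
    y <- stepsynergy:::zero_phase_filter(sin(2 * pi * f * t), hp$b, hp$a)
    # steady-state amplitude away from the edges
    max(abs(y[seq(fs, 3 * fs)]))
  }
  ratio_db <- 20 * log10(amp(100) / amp(10))
  expect_gte(ratio_db, 20)
})

test_that("conditioning rejects sampling rates below the filter corners", {
  rec <- emg_recording("S01", "voluntary", "right", 70, matrix(1, 8, 700),
                       events = list(PON = 0.1, LO = 0.3, TD = 0.45))
  expect_error(condition_emg(rec), "Nyquist")
})

test_that("conditioning an already-conditioned recording barely changes the binned matrix", {
  coh <- generate_cohort(synthetic_spec(n_subjects = 1, seed = 12))
  rec <- coh$recordings[["S01_voluntary_right"]]
  once <- condition_emg(rec)
  twice <- condition_emg(once)
  w <- c(rec$events$PON, rec$events$TD)
  b1 <- bin_average(once$samples, rec$sampling_rate, w, 15)
  b2 <- bin_average(twice$samples, rec$sampling_rate, w, 15)
  rel <- norm(b2 - b1, "F") / norm(b1, "F")
  expect_lt(rel, 0.05)
})

test_that("bin averaging matches the 18-samples-per-bin arithmetic", {
  x <- matrix(rep(1:600, each = 8), 8, 600, byrow = FALSE)
  x <- matrix(seq_len(8 * 600), 8, 600)
  b <- bin_average(x, 1200, c(0, 0.5), 15)
  expect_equal(ncol(b), 33L)  # floor(0.5 / 0.015), 4 trailing samples dropped
  expect_equal(b[, 1], rowMeans(x[, 1:18]))
  expect_equal(b[, 33], rowMeans(x[, (32 * 18 + 1):(33 * 18)]))

  # constant signal: every bin equals the constant
  bc <- bin_average(matrix(3.5, 8, 600), 1200, c(0, 0.5), 15)
  expect_true(all(bc == 3.5))

  # partial-last-bin variant keeps the remainder
  bp <- bin_average(x, 1200, c(0, 0.5), 15, partial_last = TRUE)
  expect_equal(ncol(bp), 34L)
  expect_equal(bp[, 34], rowMeans(x[, 595:600]))
})

test_that("bin averaging rejects windows shorter than one bin", {
  expect_error(bin_average(matrix(1, 8, 600), 1200, c(0, 0.01), 15),
               "shorter than one bin")
})

test_that("normalization divides by voluntary maxima and scales rows to unit SD", {
  set.seed(21)
  v1 <- random_nonneg(8, 30, 1)
  v2 <- random_nonneg(8, 30, 2)
  re <- random_nonneg(8, 20, 3) * 2  # reactive may exceed voluntary maxima
  out <- normalize_and_scale(list(v1, v2), list(re))
  expect_length(out, 3)
  for (bm in out) {
    expect_equal(unname(apply(bm$matrix, 1, sd)), rep(1, 8), tolerance = 1e-9)
  }
  # before unit-variance scaling, the voluntary row maxima are exactly 1
  m1 <- out[[1]]$matrix * out[[1]]$row_sds
  m2 <- out[[2]]$matrix * out[[2]]$row_sds
  expect_equal(unname(pmax(apply(m1, 1, max), apply(m2, 1, max))), rep(1, 8),
               tolerance = 1e-9)
  # reactive rows are not clipped and may exceed 1
  mr <- out[[3]]$matrix * out[[3]]$row_sds
  expect_gt(max(mr), 1)
})

test_that("scaling round-trips exactly and zero channels are reported", {
  v1 <- random_nonneg(8, 30, 4)
  v2 <- random_nonneg(8, 30, 5)
  out <- normalize_and_scale(list(v1, v2))
  expect_equal(unname(unscale_binned(out[[1]])), unname(v1), tolerance = 1e-9)
  expect_equal(unname(unscale_binned(out[[2]])), unname(v2), tolerance = 1e-9)

  dead <- v1; dead[3, ] <- 0
  dead2 <- v2; dead2[3, ] <- 0
  rownames(dead) <- rownames(dead2) <- canonical_muscles()
  expect_error(normalize_and_scale(list(dead, dead2)), "step_GAS")
})

test_that("invert_scaling multiplies rows by their recorded SDs", {
  W <- matrix(1, 8, 3)
  expect_equal(invert_scaling(W, rep(1, 8)), W)
  sds <- c(2, rep(1, 7))
  out <- invert_scaling(W, sds)
  expect_equal(out[1, ], rep(2, 3))
  expect_equal(out[2:8, ], W[2:8, ])
  expect_error(invert_scaling(W, 1:3), "length")
})

test_that("full pipeline on noiseless data recovers planted weights", {
  spec <- synthetic_spec(n_subjects = 1, noise_sd = 0, subject_jitter_sd = 0,
                         seed = 5)
  coh <- generate_cohort(spec)
  res <- extract_subject(subject_recs(coh, "S01"), pipeline_config())
  m <- match_synergies(res$voluntary$W_envelope, spec$true_synergies)
  expect_equal(res$voluntary$k, 4L)
  expect_true(all(m$r >= 0.999))
})
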