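# Zero-phase Butterworth filtering with reflective edge padding.
#
# signal::filtfilt does not pad, so transients can leak into short trials;
# we reflect 3 x the filter length at both ends (odd reflection about the
# end samples, the standard transient-suppression scheme) before running the
# filter forward and backward.
zero_phase_filter <- function(x, b, a) {
  n_pad <- 3L * max(length(b), length(a))
  n <- length(x)
  if (n <= n_pad) stop("signal too short for zero-phase filtering")
  pre <- 2 * x[1] - x[seq(n_pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - n_pad)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[seq(n_pad + 1L, n_pad + n)]
}

#' Condition raw EMG into a rectified envelope
#'
#' Applies the standard stepping-EMG conditioning chain: zero-phase
#' Butterworth high-pass at 35 Hz (4th order by default), full-wave
#' rectification, then a 2nd-order Butterworth low-pass at 40 Hz applied
#' forward and backward (dual pass).  The smoothed envelope is clipped at
#' zero, since ringing of the low-pass stage can undershoot slightly.
#'
#' The high-pass stage removes baseline drift and motion artifact from raw
#' interference EMG and is skipped for recordings already holding a
#' rectified envelope (`rec$conditioned == TRUE`, e.g. synthetic cohorts
#' that generate the activation envelope directly): the envelope's content
#' lies below the 35 Hz corner, so re-applying the high-pass would remove
#' the signal itself rather than artifact.  Rectification and the 40 Hz
#' low-pass are near-identities on a smooth non-negative envelope, which
#' makes conditioning idempotent in envelope shape.
#'
#' @param rec An [emg_recording()].
#' @param highpass_hz High-pass corner frequency (default 35).
#' @param lowpass_hz Low-pass corner frequency (default 40).
#' @param highpass_order High-pass Butterworth order (default 4).
#' @return An `EmgRecording` whose `samples` hold the non-negative envelope;
#'   attribute `conditioned` set to `TRUE`.
#' @export
condition_emg <- function(rec, highpass_hz = 35, lowpass_hz = 40,
                          highpass_order = 4) {
  stopifnot(inherits(rec, "EmgRecording"))
  nyq <- rec$sampling_rate / 2
  if (max(highpass_hz, lowpass_hz) >= nyq) {
    stop(sprintf(
      "sampling rate %g Hz too low: filter corner %g Hz is at or above the Nyquist frequency %g Hz",
      rec$sampling_rate, max(highpass_hz, lowpass_hz), nyq))
  }
  hp <- signal::butter(highpass_order, highpass_hz / nyq, type = "high")
  lp <- signal::butter(2, lowpass_hz / nyq, type = "low")
  apply_hp <- !isTRUE(rec$conditioned)
  out <- rec$samples
  for (i in seq_len(nrow(out))) {
    x <- rec$samples[i, ]
    if (apply_hp) x <- zero_phase_filter(x, hp$b, hp$a)
    x <- abs(x)
    x <- zero_phase_filter(x, lp$b, lp$a)
    x[x < 0] <- 0
    out[i, ] <- x
  }
  rec$samples <- out
  rec$conditioned <- TRUE
  rec
}

#' Average EMG into fixed-width time bins over an event window
#'
#' Down-samples each channel by arithmetic averaging within consecutive
#' bins of `bin_ms` milliseconds covering `[window[1], window[2])`.  Only
#' whole bins are kept: trailing samples that do not fill a bin are
#' discarded (set `partial_last = TRUE` to keep a shorter final bin).  At
#' 1200 Hz with 15 ms bins each bin averages exactly 18 samples.
#'
#' @param samples 8 x T numeric matrix.
#' @param sampling_rate Hz.
#' @param window Numeric length-2, start and end of the analysis window in
#'   seconds (typically PON and TD).
#' @param bin_ms Bin width in milliseconds (15 by default; 28 is the
#'   coarser alternative).
#' @param partial_last Keep a trailing partial bin instead of discarding it.
#' @return 8 x n_bins matrix; attribute `bin_ms` records the width.
#' @export
bin_average <- function(samples, sampling_rate, window, bin_ms = 15,
                        partial_last = FALSE) {
  stopifnot(bin_ms > 0, length(window) == 2, window[2] > window[1])
  t_end <- ncol(samples) / sampling_rate
  if (window[1] < 0 || window[2] > t_end + 1e-9)
    stop("window must lie within the trial")
  bin_s <- bin_ms / 1000
  n_bins <- floor((window[2] - window[1]) / bin_s + 1e-9)
  if (n_bins < 1) stop("window shorter than one bin")
  first <- floor(window[1] * sampling_rate) + 1L
  out <- matrix(0, nrow(samples), n_bins)
  for (j in seq_len(n_bins)) {
    i0 <- floor((window[1] + (j - 1) * bin_s) * sampling_rate + 1e-9) + 1L
    i1 <- floor((window[1] + j * bin_s) * sampling_rate + 1e-9)
    out[, j] <- rowMeans(samples[, i0:i1, drop = FALSE])
  }
  if (partial_last) {
    i0 <- floor((window[1] + n_bins * bin_s) * sampling_rate + 1e-9) + 1L
    i1 <- floor(window[2] * sampling_rate + 1e-9)
    if (i1 >= i0) out <- cbind(out, rowMeans(samples[, i0:i1, drop = FALSE]))
  }
  rownames(out) <- rownames(samples)
  attr(out, "bin_ms") <- bin_ms
  attr(out, "window") <- window
  out
}

#' Normalize and unit-variance scale a subject's binned trial matrices
#'
#' Two-step scaling with full bookkeeping for exact inversion.  Step 1:
#' every muscle row of every trial is divided by that muscle's maximum
#' activation over the subject's two voluntary (non-perturbation) trials;
#' reactive rows may therefore exceed 1 and are not clipped.  Step 2: each
#' row of each trial matrix is divided by its own standard deviation so all
#' muscles weigh equally in the factorization; the removed SDs are stored so
#' synergy weights can be mapped back to the original scaling with
#' [invert_scaling()].
#'
#' @param voluntary List of two binned voluntary-trial matrices (8 x n_bins).
#' @param reactive Optional list of binned reactive-trial matrices.
#' @param zero_sd `"error"` (default) to fail on a muscle that is flat over
#'   the window (a dead channel under this protocol), or `"one"` to
#'   substitute SD = 1 for tolerant batch runs.
#' @return List of `BinnedEmgMatrix` objects, one per input trial in order
#'   (voluntary first), each a list with `matrix`, `bin_ms`,
#'   `row_max_divisors`, `row_sds`, `task`.
#' @export
normalize_and_scale <- function(voluntary, reactive = list(),
                                zero_sd = c("error", "one")) {
  zero_sd <- match.arg(zero_sd)
  if (length(voluntary) != 2)
    stop("the subject's two voluntary trials are required for normalization")
  muscles <- rownames(voluntary[[1]]) %||% canonical_muscles()
  row_max <- pmax(apply(voluntary[[1]], 1, max), apply(voluntary[[2]], 1, max))
  if (any(row_max <= 0)) {
    stop("zero maximum over voluntary trials for muscle(s): ",
         paste(muscles[row_max <= 0], collapse = ", "))
  }
  trials <- c(lapply(voluntary, function(m) list(m = m, task = "voluntary")),
              lapply(reactive, function(m) list(m = m, task = "reactive")))
  lapply(trials, function(tr) {
    m <- tr$m / row_max
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      if (zero_sd == "error") {
        stop("zero SD after normalization for muscle(s): ",
             paste(muscles[sds == 0], collapse = ", "))
      }
      sds[sds == 0] <- 1
    }
    structure(list(matrix = m / sds,
                   bin_ms = attr(tr$m, "bin_ms"),
                   window = attr(tr$m, "window"),
                   row_max_divisors = row_max,
                   row_sds = sds,
                   task = tr$task),
              class = "BinnedEmgMatrix")
  })
}

#' Undo unit-variance scaling of synergy weights
#'
#' Multiplies each row of a weight matrix extracted from unit-variance data
#' by the SD removed in the forward pass, returning the synergy weights to
#' the normalized-activation scaling.  Column max-normalization is the
#' caller's concern (the extraction module re-normalizes).
#'
#' @param W 8 x k weight matrix on the unit-variance scale.
#' @param row_sds The per-row SDs recorded by [normalize_and_scale()].
#' @return Weight matrix on the original (pre unit-variance) scaling.
#' @export
invert_scaling <- function(W, row_sds) {
  if (nrow(W) != length(row_sds))
    stop("row_sds length must match the number of weight-matrix rows")
  W * row_sds
}

#' Invert both scaling steps of a binned matrix (round-trip helper)
#'
#' @param bm A `BinnedEmgMatrix` from [normalize_and_scale()].
#' @return The original binned matrix (before max-normalization and
#'   unit-variance scaling).
#' @export
unscale_binned <- function(bm) {
  stopifnot(inherits(bm, "BinnedEmgMatrix"))
  (bm$matrix * bm$row_sds) * bm$row_max_divisors
}
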