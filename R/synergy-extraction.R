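#' Variance accounted for by a synergy reconstruction
#'
#' Overall VAF is the uncentered coefficient of determination of the
#' reconstruction, `100 * (1 - ||M - W C||_F^2 / ||M||_F^2)`.  Per-muscle
#' VAF applies the same formula row-wise.  A centered variant (row means
#' removed from both numerator terms' reference) is available for
#' sensitivity checks.
#'
#' @param M 8 x n non-negative activation matrix.
#' @param W 8 x k weight matrix.
#' @param C k x n coefficient matrix.
#' @param centered Use the centered (variance about the row mean) form.
#' @return List with `overall` (percent) and `per_muscle` (length-8 percent
#'   vector).
#' @export
vaf <- function(M, W, C, centered = FALSE) {
  if (all(M == 0)) stop("VAF undefined for an all-zero activation matrix")
  R <- M - W %*% C
  if (centered) {
    Mc <- M - rowMeans(M)
    ss_row <- rowSums(Mc^2)
  } else {
    ss_row <- rowSums(M^2)
  }
  sse_row <- rowSums(R^2)
  per <- 100 * (1 - sse_row / ss_row)
  per[ss_row == 0] <- NA_real_
  overall <- 100 * (1 - sum(sse_row) / sum(ss_row))
  list(overall = overall, per_muscle = per)
}

# One multiplicative-update run (Lee-Seung, squared Frobenius objective).
nnmf_once <- function(M, k, tol, max_iter) {
  eps <- 1e-12
  n <- ncol(M)
  W <- matrix(runif(8L * k), 8L, k)
  C <- matrix(runif(k * n), k, n)
  err_prev <- Inf
  norm_M <- sum(M^2)
  for (it in seq_len(max_iter)) {
    C <- C * (crossprod(W, M)) / (crossprod(W) %*% C + eps)
    W <- W * (M %*% t(C)) / (W %*% tcrossprod(C) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      err <- sum((M - W %*% C)^2) / norm_M
      if (is.finite(err_prev) &&
          abs(err_prev - err) < tol * max(err, .Machine$double.eps)) break
      err_prev <- err
    }
  }
  list(W = W, C = C, iters = it)
}

# Max-normalize W columns, folding the inverse scale into C so W %*% C is
# unchanged.  All-zero columns are left untouched.
normalize_columns <- function(W, C) {
  scales <- apply(W, 2, max)
  nz <- scales > 0
  W[, nz] <- sweep(W[, nz, drop = FALSE], 2, scales[nz], "/")
  C[nz, ] <- sweep(C[nz, , drop = FALSE], 1, scales[nz], "*")
  list(W = W, C = C)
}

#' Non-negative matrix factorization of a binned activation matrix
#'
#' Factorizes `M ~ W C` with all entries non-negative by multiplicative
#' updates minimizing squared Frobenius error, restarted from `n_restarts`
#' uniform random initializations; the run with the highest overall VAF is
#' kept.  Weight columns are max-normalized to 1 with the inverse scale
#' folded into `C`, so the reconstruction is unchanged.  Deterministic for a
#' fixed seed.
#'
#' @param M 8 x n non-negative matrix (a `BinnedEmgMatrix` matrix slot or
#'   plain matrix).
#' @param k Number of synergies, 1..8 and at most `ncol(M)`.
#' @param seed Integer seed for the restart initializations.
#' @param n_restarts Number of random restarts (default 10).
#' @param tol Convergence tolerance on the relative-error change (default
#'   1e-6).
#' @param max_iter Iteration cap per restart (default 2000).
#' @return Object of class `SynergySet`: `W`, `C`, `k`, `vaf_overall`,
#'   `vaf_per_muscle`, `restarts_used`, `seed`.
#' @export
nnmf <- function(M, k, seed = 1L, n_restarts = 10L, tol = 1e-6,
                 max_iter = 2000L) {
  if (inherits(M, "BinnedEmgMatrix")) M <- M$matrix
  M <- as.matrix(M)
  if (any(M < 0)) stop("activation matrix must be non-negative")
  if (k < 1 || k > 8) stop("k must lie in 1..8")
  if (ncol(M) < k) stop("k must not exceed the number of time bins")
  set.seed(seed)
  best <- NULL
  best_vaf <- -Inf
  for (r in seq_len(n_restarts)) {
    fit <- nnmf_once(M, k, tol, max_iter)
    v <- vaf(M, fit$W, fit$C)
    if (v$overall > best_vaf) {
      best_vaf <- v$overall
      best <- fit
    }
  }
  nc <- normalize_columns(best$W, best$C)
  v <- vaf(M, nc$W, nc$C)
  rownames(nc$W) <- rownames(M)
  structure(list(W = nc$W, C = nc$C, k = as.integer(k),
                 vaf_overall = v$overall, vaf_per_muscle = v$per_muscle,
                 restarts_used = as.integer(n_restarts), seed = as.integer(seed)),
            class = "SynergySet")
}

#' @export
print.SynergySet <- function(x, ...) {
  cat(sprintf("<SynergySet> k = %d, overall VAF = %.2f%%, per-muscle VAF range %.1f-%.1f%%\n",
              x$k, x$vaf_overall, min(x$vaf_per_muscle), max(x$vaf_per_muscle)))
  invisible(x)
}

#' Select the number of synergies by the dual VAF rule
#'
#' Ascends `k = 1..8` and returns the smallest `k` whose best factorization
#' exceeds the overall VAF threshold (default 90%) while every muscle's VAF
#' exceeds the per-muscle threshold (default 75%; the conservative
#' validation variant raises it to 80%).  Each `k` is fit afresh (no warm
#' starts across `k`).  If no `k` up to 8 satisfies both criteria the
#' full-order fit is returned with `criteria_met = FALSE`.
#'
#' @param M 8 x n non-negative matrix.
#' @param overall_thresh Overall VAF threshold in percent (default 90).
#' @param per_muscle_thresh Per-muscle VAF threshold in percent (default 75).
#' @param ... Passed to [nnmf()] (`seed`, `n_restarts`, `tol`, `max_iter`).
#' @return List with `k` and `fit` (the selected `SynergySet`, which carries
#'   `criteria_met`).
#' @export
select_num_synergies <- function(M, overall_thresh = 90,
                                 per_muscle_thresh = 75, ...) {
  stopifnot(overall_thresh >= 0, overall_thresh <= 100,
            per_muscle_thresh >= 0, per_muscle_thresh <= 100)
  if (inherits(M, "BinnedEmgMatrix")) M <- M$matrix
  k_max <- min(8L, ncol(M))
  fit <- NULL
  for (k in seq_len(k_max)) {
    fit <- nnmf(M, k, ...)
    ok <- fit$vaf_overall > overall_thresh &&
      all(fit$vaf_per_muscle > per_muscle_thresh, na.rm = TRUE)
    if (ok) {
      fit$criteria_met <- TRUE
      return(list(k = k, fit = fit))
    }
  }
  fit$criteria_met <- FALSE
  list(k = k_max, fit = fit)
}

#' Major contributing muscles of each synergy
#'
#' A muscle is a major contributor to a synergy when its weight in the
#' max-normalized weight column exceeds the threshold (default 0.4, strict
#' inequality).
#'
#' @param W 8 x k max-normalized weight matrix.
#' @param threshold Contribution threshold in (0, 1].
#' @return List of length k; element i holds the muscle indices (named when
#'   W has rownames) contributing to synergy i.
#' @export
major_contributors <- function(W, threshold = 0.4) {
  stopifnot(threshold > 0, threshold <= 1)
  lapply(seq_len(ncol(W)), function(j) which(W[, j] > threshold))
}

#' Peak value, peak time and recruitment order of coefficient traces
#'
#' For each synergy's recruitment coefficient row: the peak value, the peak
#' time taken as the center of the argmax bin (in seconds from the window
#' start), and the recruitment order by ascending peak time (ties broken by
#' synergy index).  All-zero rows get a missing peak time and are ordered
#' last.
#'
#' @param C k x n_bins non-negative coefficient matrix.
#' @param bin_ms Bin width in milliseconds.
#' @return Data frame with columns `synergy`, `peak`, `peak_time_s`,
#'   `order`.
#' @export
recruitment_metrics <- function(C, bin_ms) {
  if (any(C < 0)) stop("coefficients must be non-negative")
  k <- nrow(C)
  peak <- apply(C, 1, max)
  peak_time <- vapply(seq_len(k), function(i) {
    if (peak[i] == 0) return(NA_real_)
    (which.max(C[i, ]) - 0.5) * bin_ms / 1000
  }, numeric(1))
  ord_time <- ifelse(is.na(peak_time), Inf, peak_time)
  ord <- order(ord_time, seq_len(k))
  rank <- integer(k)
  rank[ord] <- seq_len(k)
  data.frame(synergy = seq_len(k), peak = peak, peak_time_s = peak_time,
             order = rank)
}
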