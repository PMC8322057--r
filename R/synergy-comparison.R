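#' Pearson similarity between two synergy weight vectors
#'
#' @param w_a,w_b Numeric length-8 weight vectors.
#' @return Pearson correlation coefficient.
#' @export
synergy_similarity <- function(w_a, w_b) {
  if (length(w_a) != length(w_b))
    stop("weight vectors must have equal length")
  if (sd(w_a) == 0 || sd(w_b) == 0)
    stop("similarity undefined for a zero-variance weight vector")
  cor(w_a, w_b)
}

#' Critical Pearson correlation for a given significance level
#'
#' The two-sided critical value of r for `n_points` paired observations:
#' `r_crit = t_crit / sqrt(df + t_crit^2)` with `df = n_points - 2` and
#' `t_crit` the two-sided alpha quantile of Student's t.  With 8 muscles
#' per weight vector and alpha = 0.01 this gives the r > 0.834 similarity
#' criterion.
#'
#' @param n_points Number of paired observations (8 muscles by default).
#' @param alpha Significance level (default 0.01).
#' @param two_sided Two-sided test (default TRUE).
#' @return The critical correlation.
#' @export
critical_r <- function(n_points = 8, alpha = 0.01, two_sided = TRUE) {
  if (n_points < 3) stop("n_points must be at least 3")
  stopifnot(alpha > 0, alpha <= 1)
  df <- n_points - 2
  p <- if (two_sided) 1 - alpha / 2 else 1 - alpha
  t_crit <- qt(p, df)
  t_crit / sqrt(df + t_crit^2)
}

#' Benjamini-Yekutieli corrected significance level
#'
#' The fixed corrected level for a family of `m` comparisons under
#' arbitrary dependence: `alpha / sum(1/i, i = 1..m)`.  For m = 4 at
#' alpha = 0.05 this is 0.024.
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of comparisons.
#' @return Corrected per-comparison level.
#' @export
by_corrected_alpha <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / sum(1 / seq_len(m))
}

#' Merge synergies by non-negative least squares
#'
#' Expresses a target synergy as a non-negative linear combination of
#' source synergies: mixing weights minimize the squared error to the
#' target under a non-negativity constraint (NNLS), the merged vector is
#' max-normalized, and the fit is scored by Pearson r to the target.
#'
#' @param sources List (or 8 x m matrix) of source weight vectors, m >= 2.
#' @param target Length-8 target weight vector.
#' @param nonneg Use NNLS (default); `FALSE` gives the unconstrained
#'   least-squares variant for sensitivity checks.
#' @return Object of class `MergeResult`: `weights`, `merged`
#'   (max-normalized), `r`.
#' @export
merge_synergies <- function(sources, target, nonneg = TRUE) {
  A <- if (is.list(sources)) do.call(cbind, sources) else as.matrix(sources)
  if (ncol(A) < 2) stop("at least two source synergies are required")
  if (all(A == 0)) stop("all-zero source synergies")
  if (nonneg) {
    w <- pracma::lsqnonneg(A, as.numeric(target))$x
  } else {
    w <- as.numeric(qr.solve(A, as.numeric(target)))
  }
  merged <- as.numeric(A %*% w)
  if (max(merged) > 0) merged <- merged / max(merged)
  if (sd(merged) == 0) {
    # degenerate: the non-negativity constraint drives all mixing weights
    # to zero (target lies outside the source cone entirely); no structure
    # is explained, reported as r = 0 rather than an undefined correlation
    return(structure(list(weights = w, merged = merged, r = 0,
                          degenerate = TRUE), class = "MergeResult"))
  }
  structure(list(weights = w, merged = merged,
                 r = synergy_similarity(merged, target), degenerate = FALSE),
            class = "MergeResult")
}

#' Optimal matching of two centroid sets by total correlation
#'
#' Exact assignment (exhaustive over permutations; at most 8 synergies per
#' repertoire so the search is trivial) pairing each column of `A` with a
#' distinct column of `B` to maximize the summed Pearson r.  A greedy
#' best-first variant is available for parity with simpler practice.
#'
#' @param A,B 8 x kA and 8 x kB weight matrices (kA <= kB or vice versa;
#'   the smaller set is fully matched).
#' @param method `"exact"` (default) or `"greedy"`.
#' @return Data frame with `idx_a`, `idx_b`, `r` for each matched pair.
#' @export
match_synergies <- function(A, B, method = c("exact", "greedy")) {
  method <- match.arg(method)
  A <- as.matrix(A); B <- as.matrix(B)
  swap <- ncol(A) > ncol(B)
  if (swap) { tmp <- A; A <- B; B <- tmp }
  R <- cor(A, B)  # kA x kB
  kA <- ncol(A); kB <- ncol(B)
  if (method == "exact") {
    best <- NULL; best_sum <- -Inf
    assign_rec <- function(i, used, picks, acc) {
      if (i > kA) {
        if (acc > best_sum) { best_sum <<- acc; best <<- picks }
        return(invisible(NULL))
      }
      # bound: remaining rows can add at most their row maxima
      bound <- acc + sum(apply(R[i:kA, !used, drop = FALSE], 1, max))
      if (bound <= best_sum) return(invisible(NULL))
      for (j in which(!used)) {
        used[j] <- TRUE
        assign_rec(i + 1L, used, c(picks, j), acc + R[i, j])
        used[j] <- FALSE
      }
    }
    assign_rec(1L, rep(FALSE, kB), integer(0), 0)
    picks <- best
  } else {
    picks <- integer(kA)
    used <- rep(FALSE, kB)
    for (step in seq_len(kA)) {
      Rm <- R
      Rm[picks[picks > 0], ] <- -Inf
      Rm[, used] <- -Inf
      ij <- which(Rm == max(Rm), arr.ind = TRUE)[1, ]
      picks[ij[1]] <- ij[2]
      used[ij[2]] <- TRUE
    }
  }
  out <- data.frame(idx_a = seq_len(kA), idx_b = picks,
                    r = R[cbind(seq_len(kA), picks)])
  if (swap) out <- data.frame(idx_a = out$idx_b, idx_b = out$idx_a, r = out$r)
  out
}

#' Build a similarity report between two clustered repertoires
#'
#' Matches centroids across two clusterings and reports per-pair Pearson r
#' with the similar/dissimilar call at the r threshold (default 0.834, the
#' p < 0.01 critical correlation for 8 muscles; `"auto"` recomputes it via
#' [critical_r()]).
#'
#' @param clusters_a,clusters_b `SynergyClustering` objects.
#' @param threshold Similarity threshold, numeric or `"auto"`.
#' @param context Free-text descriptor of the comparison.
#' @return Object of class `SimilarityReport`: data frame `pairs` with
#'   `label_a`, `label_b`, `r`, `similar`, plus `threshold` and `context`.
#' @export
similarity_report <- function(clusters_a, clusters_b, threshold = 0.834,
                              context = "") {
  if (identical(threshold, "auto")) threshold <- critical_r(8, 0.01)
  Ca <- vapply(clusters_a, `[[`, numeric(8), "centroid")
  Cb <- vapply(clusters_b, `[[`, numeric(8), "centroid")
  m <- match_synergies(Ca, Cb)
  pairs <- data.frame(
    label_a = vapply(clusters_a, `[[`, character(1), "label")[m$idx_a],
    label_b = vapply(clusters_b, `[[`, character(1), "label")[m$idx_b],
    r = m$r,
    similar = m$r > threshold
  )
  structure(list(pairs = pairs, threshold = threshold, context = context),
            class = "SimilarityReport")
}

#' @export
print.SimilarityReport <- function(x, ...) {
  cat(sprintf("<SimilarityReport> %s (threshold r > %.3f)\n",
              if (nzchar(x$context)) x$context else "centroid matching",
              x$threshold))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Cross-validate clustered synergies on an 80% subject subset
#'
#' Draws a random subset of ceiling(fraction * n) subjects, re-clusters
#' their already-extracted synergies, and matches the subset centroids to
#' the full-cohort centroids by optimal assignment.  Per-subject
#' factorizations are independent across subjects, so subsetting the cohort
#' leaves each subject's extraction unchanged and only the pooling and
#' clustering stage is recomputed.
#'
#' @param fits Named list (by subject) of selected `SynergySet` objects for
#'   one task.
#' @param fraction Subject fraction in (0, 1] (default 0.8).
#' @param seed Integer seed controlling subset membership.
#' @param bin_ms Bin width for peak-time bookkeeping.
#' @param task Task label.
#' @param threshold Similarity threshold for the report.
#' @return A `SimilarityReport`; attribute `subset` lists the sampled
#'   subjects.
#' @export
cross_validate <- function(fits, fraction = 0.8, seed = 1L, bin_ms = 15,
                           task = "voluntary", threshold = 0.834) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (length(fits) < 5) stop("cross-validation needs at least 5 subjects")
  full <- cluster_pool(synergy_pool(fits, bin_ms, task))
  set.seed(seed)
  n_sub <- ceiling(fraction * length(fits))
  keep <- sort(sample(names(fits), n_sub))
  sub <- cluster_pool(synergy_pool(fits[keep], bin_ms, task))
  rep <- similarity_report(full, sub, threshold = threshold,
                           context = sprintf("full vs %d%% subset", round(100 * fraction)))
  attr(rep, "subset") <- keep
  rep
}

#' Compare synergy repertoires across two bin widths
#'
#' Runs binning, normalization, extraction and clustering at each bin width
#' on the same conditioned recordings and matches the resulting centroids.
#'
#' @param cohort_fits_by_bin Named list: for each bin width (as character,
#'   e.g. `"15"`, `"28"`), a named list of per-subject selected
#'   `SynergySet`s.
#' @param task Task label.
#' @param threshold Similarity threshold.
#' @return A `SimilarityReport` between the two bin widths' clusterings.
#' @export
compare_bin_widths <- function(cohort_fits_by_bin, task = "voluntary",
                               threshold = 0.834) {
  bins <- names(cohort_fits_by_bin)
  if (length(bins) != 2) stop("exactly two bin widths are compared")
  cl <- lapply(bins, function(b) {
    cluster_pool(synergy_pool(cohort_fits_by_bin[[b]],
                              bin_ms = as.numeric(b), task = task))
  })
  similarity_report(cl[[1]], cl[[2]], threshold = threshold,
                    context = sprintf("bin %s ms vs %s ms", bins[1], bins[2]))
}

#' Cohen's d with pooled SD
#'
#' @param x,y Numeric samples.
#' @return The standardized mean difference `(mean(x) - mean(y)) / s_pooled`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Compare synergy counts between tasks and groups
#'
#' Thin wrappers over the standard routines: a paired Wilcoxon signed-rank
#' test across tasks within subjects, a Kruskal-Wallis test across groups,
#' and Cohen's d for the task contrast.
#'
#' @param k_voluntary,k_reactive Per-subject synergy counts (paired).
#' @param groups Optional group factor for the between-group test on
#'   `k_voluntary`.
#' @return List with `wilcoxon` (htest), `cohens_d`, and `kruskal` (htest or
#'   NULL).
#' @export
compare_synergy_counts <- function(k_voluntary, k_reactive, groups = NULL) {
  w <- suppressWarnings(wilcox.test(k_voluntary, k_reactive, paired = TRUE))
  kw <- if (!is.null(groups)) kruskal.test(k_voluntary, as.factor(groups)) else NULL
  list(wilcoxon = w, cohens_d = cohens_d(k_voluntary, k_reactive), kruskal = kw)
}
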