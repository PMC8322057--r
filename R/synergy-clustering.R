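#' Pool per-subject synergy vectors for clustering
#'
#' Collects the max-normalized weight columns of each subject's selected
#' factorization, together with the peak time of the matching recruitment
#' coefficient, into a flat pool for cross-subject clustering within a
#' task.
#'
#' @param fits Named list (by subject id) of `SynergySet` objects for one
#'   task.
#' @param bin_ms Bin width used for the coefficient matrices, in ms.
#' @param task Task label attached to the pool.
#' @return Object of class `SynergyPool`: data frame bookkeeping plus a
#'   `vectors` matrix (8 x n_entries).
#' @export
synergy_pool <- function(fits, bin_ms = 15, task = "voluntary") {
  entries <- list()
  vectors <- NULL
  for (sid in names(fits)) {
    fit <- fits[[sid]]
    rm <- recruitment_metrics(fit$C, bin_ms)
    for (j in seq_len(fit$k)) {
      entries[[length(entries) + 1L]] <- data.frame(
        subject_id = sid, task = task, synergy = j,
        peak_time_s = rm$peak_time_s[j])
      vectors <- cbind(vectors, fit$W[, j])
    }
  }
  info <- do.call(rbind, entries)
  colnames(vectors) <- paste(info$subject_id, info$synergy, sep = ".")
  structure(list(info = info, vectors = vectors, task = task),
            class = "SynergyPool")
}

# Subject-uniqueness predicate for one clustering assignment.
clusters_subject_unique <- function(assignment, subjects) {
  for (cl in unique(assignment)) {
    s <- subjects[assignment == cl]
    if (anyDuplicated(s)) return(FALSE)
  }
  TRUE
}

#' Cluster pooled synergy vectors under the subject-uniqueness rule
#'
#' Hierarchical agglomerative clustering on the correlation distance
#' `d = 1 - r` (Pearson between 8-muscle weight vectors), average linkage
#' by default.  The dendrogram is cut at the smallest number of clusters
#' for which no cluster contains two synergies from the same subject.
#' Clusters are labeled `MV1, MV2, ...` (voluntary) or `MR1, ...`
#' (reactive) in ascending mean member peak time; ties break by cluster
#' size (larger first), then lexical subject order.
#'
#' @param pool A [synergy_pool()].
#' @param linkage `hclust` agglomeration method (default `"average"`;
#'   `"complete"` is the common alternative).
#' @return List of `SynergyCluster` objects, each with `label`, `members`
#'   (info rows), `vectors`, `centroid` (max-normalized mean vector),
#'   `mean_peak_time`, `member_similarities`.  Attribute `n_clusters`
#'   records the cut; attribute `degenerate` flags the fallback to
#'   singletons when a subject contributes indistinguishable vectors.
#' @export
cluster_pool <- function(pool, linkage = "average") {
  stopifnot(inherits(pool, "SynergyPool"))
  n <- ncol(pool$vectors)
  subjects <- pool$info$subject_id
  degenerate <- FALSE
  if (n == 1L) {
    assignment <- 1L
  } else {
    d <- as.dist(1 - cor(pool$vectors))
    tree <- hclust(d, method = linkage)
    assignment <- NULL
    for (ncl in seq_len(n)) {
      a <- cutree(tree, k = ncl)
      if (clusters_subject_unique(a, subjects)) {
        assignment <- a
        break
      }
    }
    if (is.null(assignment)) {
      assignment <- seq_len(n)  # unreachable for distinct vectors, kept as guard
    }
    if (max(assignment) == n && n > length(unique(subjects))) degenerate <- TRUE
  }
  prefix <- if (pool$task == "reactive") "MR" else "MV"
  clusters <- lapply(sort(unique(assignment)), function(cl) {
    idx <- which(assignment == cl)
    vecs <- pool$vectors[, idx, drop = FALSE]
    centroid <- rowMeans(vecs)
    centroid <- centroid / max(centroid)
    sims <- as.numeric(cor(vecs, centroid))
    structure(list(
      members = pool$info[idx, , drop = FALSE],
      vectors = vecs,
      centroid = centroid,
      mean_peak_time = mean(pool$info$peak_time_s[idx], na.rm = TRUE),
      member_similarities = sims,
      singleton = length(idx) == 1L
    ), class = "SynergyCluster")
  })
  sizes <- vapply(clusters, function(cl) nrow(cl$members), integer(1))
  first_subj <- vapply(clusters, function(cl) min(cl$members$subject_id), character(1))
  ord <- order(vapply(clusters, `[[`, numeric(1), "mean_peak_time"),
               -sizes, first_subj)
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$label <- paste0(prefix, i)
  structure(clusters, n_clusters = length(clusters), degenerate = degenerate,
            task = pool$task, class = "SynergyClustering")
}

#' @export
print.SynergyClustering <- function(x, ...) {
  cat(sprintf("<SynergyClustering> %d clusters (%s)\n",
              attr(x, "n_clusters"), attr(x, "task")))
  for (cl in x) {
    cat(sprintf("  %s: %d members, mean peak %.3f s\n",
                cl$label, nrow(cl$members), cl$mean_peak_time))
  }
  invisible(x)
}

#' Per-cluster recruitment prevalence
#'
#' Reports how many of the cohort's subjects express each clustered
#' synergy, as the `"x/n"` strings used beside repertoire figures.
#'
#' @param clusters A `SynergyClustering` from [cluster_pool()].
#' @param n_subjects Cohort size.
#' @return Data frame with `label`, `count`, `prevalence` (string).
#' @export
cluster_prevalence <- function(clusters, n_subjects) {
  data.frame(
    label = vapply(clusters, `[[`, character(1), "label"),
    count = vapply(clusters, function(cl) length(unique(cl$members$subject_id)),
                   integer(1)),
    prevalence = vapply(clusters, function(cl) {
      sprintf("%d/%d", length(unique(cl$members$subject_id)), n_subjects)
    }, character(1))
  )
}

#' Similarity of cluster members to their centroid
#'
#' Pearson r of each member synergy vector against the full-cluster
#' centroid (not leave-one-out), summarized as mean and SD.  Singleton
#' clusters give r = 1 by construction and are flagged degenerate.
#'
#' @param cluster A `SynergyCluster`.
#' @return List with `r` (per member), `mean`, `sd`, `degenerate`.
#' @export
member_centroid_similarity <- function(cluster) {
  stopifnot(inherits(cluster, "SynergyCluster"))
  r <- cluster$member_similarities
  list(r = r, mean = mean(r), sd = if (length(r) > 1) sd(r) else 0,
       degenerate = length(r) == 1L)
}
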