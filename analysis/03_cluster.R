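#!/usr/bin/env Rscript
# Pool per-subject synergies within each task and group them by
# hierarchical clustering (distance 1 - r, average linkage), cutting the
# dendrogram at the smallest cluster count with no two same-subject
# members.  Writes the per-task repertoire tables (centroids, prevalence,
# member-centroid similarity).

library(stepsynergy)

syn_dir <- "results/synergies"
n_subjects <- 10

for (task in c("voluntary", "reactive")) {
  files <- list.files(syn_dir, pattern = paste0("_", task, "\\.json$"),
                      full.names = TRUE)
  fits <- lapply(files, read_synergy_set)
  names(fits) <- sub(paste0("_", task, ".json"), "", basename(files))
  clusters <- cluster_pool(synergy_pool(fits, bin_ms = 15, task = task))
  write_cluster_report(clusters, n_subjects,
                       sprintf("results/clusters_%s.csv", task))
  prev <- cluster_prevalence(clusters, n_subjects)
  cat(sprintf("%s stepping: %d clustered synergies\n", task, length(clusters)))
  for (i in seq_along(clusters)) {
    sim <- member_centroid_similarity(clusters[[i]])
    cat(sprintf("  %s  recruited by %s  mean peak %.3f s  member r %.2f +/- %.2f\n",
                prev$label[i], prev$prevalence[i],
                clusters[[i]]$mean_peak_time, sim$mean, sim$sd))
  }
}
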