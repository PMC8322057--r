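#' Write a synthetic cohort to delimited text files
#'
#' One wide tab-delimited file per trial (`time_s` plus the 8 channel
#' columns), a JSON sidecar per trial with subject, task, side, events and
#' sampling rate, and one JSON ground-truth bundle for the cohort.
#'
#' @param cohort A `SyntheticCohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (key in names(cohort$recordings)) {
    rec <- cohort$recordings[[key]]
    t <- (seq_len(ncol(rec$samples)) - 1) / rec$sampling_rate
    df <- data.frame(time_s = t, t(rec$samples))
    colnames(df) <- c("time_s", rec$channels)
    f_data <- file.path(dir, paste0(key, ".tsv"))
    write.table(df, f_data, sep = "\t", row.names = FALSE, quote = FALSE)
    meta <- list(subject = rec$subject_id, task = rec$task, side = rec$side,
                 sampling_rate = rec$sampling_rate,
                 PON = rec$events$PON, LO = rec$events$LO, TD = rec$events$TD,
                 conditioned = rec$conditioned)
    f_meta <- file.path(dir, paste0(key, ".json"))
    jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, f_data, f_meta)
  }
  gt <- lapply(cohort$ground_truth, function(g) {
    list(W_voluntary = unname(g$W$voluntary), W_reactive = unname(g$W$reactive))
  })
  f_gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, f_gt, digits = NA)
  invisible(c(paths, f_gt))
}

#' Read one trial written by [write_cohort()]
#'
#' @param data_path Path to the `.tsv` trial file (the `.json` sidecar is
#'   expected alongside).
#' @return An [emg_recording()].
#' @export
read_trial <- function(data_path) {
  meta_path <- sub("\\.tsv$", ".json", data_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- read.table(data_path, header = TRUE, sep = "\t", check.names = FALSE)
  samples <- t(as.matrix(df[, -1]))
  emg_recording(meta$subject, meta$task, meta$side, meta$sampling_rate,
                samples,
                events = list(PON = meta$PON, LO = meta$LO, TD = meta$TD),
                channels = colnames(df)[-1],
                conditioned = isTRUE(meta$conditioned))
}

#' Read a cohort directory back into recordings
#'
#' @param dir Directory written by [write_cohort()].
#' @return Named list of [emg_recording()] objects.
#' @export
read_cohort_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  recs <- lapply(files, read_trial)
  names(recs) <- sub("\\.tsv$", "", basename(files))
  recs
}

#' Write a synergy set as JSON
#'
#' @param fit A `SynergySet`.
#' @param path Output path.
#' @export
write_synergy_set <- function(fit, path) {
  stopifnot(inherits(fit, "SynergySet"))
  jsonlite::write_json(list(
    k = fit$k, W = unname(fit$W), C = unname(fit$C),
    vaf_overall = fit$vaf_overall,
    vaf_per_muscle = unname(fit$vaf_per_muscle),
    restarts_used = fit$restarts_used, seed = fit$seed,
    muscles = rownames(fit$W)
  ), path, digits = NA)
  invisible(path)
}

#' Read a synergy set written by [write_synergy_set()]
#'
#' @param path JSON path.
#' @return A `SynergySet`.
#' @export
read_synergy_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(unlist(x$W), nrow = 8)
  rownames(W) <- x$muscles
  structure(list(W = W, C = matrix(unlist(x$C), nrow = x$k),
                 k = as.integer(x$k), vaf_overall = x$vaf_overall,
                 vaf_per_muscle = x$vaf_per_muscle,
                 restarts_used = x$restarts_used, seed = x$seed),
            class = "SynergySet")
}

#' Write a cluster report as CSV
#'
#' One row per cluster: label, member count, prevalence, mean peak time and
#' member-to-centroid similarity summary, followed by the centroid weights.
#'
#' @param clusters A `SynergyClustering`.
#' @param n_subjects Cohort size for the prevalence strings.
#' @param path Output CSV path.
#' @export
write_cluster_report <- function(clusters, n_subjects, path) {
  prev <- cluster_prevalence(clusters, n_subjects)
  sims <- lapply(clusters, member_centroid_similarity)
  cents <- t(vapply(clusters, `[[`, numeric(8), "centroid"))
  colnames(cents) <- canonical_muscles()
  df <- cbind(prev,
              mean_peak_time_s = vapply(clusters, `[[`, numeric(1), "mean_peak_time"),
              member_r_mean = vapply(sims, `[[`, numeric(1), "mean"),
              member_r_sd = vapply(sims, `[[`, numeric(1), "sd"),
              cents)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
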