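#' Pipeline configuration
#'
#' Bundles the analysis constants: bin width, the dual VAF thresholds
#' (overall 90%, per-muscle 75% with the conservative 80% variant), the
#' 0.4 major-contributor threshold, the similarity threshold (0.834, or
#' `"auto"` to recompute the p < 0.01 critical correlation for 8 muscles),
#' the number of NNMF restarts and the seed.
#'
#' @param bin_ms Bin width in ms (15 or 28).
#' @param overall_vaf Overall VAF threshold (percent).
#' @param per_muscle_vaf Per-muscle VAF threshold (percent).
#' @param contributor_threshold Major-contributor weight threshold.
#' @param similarity_threshold Numeric r threshold or `"auto"`.
#' @param restarts NNMF restarts.
#' @param seed Integer seed.
#' @return Object of class `PipelineConfig`.
#' @export
pipeline_config <- function(bin_ms = 15, overall_vaf = 90, per_muscle_vaf = 75,
                            contributor_threshold = 0.4,
                            similarity_threshold = 0.834,
                            restarts = 10L, seed = 1L) {
  stopifnot(bin_ms > 0, overall_vaf > 0, overall_vaf <= 100,
            per_muscle_vaf > 0, per_muscle_vaf <= 100,
            contributor_threshold > 0, contributor_threshold <= 1,
            restarts >= 1)
  if (!identical(similarity_threshold, "auto"))
    stopifnot(similarity_threshold > -1, similarity_threshold < 1)
  structure(list(bin_ms = bin_ms, overall_vaf = overall_vaf,
                 per_muscle_vaf = per_muscle_vaf,
                 contributor_threshold = contributor_threshold,
                 similarity_threshold = similarity_threshold,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration
#'
#' JSON round-trip for configurations (YAML also supported for reading when
#' the yaml package is installed).
#'
#' @param config A `PipelineConfig`.
#' @param path File path (`.json` or `.yaml`).
#' @return `read_config()` returns a `PipelineConfig`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configurations")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals)
}

#' Condition, bin, normalize and factorize one subject's trials
#'
#' Runs the full per-subject chain: envelope conditioning of the two
#' voluntary trials and the reactive trial, bin averaging over each trial's
#' PON-TD window, normalization to the voluntary maxima plus unit-variance
#' scaling, and dual-VAF model-order selection on the analyzed voluntary
#' trial (same stepping side as the reactive trial) and the reactive trial.
#' Extracted weights are returned both on the unit-variance scale and with
#' the scaling inverted ([invert_scaling()] then column max-normalization).
#'
#' @param recs List of the subject's recordings (two voluntary, one
#'   reactive).
#' @param config A [pipeline_config()].
#' @param bin_ms Optional override of `config$bin_ms`.
#' @return List with `voluntary` and `reactive`, each holding `k`, `fit`
#'   (`SynergySet` on the unit-variance scale), `W_original` (weights on
#'   the normalized-activation scale, columns max 1), `W_envelope` (both
#'   scaling steps inverted, i.e. on the raw envelope scale, columns max 1
#'   -- directly comparable to generator ground truth) and `binned` (the
#'   `BinnedEmgMatrix`).
#' @export
extract_subject <- function(recs, config = pipeline_config(), bin_ms = NULL) {
  bin_ms <- bin_ms %||% config$bin_ms
  tasks <- vapply(recs, `[[`, character(1), "task")
  sides <- vapply(recs, `[[`, character(1), "side")
  vol_idx <- which(tasks == "voluntary")
  rea_idx <- which(tasks == "reactive")
  if (length(vol_idx) != 2 || length(rea_idx) != 1)
    stop("expected two voluntary trials and one reactive trial per subject")
  analyzed_vol <- vol_idx[sides[vol_idx] == sides[rea_idx]][1]
  if (is.na(analyzed_vol)) analyzed_vol <- vol_idx[1]
  cond <- lapply(recs, condition_emg)
  binned <- lapply(cond, function(rec) {
    bin_average(rec$samples, rec$sampling_rate,
                c(rec$events$PON, rec$events$TD), bin_ms)
  })
  scaled <- normalize_and_scale(binned[vol_idx], binned[rea_idx])
  names(scaled) <- c(names(recs)[vol_idx], names(recs)[rea_idx])
  sel <- list(voluntary = scaled[[which(vol_idx == analyzed_vol)]],
              reactive = scaled[[3]])
  lapply(sel, function(bm) {
    res <- select_num_synergies(bm$matrix,
                                overall_thresh = config$overall_vaf,
                                per_muscle_thresh = config$per_muscle_vaf,
                                seed = config$seed,
                                n_restarts = config$restarts)
    W_orig <- invert_scaling(res$fit$W, bm$row_sds)
    W_orig <- sweep(W_orig, 2, apply(W_orig, 2, max), "/")
    W_env <- invert_scaling(res$fit$W, bm$row_sds) * bm$row_max_divisors
    W_env <- sweep(W_env, 2, apply(W_env, 2, max), "/")
    list(k = res$k, fit = res$fit, W_original = W_orig, W_envelope = W_env,
         binned = bm)
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> condition/bin/normalize -> extract (dual-VAF selection) ->
#' pool and cluster per task -> task-similarity report and 80% subset
#' cross-validation.  When `out` is given, artifacts (synergy JSONs,
#' cluster CSVs, similarity CSV, run log with the configuration and seed)
#' are written there.
#'
#' @param spec A [synthetic_spec()]; its seed drives the simulation.
#' @param config A [pipeline_config()]; its seed drives extraction and
#'   subsetting.
#' @param out Optional artifact directory.
#' @return List with `cohort`, `subject_results`, `fits` (per task),
#'   `clusters` (per task), `task_report`, `cv_report`, `config`.
#' @export
run_pipeline <- function(spec = synthetic_spec(), config = pipeline_config(),
                         out = NULL) {
  t0 <- Sys.time()
  cohort <- generate_cohort(spec)
  subjects <- names(cohort$ground_truth)
  subject_results <- lapply(subjects, function(sid) {
    recs <- cohort$recordings[grep(paste0("^", sid, "_"), names(cohort$recordings))]
    extract_subject(recs, config)
  })
  names(subject_results) <- subjects
  fits <- list(
    voluntary = lapply(subject_results, function(r) r$voluntary$fit),
    reactive = lapply(subject_results, function(r) r$reactive$fit)
  )
  clusters <- list(
    voluntary = cluster_pool(synergy_pool(fits$voluntary, config$bin_ms, "voluntary")),
    reactive = cluster_pool(synergy_pool(fits$reactive, config$bin_ms, "reactive"))
  )
  thr <- if (identical(config$similarity_threshold, "auto"))
    critical_r(8, 0.01) else config$similarity_threshold
  task_report <- similarity_report(clusters$voluntary, clusters$reactive,
                                   threshold = thr,
                                   context = "voluntary vs reactive")
  cv_report <- cross_validate(fits$voluntary, fraction = 0.8,
                              seed = config$seed, bin_ms = config$bin_ms,
                              task = "voluntary", threshold = thr)
  res <- list(cohort = cohort, subject_results = subject_results,
              fits = fits, clusters = clusters, task_report = task_report,
              cv_report = cv_report, config = config)
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    for (task in names(fits)) {
      for (sid in names(fits[[task]])) {
        write_synergy_set(fits[[task]][[sid]],
                          file.path(out, sprintf("synergies_%s_%s.json", task, sid)))
      }
      write_cluster_report(clusters[[task]], spec$n_subjects,
                           file.path(out, sprintf("clusters_%s.csv", task)))
    }
    write.csv(task_report$pairs, file.path(out, "task_similarity.csv"),
              row.names = FALSE)
    write.csv(cv_report$pairs, file.path(out, "cross_validation.csv"),
              row.names = FALSE)
    log <- list(config = unclass(config), spec_seed = spec$seed,
                n_subjects = spec$n_subjects,
                similarity_threshold_used = thr,
                package_version = as.character(utils::packageVersion("stepsynergy")),
                elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(log, file.path(out, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
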