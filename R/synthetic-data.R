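#' Default voluntary-stepping synergy templates
#'
#' Four sparse 8-muscle synergy templates loosely modeled on the synergy
#' compositions reported for voluntary backward stepping: an ankle push-off
#' synergy dominated by stepping GAS with stance TA, a swing-initiation
#' synergy (stepping TA/BFLH with stance GAS/VLAT), a stepping-knee synergy
#' (stepping VLAT with stance BFLH) and a stance-loading synergy (stance
#' GAS/VLAT).  Columns are max-normalized to 1.  Each template holds exact
#' zeros for the muscles silent in that synergy: together with recruitment
#' bursts that have exclusive time support, this makes the planted
#' factorization identifiable (a strictly positive weight/coefficient pair
#' admits a continuum of exact factorizations, so recovery would be
#' ill-posed without the zeros).  Every muscle is active in at least one
#' synergy, so no channel is dead.
#'
#' @return 8 x 4 non-negative matrix, rownames = [canonical_muscles()],
#'   each column maximum exactly 1.
#' @export
default_voluntary_templates <- function() {
  W <- cbind(
    c(0.15, 0.00, 1.00, 0.00, 0.80, 0.00, 0.00, 0.10),
    c(1.00, 0.70, 0.00, 0.00, 0.00, 0.00, 0.60, 0.45),
    c(0.00, 0.15, 0.00, 1.00, 0.00, 0.80, 0.00, 0.00),
    c(0.00, 0.30, 0.00, 0.00, 0.15, 0.00, 1.00, 0.70)
  )
  rownames(W) <- canonical_muscles()
  colnames(W) <- paste0("V", seq_len(ncol(W)))
  W
}

#' Default reactive-stepping synergy templates
#'
#' Two broad co-activation templates emulating the widespread muscle
#' recruitment of protective stepping after a slip-like perturbation: each
#' template loads more than five muscles above the 0.4 major-contributor
#' threshold, with exact zeros on its silent muscles for identifiability.
#'
#' @return 8 x 2 non-negative matrix, each column maximum exactly 1.
#' @export
default_reactive_templates <- function() {
  W <- cbind(
    c(1.00, 0.85, 0.70, 0.45, 0.90, 0.00, 0.00, 0.75),
    c(0.00, 0.45, 0.90, 1.00, 0.00, 0.85, 0.95, 0.50)
  )
  rownames(W) <- canonical_muscles()
  colnames(W) <- paste0("R", seq_len(ncol(W)))
  W
}

#' Specification for a synthetic stepping-EMG cohort
#'
#' Defines the generative model \code{M = W \%*\% C + noise} for a cohort of
#' subjects, each contributing two voluntary stepping trials (one per
#' stepping side) and one reactive stepping trial.  Per-subject weight
#' matrices are jittered copies of the task templates; recruitment
#' coefficients are truncated Gaussian bursts spanning the reaction plus
#' execution window.
#'
#' Default event timings use mean young-adult step-phase durations: a
#' voluntary reaction period of 490 ms with a 270 ms execution period, and a
#' reactive reaction period of 210 ms with a 155 ms execution period.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param true_synergies 8 x k_true non-negative template matrix for
#'   voluntary trials, each column max-normalized to 1.
#' @param true_synergies_reactive Optional template matrix for reactive
#'   trials; defaults to `true_synergies` (same synergies in both tasks).
#' @param trial_duration Trial length in seconds.
#' @param sampling_rate EMG sampling rate in Hz (default 1200).
#' @param noise_sd Additive Gaussian noise SD as a fraction of the trial's
#'   peak clean signal (default 0.05).
#' @param subject_jitter_sd SD of additive Gaussian jitter applied to the
#'   template weights per subject (default 0.05).
#' @param pon Perturbation / cue onset in seconds from trial start.
#' @param voluntary_reaction,voluntary_execution,reactive_reaction,reactive_execution
#'   Step-phase durations in seconds.
#' @param burst_width_frac Burst SD as a fraction of the inter-burst spacing
#'   (default 0.25; bursts are truncated at 2 SD, so at the default the
#'   supports of adjacent bursts exactly touch and every synergy has
#'   exclusive time bins -- a prerequisite for unique recovery).
#' @param seed Integer seed; identical specs and seeds give byte-identical
#'   cohorts.
#' @return Object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_subjects = 10,
                           true_synergies = default_voluntary_templates(),
                           true_synergies_reactive = NULL,
                           trial_duration = 2,
                           sampling_rate = 1200,
                           noise_sd = 0.05,
                           subject_jitter_sd = 0.05,
                           pon = 0.5,
                           voluntary_reaction = 0.49,
                           voluntary_execution = 0.27,
                           reactive_reaction = 0.21,
                           reactive_execution = 0.155,
                           burst_width_frac = 0.25,
                           seed = 1L) {
  stopifnot(n_subjects >= 1, trial_duration > 0, sampling_rate > 0,
            burst_width_frac > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (subject_jitter_sd < 0) stop("subject_jitter_sd must be non-negative")
  check_templates <- function(W, what) {
    if (any(W < 0)) stop(what, " templates must be non-negative")
    if (nrow(W) != 8L) stop(what, " templates must have 8 rows")
    if (ncol(W) > 8L) stop("number of true synergies must not exceed 8")
    if (any(abs(apply(W, 2, max) - 1) > 1e-9))
      stop(what, " template columns must be max-normalized to 1")
  }
  check_templates(true_synergies, "voluntary")
  if (is.null(true_synergies_reactive)) true_synergies_reactive <- true_synergies
  check_templates(true_synergies_reactive, "reactive")
  dur <- list(voluntary = voluntary_reaction + voluntary_execution,
              reactive = reactive_reaction + reactive_execution)
  for (task in names(dur)) {
    if (pon + dur[[task]] >= trial_duration)
      stop("events exceed trial duration for task ", task)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    muscles = canonical_muscles(),
    true_synergies = true_synergies,
    true_synergies_reactive = true_synergies_reactive,
    trial_duration = trial_duration,
    sampling_rate = sampling_rate,
    noise_sd = noise_sd,
    subject_jitter_sd = subject_jitter_sd,
    pon = pon,
    reaction = list(voluntary = voluntary_reaction, reactive = reactive_reaction),
    execution = list(voluntary = voluntary_execution, reactive = reactive_execution),
    burst_width_frac = burst_width_frac,
    seed = as.integer(seed)
  ), class = "SyntheticSpec")
}

#' Construct an EMG recording object
#'
#' @param subject_id Subject identifier.
#' @param task `"voluntary"` or `"reactive"`.
#' @param side Stepping side, `"left"` or `"right"`.
#' @param sampling_rate Sampling rate in Hz.
#' @param samples 8 x T numeric matrix (channels x samples).
#' @param events Named list with `PON`, `LO`, `TD` in seconds from trial
#'   start; must satisfy PON < LO < TD and lie within the trial.
#' @param channels Channel labels; defaults to [canonical_muscles()].
#' @param conditioned `TRUE` when `samples` already hold a rectified
#'   activation envelope rather than raw interference EMG (synthetic
#'   cohorts generate the envelope directly); [condition_emg()] then skips
#'   the raw-signal high-pass stage.
#' @return Object of class `EmgRecording`.
#' @export
emg_recording <- function(subject_id, task, side, sampling_rate, samples,
                          events, channels = canonical_muscles(),
                          conditioned = FALSE) {
  task <- match.arg(task, c("voluntary", "reactive"))
  side <- match.arg(side, c("left", "right"))
  samples <- as.matrix(samples)
  if (nrow(samples) != 8L) stop("EMG recordings must have exactly 8 channels")
  if (length(channels) != 8L) stop("exactly 8 channel labels required")
  ev <- events
  if (!(ev$PON < ev$LO && ev$LO < ev$TD))
    stop("event times must satisfy PON < LO < TD")
  t_end <- ncol(samples) / sampling_rate
  if (ev$PON < 0 || ev$TD > t_end)
    stop("event times must lie within the trial")
  rownames(samples) <- channels
  structure(list(subject_id = subject_id, task = task, side = side,
                 sampling_rate = sampling_rate, channels = channels,
                 samples = samples,
                 events = list(PON = ev$PON, LO = ev$LO, TD = ev$TD),
                 conditioned = isTRUE(conditioned)),
            class = "EmgRecording")
}

#' @export
print.EmgRecording <- function(x, ...) {
  cat(sprintf("<EmgRecording> subject %s, %s step (%s side), %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$task, x$side, nrow(x$samples), ncol(x$samples),
              x$sampling_rate))
  cat(sprintf("  events: PON=%.3fs LO=%.3fs TD=%.3fs\n",
              x$events$PON, x$events$LO, x$events$TD))
  invisible(x)
}

# Truncated-Gaussian burst coefficient traces over [PON, TD]; k rows x T
# cols.  Each burst is a Gaussian with its tail beyond 2 SD subtracted off
# (so it reaches zero smoothly at the truncation boundary and bursts have
# exclusive time support when width = spacing/4), renormalized to peak 1.
burst_coefficients <- function(k, times, pon, td, width_frac, trunc_sd = 2) {
  span <- td - pon
  centers <- pon + span * (seq_len(k) - 0.5) / k
  spacing <- span / k
  width <- width_frac * spacing
  floor_val <- exp(-trunc_sd^2 / 2)
  C <- matrix(0, k, length(times))
  inside <- times >= pon & times <= td
  for (i in seq_len(k)) {
    g <- exp(-(times[inside] - centers[i])^2 / (2 * width^2))
    C[i, inside] <- pmax(0, g - floor_val) / (1 - floor_val)
  }
  C
}

# Jitter template weights for one subject: additive Gaussian, absolute
# value, column re-normalized to max 1.
jitter_weights <- function(W, jitter_sd) {
  Wj <- abs(W + matrix(rnorm(length(W), sd = jitter_sd), nrow(W), ncol(W)))
  sweep(Wj, 2, apply(Wj, 2, max), "/")
}

#' Generate a synthetic stepping-EMG cohort
#'
#' For each subject, draws a jittered per-subject weight matrix from the
#' task templates and synthesizes two voluntary trials (right then left
#' stepping side) and one reactive trial (right side) as non-negative
#' synergy mixtures plus additive Gaussian noise clipped at zero.  All
#' randomness derives from `spec$seed` through fixed per-subject offsets, so
#' cohorts are reproducible subject-by-subject.
#'
#' @param spec A [synthetic_spec()] object.
#' @return Object of class `SyntheticCohort`: list with `recordings` (list of
#'   [emg_recording()]), `ground_truth` (per subject: jittered weight
#'   matrices and coefficient traces per trial) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  fs <- spec$sampling_rate
  times <- seq(0, spec$trial_duration - 1 / fs, by = 1 / fs)
  trial_plan <- list(
    list(task = "voluntary", side = "right"),
    list(task = "voluntary", side = "left"),
    list(task = "reactive", side = "right")
  )
  recordings <- list()
  ground_truth <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%02d", s)
    set.seed(spec$seed + 1000L * s)
    W_sub <- list(
      voluntary = jitter_weights(spec$true_synergies, spec$subject_jitter_sd),
      reactive = jitter_weights(spec$true_synergies_reactive, spec$subject_jitter_sd)
    )
    gt_trials <- list()
    for (j in seq_along(trial_plan)) {
      tp <- trial_plan[[j]]
      pon <- spec$pon
      lo <- pon + spec$reaction[[tp$task]]
      td <- lo + spec$execution[[tp$task]]
      W <- W_sub[[tp$task]]
      C <- burst_coefficients(ncol(W), times, pon, td, spec$burst_width_frac)
      clean <- W %*% C
      noise_sd <- spec$noise_sd * max(clean)
      samples <- clean
      if (noise_sd > 0) {
        samples <- samples + matrix(rnorm(length(clean), sd = noise_sd),
                                    nrow(clean), ncol(clean))
      }
      samples[samples < 0] <- 0
      rec <- emg_recording(sid, tp$task, tp$side, fs, samples,
                           events = list(PON = pon, LO = lo, TD = td),
                           channels = spec$muscles, conditioned = TRUE)
      key <- paste(sid, tp$task, tp$side, sep = "_")
      recordings[[key]] <- rec
      gt_trials[[key]] <- list(W = W, C = C)
    }
    ground_truth[[sid]] <- list(W = W_sub, trials = gt_trials)
  }
  structure(list(recordings = recordings, ground_truth = ground_truth,
                 spec = spec),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("<SyntheticCohort> %d subjects, %d recordings, k_true = %d (voluntary) / %d (reactive)\n",
              x$spec$n_subjects, length(x$recordings),
              ncol(x$spec$true_synergies), ncol(x$spec$true_synergies_reactive)))
  invisible(x)
}

#' Generate a synthetic vertical foot-marker trace
#'
#' Produces a vertical-position time series that sits at a noisy baseline,
#' rises smoothly between a planted lift-off and touchdown (steep ramps at
#' both ends of a plateau), and returns to baseline, for exercising the
#' two-standard-deviation gait event detector.
#'
#' @param baseline_mm Baseline vertical position in mm.
#' @param lift_time,touchdown_time Planted lift-off and touchdown in seconds;
#'   `lift_time < touchdown_time`.
#' @param noise_sd Baseline noise SD in mm (0 allowed; the detector applies
#'   an SD floor).
#' @param seed Integer seed.
#' @param duration Trace duration in seconds (default covers the touchdown
#'   plus 0.5 s).
#' @param sampling_rate Samples per second (default 1200).
#' @param peak_mm Swing apex height above baseline in mm.
#' @param ramp_frac Fraction of the swing spent in each rise/fall ramp.
#' @return Data frame with columns `time_s` and `z_mm`; attributes `lift`,
#'   `touchdown`, `sampling_rate`.
#' @export
generate_marker_trace <- function(baseline_mm, lift_time, touchdown_time,
                                  noise_sd, seed = 1L,
                                  duration = touchdown_time + 0.5,
                                  sampling_rate = 1200,
                                  peak_mm = 80, ramp_frac = 0.15) {
  if (lift_time >= touchdown_time) stop("lift_time must precede touchdown_time")
  if (touchdown_time >= duration) stop("events must lie within the trace")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  z <- rep(baseline_mm, length(t))
  if (noise_sd > 0) z <- z + rnorm(length(t), sd = noise_sd)
  s <- (t - lift_time) / (touchdown_time - lift_time)
  bump <- numeric(length(t))
  in_swing <- s >= 0 & s <= 1
  sw <- s[in_swing]
  shape <- rep(1, length(sw))
  shape[sw < ramp_frac] <- sin(pi / 2 * sw[sw < ramp_frac] / ramp_frac)^2
  shape[sw > 1 - ramp_frac] <- sin(pi / 2 * (1 - sw[sw > 1 - ramp_frac]) / ramp_frac)^2
  bump[in_swing] <- peak_mm * shape
  out <- data.frame(time_s = t, z_mm = z + bump)
  attr(out, "lift") <- lift_time
  attr(out, "touchdown") <- touchdown_time
  attr(out, "sampling_rate") <- sampling_rate
  out
}
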