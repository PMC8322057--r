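#' Trapezoidal treadmill perturbation profile
#'
#' A slip-like belt translation with an acceleration phase (`t1` seconds at
#' `a` m/s^2), a constant-speed phase (`t2`) and a symmetric deceleration
#' phase (`t3`, decelerating at `a`).
#'
#' @param t1,t2,t3 Phase durations in seconds (non-negative).
#' @param a Acceleration magnitude in m/s^2 (non-negative).
#' @return Object of class `PerturbationProfile`.
#' @export
perturbation_profile <- function(t1, a, t2, t3) {
  stopifnot(t1 >= 0, t2 >= 0, t3 >= 0, a >= 0)
  structure(list(t1 = t1, a = a, t2 = t2, t3 = t3),
            class = "PerturbationProfile")
}

#' Peak velocity and displacement of a perturbation profile
#'
#' Peak velocity is `a * t1`; displacement is the integral of the
#' piecewise-linear speed profile,
#' `a*t1^2/2 + (a*t1)*t2 + (a*t1)*t3 - a*t3^2/2`.
#'
#' @param p A [perturbation_profile()].
#' @return List with `peak_velocity` (m/s) and `displacement` (m).
#' @export
profile_kinematics <- function(p) {
  stopifnot(inherits(p, "PerturbationProfile"))
  v <- p$a * p$t1
  disp <- 0.5 * p$a * p$t1^2 + v * p$t2 + v * p$t3 - 0.5 * p$a * p$t3^2
  list(peak_velocity = v, displacement = disp)
}

#' Low-pass filter a marker trace
#'
#' Zero-phase 4th-order Butterworth low-pass (6 Hz default), the standard
#' kinematic marker smoothing, applied before event detection.
#'
#' @param z Numeric trace.
#' @param sampling_rate Hz.
#' @param cutoff_hz Corner frequency (default 6).
#' @return Filtered trace.
#' @export
filter_marker <- function(z, sampling_rate, cutoff_hz = 6) {
  bf <- signal::butter(4, cutoff_hz / (sampling_rate / 2), type = "low")
  zero_phase_filter(z, bf$b, bf$a)
}

#' Detect lift-off and touchdown from a vertical foot-marker trace
#'
#' Lift-off (LO) is the first sample after the perturbation/cue onset where
#' the vertical position exceeds the quiet-stance baseline mean by more
#' than `threshold_sds` baseline standard deviations.  Touchdown (TD) is
#' the first sample after the post-LO swing apex where the trace re-enters
#' that baseline band (symmetric with the LO criterion).  An SD floor of
#' 1e-9 mm keeps the rule defined for noiseless traces.
#'
#' Because roughly 2% of baseline-noise samples exceed a 2-SD band by
#' chance, a threshold crossing only counts when at least 80% of the
#' following `min_hold_s` seconds also satisfy it; isolated noise spikes
#' are thereby rejected (and cannot postpone a genuine crossing) while a
#' true swing, always far longer than the hold, is detected at its first
#' crossing sample.
#'
#' @param trace Data frame with `time_s` and `z_mm` (as from
#'   [generate_marker_trace()]), or a numeric vector with `sampling_rate`
#'   supplied.
#' @param baseline_window Length-2 numeric, start/end (s) of the
#'   quiet-stance baseline; must precede `pon`.
#' @param pon Perturbation or cue onset in seconds.
#' @param threshold_sds Band half-width in baseline SDs (default 2).
#' @param sampling_rate Required when `trace` is a bare numeric vector.
#' @param smooth Apply the 6 Hz marker low-pass before detection (default
#'   FALSE; synthetic fixtures are already smooth).
#' @param min_hold_s Minimum duration a crossing must persist to count as
#'   an event (default 0.02 s).
#' @return List with `LO` and `TD` in seconds.
#' @export
detect_events <- function(trace, baseline_window, pon, threshold_sds = 2,
                          sampling_rate = NULL, smooth = FALSE,
                          min_hold_s = 0.02) {
  if (is.data.frame(trace)) {
    t <- trace$time_s
    z <- trace$z_mm
  } else {
    if (is.null(sampling_rate)) stop("sampling_rate required for a bare trace")
    z <- as.numeric(trace)
    t <- (seq_along(z) - 1) / sampling_rate
  }
  if (baseline_window[2] > pon) stop("baseline window must precede PON")
  if (smooth) {
    fs <- sampling_rate %||% attr(trace, "sampling_rate") %||%
      (1 / mean(diff(t)))
    z <- filter_marker(z, fs)
  }
  base <- z[t >= baseline_window[1] & t <= baseline_window[2]]
  if (!length(base)) stop("empty baseline window")
  mu <- mean(base)
  sdev <- max(sd(base), 1e-9)
  thr <- mu + threshold_sds * sdev
  dt <- mean(diff(t))
  hold_n <- max(1L, ceiling(min_hold_s / dt))
  # first index in `idx` where cond holds and stays satisfied over >= 80%
  # of the next hold_n samples (window truncated at the trace end)
  first_sustained <- function(idx, cond) {
    n <- length(cond)
    cs <- c(0, cumsum(cond))
    ends <- pmin(seq_len(n) + hold_n - 1L, n)
    frac <- (cs[ends + 1L] - cs[seq_len(n)]) / (ends - seq_len(n) + 1L)
    hit <- which(cond & frac >= 0.8)
    if (!length(hit)) return(NA_integer_)
    idx[hit[1]]
  }
  after <- which(t > pon)
  lo_idx <- first_sustained(after, z[after] > thr)
  if (is.na(lo_idx)) stop("no step detected: trace never leaves the baseline band")
  post <- seq(lo_idx, length(z))
  apex <- post[which.max(z[post])]
  descent <- seq(apex, length(z))
  td_idx <- first_sustained(descent, z[descent] <= thr)
  if (is.na(td_idx)) stop("no step detected: trace never returns to the baseline band")
  list(LO = t[lo_idx], TD = t[td_idx])
}

#' Step length from heel positions at touchdown
#'
#' Signed anteroposterior distance between the stepping and stance heels at
#' TD, in mm.  Sign convention: positive when the stepping heel lies
#' posterior to the stance heel (a backward step is positive).
#'
#' @param heel_ap_step Stepping-limb heel AP position at TD (mm; AP axis
#'   positive anterior).
#' @param heel_ap_stance Stance-limb heel AP position at TD (mm).
#' @return Step length in mm.
#' @export
step_length <- function(heel_ap_step, heel_ap_stance) {
  heel_ap_stance - heel_ap_step
}

#' Included angle between two planar segments
#'
#' @param u,v Length-2 numeric vectors (sagittal-plane segment vectors).
#' @return Angle in degrees in `[0, 180]`.
#' @export
segment_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("degenerate (zero-length) segment")
  ct <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Knee and foot angles at touchdown, with window extrema
#'
#' Knee angle is the included angle between thigh (hip-to-knee) and shank
#' (knee-to-ankle) segment vectors in the sagittal plane (180 deg = full
#' extension); foot angle is the angle between the foot segment and the
#' ground (horizontal).  Maxima over the PON-TD window follow the reporting
#' convention for reactive stepping: maximum knee flexion is the minimum
#' included knee angle, maximum plantarflexion the maximum foot angle.
#'
#' @param thigh,shank 2 x n matrices of sagittal segment vectors over the
#'   window (columns = time samples; the last column is TD).
#' @param foot 2 x n matrix of foot-segment vectors over the window.
#' @return List with `knee_td`, `foot_td`, `max_knee_flexion` (minimum knee
#'   angle, deg) and `max_plantarflexion` (deg).
#' @export
segment_angles <- function(thigh, shank, foot) {
  n <- ncol(thigh)
  stopifnot(ncol(shank) == n, ncol(foot) == n)
  knee <- vapply(seq_len(n), function(i) {
    # included angle at the knee: thigh vector reversed so both point away
    # from the joint; collinear segments then give 180 (straight knee)
    segment_angle(-thigh[, i], shank[, i])
  }, numeric(1))
  ground <- c(1, 0)
  foot_angle <- vapply(seq_len(n), function(i) segment_angle(foot[, i], ground),
                       numeric(1))
  list(knee_td = knee[n], foot_td = foot_angle[n],
       max_knee_flexion = min(knee), max_plantarflexion = max(foot_angle))
}

#' Reaction and execution periods from events
#'
#' @param pon,lo,td Event times in seconds (PON < LO < TD).
#' @return List with `reaction_ms` (PON to LO) and `execution_ms` (LO to
#'   TD).
#' @export
step_periods <- function(pon, lo, td) {
  if (!(pon < lo && lo < td)) stop("event times must satisfy PON < LO < TD")
  list(reaction_ms = 1000 * (lo - pon), execution_ms = 1000 * (td - lo))
}
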