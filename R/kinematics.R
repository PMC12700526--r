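# Per-trial event detection and outcome metrics for reach trials.
#
# Thresholds follow the standard rules: movement onset at speed > 3.5 cm/s,
# movement end within the target (radius 0.5 cm, from the 10 mm target
# diameter) at speed < 3.5 cm/s, settling/stabilization at 2 cm/s sustained
# for 100 ms, reach angles over 150 ms chords.

#' Default kinematic thresholds
#'
#' @return named list: `onset_speed` and `end_speed` (3.5 cm/s),
#'   `settle_speed` (2 cm/s), `persist_s` (0.100 s), `angle_chord_s`
#'   (0.150 s), `target_radius` (0.5 cm), `endpoint_window_cm` (2 cm).
#' @export
kin_thresholds <- function() {
  list(onset_speed = 3.5, end_speed = 3.5, settle_speed = 2,
       persist_s = 0.100, angle_chord_s = 0.150, target_radius = 0.5,
       endpoint_window_cm = 2)
}

# first index i such that cond[j] holds for all j with t[j] in [t[i], t[i]+w]
# (closed window); the window must be fully recorded.
first_persistent <- function(cond, t, w, from = 1L) {
  n <- length(t)
  i <- from
  while (i <= n) {
    if (cond[i]) {
      jmax <- i
      while (jmax < n && t[jmax + 1L] <= t[i] + w + 1e-9) jmax <- jmax + 1L
      if (t[n] < t[i] + w - 1e-9) return(NA_integer_)  # window truncated
      if (all(cond[i:jmax])) return(i)
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  NA_integer_
}

#' Detect movement onset
#'
#' First time the hand speed exceeds `threshold` (default 3.5 cm/s), searching
#' from `from_t` (default the first sample, or the `go_cue` event if present).
#'
#' @param tr a [trial_record()] reach trial.
#' @param threshold speed threshold, cm/s.
#' @param from_t search start time, s.
#' @param vel optional precomputed [estimate_velocity()] output.
#' @return onset time, s.
#' @export
detect_onset <- function(tr, threshold = 3.5, from_t = NULL, vel = NULL) {
  if (is.null(vel)) vel <- estimate_velocity(tr)
  t <- tr$samples$t
  if (is.null(from_t)) {
    from_t <- if (!is.null(tr$events) && "go_cue" %in% names(tr$events))
      tr$events[["go_cue"]] else t[1]
  }
  idx <- which(t >= from_t - 1e-9 & vel$speed > threshold)
  if (length(idx) == 0L) {
    stop(sprintf("trial %s: speed never exceeds %.3g cm/s",
                 tr$meta$trial_id, threshold), call. = FALSE)
  }
  t[idx[1]]
}

#' Detect movement end
#'
#' First time after `onset_t` at which the hand is within the target
#' (`target_radius`, default 0.5 cm) and moving at less than `threshold`
#' (default 3.5 cm/s).
#'
#' @param tr a [trial_record()] reach trial with a `target_pos`.
#' @param onset_t onset time from [detect_onset()].
#' @param threshold speed threshold, cm/s.
#' @param target_radius cm.
#' @param vel optional precomputed velocity.
#' @return end time, s.
#' @export
detect_end <- function(tr, onset_t, threshold = 3.5, target_radius = 0.5,
                       vel = NULL) {
  if (is.null(vel)) vel <- estimate_velocity(tr)
  s <- tr$samples
  tgt <- tr$meta$target_pos
  d <- sqrt((s$x - tgt[1])^2 + (s$y - tgt[2])^2)
  idx <- which(s$t > onset_t & d <= target_radius & vel$speed < threshold)
  if (length(idx) == 0L) {
    stop(sprintf("trial %s: movement end criterion never satisfied",
                 tr$meta$trial_id), call. = FALSE)
  }
  s$t[idx[1]]
}

# chord heading from the sample at t0 to the sample `chord_s` later
chord_heading <- function(tr, t0, chord_s) {
  t <- tr$samples$t
  i0 <- which(t >= t0 - 1e-9)[1]
  t1 <- t[i0] + chord_s
  i1 <- which(t >= t1 - 1e-9)[1]
  if (is.na(i0) || is.na(i1)) return(NULL)
  c(tr$samples$x[i1] - tr$samples$x[i0], tr$samples$y[i1] - tr$samples$y[i0])
}

#' Reach outcomes for one trial
#'
#' Computes onset and end times, time to target, path length, the initial
#' reach angle `theta_start` (signed deviation, CCW positive, of the chord
#' from onset to onset + 150 ms relative to the start-to-target direction),
#' the endpoint reach angle `theta_end` (same, for the chord starting where
#' the hand first crosses within 2 cm of the target), and the outlier flag
#' (`|theta_start| >= 90` degrees).
#'
#' @param tr a [trial_record()] reach trial.
#' @param thresholds a [kin_thresholds()] list.
#' @param vel optional precomputed velocity.
#' @return list with fields `onset_t`, `end_t`, `time_to_target`,
#'   `path_length`, `theta_start`, `theta_end`, `outlier`.
#' @export
reach_outcomes <- function(tr, thresholds = kin_thresholds(), vel = NULL) {
  if (is.null(vel)) vel <- estimate_velocity(tr)
  th <- thresholds
  onset_t <- detect_onset(tr, th$onset_speed, vel = vel)
  end_t <- detect_end(tr, onset_t, th$end_speed, th$target_radius, vel = vel)
  s <- tr$samples
  tdir <- tr$meta$target_pos - tr$meta$start_pos

  ch <- chord_heading(tr, onset_t, th$angle_chord_s)
  if (is.null(ch)) {
    stop(sprintf("trial %s: too short for the %g ms chord", tr$meta$trial_id,
                 1000 * th$angle_chord_s), call. = FALSE)
  }
  theta_start <- signed_angle_deg(tdir, ch)

  d_tgt <- sqrt((s$x - tr$meta$target_pos[1])^2 +
                  (s$y - tr$meta$target_pos[2])^2)
  i_win <- which(s$t >= onset_t - 1e-9 & d_tgt <= th$endpoint_window_cm)
  theta_end <- NA_real_
  if (length(i_win) > 0L) {
    ch_end <- chord_heading(tr, s$t[i_win[1]], th$angle_chord_s)
    if (!is.null(ch_end) && sqrt(sum(ch_end^2)) > 0) {
      theta_end <- signed_angle_deg(tdir, ch_end)
    }
  }

  i0 <- which(s$t >= onset_t - 1e-9)[1]
  i1 <- which(s$t >= end_t - 1e-9)[1]
  path_length <- sum(sqrt(diff(s$x[i0:i1])^2 + diff(s$y[i0:i1])^2))

  list(onset_t = onset_t, end_t = end_t, time_to_target = end_t - onset_t,
       path_length = path_length, theta_start = theta_start,
       theta_end = theta_end, outlier = abs(theta_start) >= 90)
}

#' Lateral position and velocity signals
#'
#' Projects position (relative to the start-to-target line through
#' `origin`) and velocity onto the unit vector 90 degrees CCW of
#' `reference_direction`; CCW positive.
#'
#' @param tr a [trial_record()].
#' @param reference_direction_deg reference (movement) direction in degrees.
#' @param origin point on the reference line (default the trial's
#'   `start_pos`).
#' @param vel optional precomputed velocity.
#' @return data.frame with `t`, `lat_pos` (cm), `lat_vel` (cm/s).
#' @export
lateral_signal <- function(tr, reference_direction_deg, origin = NULL,
                           vel = NULL) {
  if (is.null(vel)) vel <- estimate_velocity(tr)
  if (is.null(origin)) origin <- tr$meta$start_pos
  u <- unit_deg(reference_direction_deg + 90)
  s <- tr$samples
  data.frame(t = s$t,
             lat_pos = (s$x - origin[1]) * u[1] + (s$y - origin[2]) * u[2],
             lat_vel = vel$vx * u[1] + vel$vy * u[2])
}

#' Pulse-perturbation outcomes
#'
#' Settling time: time from pulse onset to the first moment the absolute
#' lateral velocity dips below 2 cm/s and remains so for at least 100 ms; if
#' the movement ends first (or the criterion is never met in the record), the
#' settling time is censored at movement end minus pulse onset. Maximum
#' lateral deviation: maximum, over samples between pulse onset and movement
#' end, of the lateral
#' position relative to the straight start-to-target line, signed along the
#' pulse direction (`deviation_reference = "line"`), or relative to a supplied
#' mean unperturbed trajectory (`"mean_trajectory"`, via `reference_path`, a
#' function mapping forward progress to lateral offset).
#'
#' @param tr a [trial_record()] pulse trial with a `pulse_onset` event.
#' @param thresholds a [kin_thresholds()] list.
#' @param deviation_reference `"line"` or `"mean_trajectory"`.
#' @param reference_path optional function(progress cm) -> lateral offset cm,
#'   used when `deviation_reference = "mean_trajectory"`.
#' @param vel optional precomputed velocity.
#' @return list with `pulse_onset_t`, `settling_time`, `max_lateral_dev`,
#'   `censored`.
#' @export
pulse_outcomes <- function(tr, thresholds = kin_thresholds(),
                           deviation_reference = c("line", "mean_trajectory"),
                           reference_path = NULL, vel = NULL) {
  deviation_reference <- match.arg(deviation_reference)
  th <- thresholds
  if (is.null(vel)) vel <- estimate_velocity(tr)
  ev <- tr$events
  if (is.null(ev) || !"pulse_onset" %in% names(ev)) {
    stop(sprintf("trial %s: no pulse_onset event recorded", tr$meta$trial_id),
         call. = FALSE)
  }
  t_pulse <- ev[["pulse_onset"]]
  mdir <- vec_angle_deg(tr$meta$target_pos - tr$meta$start_pos)
  lat <- lateral_signal(tr, mdir, vel = vel)
  t <- lat$t

  onset_t <- detect_onset(tr, th$onset_speed, vel = vel)
  end_t <- tryCatch(detect_end(tr, onset_t, th$end_speed, th$target_radius,
                               vel = vel),
                    error = function(e) t[length(t)])

  from <- which(t >= t_pulse - 1e-9)[1]
  below <- abs(lat$lat_vel) < th$settle_speed
  i_set <- first_persistent(below, t, th$persist_s, from = from)
  if (!is.na(i_set) && t[i_set] <= end_t) {
    settling_time <- t[i_set] - t_pulse
    censored <- FALSE
  } else {
    settling_time <- end_t - t_pulse
    censored <- TRUE
  }

  sign_pulse <- if (tr$meta$pulse_sign == "CCW") 1 else -1
  post <- t > t_pulse + 1e-9 & t <= end_t + 1e-9  # the perturbed movement
  dev <- lat$lat_pos
  if (deviation_reference == "mean_trajectory") {
    if (is.null(reference_path)) {
      stop("reference_path required for mean_trajectory deviations",
           call. = FALSE)
    }
    u <- unit_deg(mdir)
    prog <- (tr$samples$x - tr$meta$start_pos[1]) * u[1] +
      (tr$samples$y - tr$meta$start_pos[2]) * u[2]
    dev <- dev - reference_path(prog)
  }
  max_lateral_dev <- max(sign_pulse * dev[post])

  list(pulse_onset_t = t_pulse, settling_time = settling_time,
       max_lateral_dev = max_lateral_dev, censored = censored)
}

#' Release-perturbation outcomes
#'
#' Time to stabilization: time from the release of the holding force to the
#' first moment at which speed dips below 2 cm/s (remaining below for at least
#' 100 ms) while the hand is within 2 cm of the target. Path to stabilization:
#' arc length from release to that moment. Maximum deviation: maximum
#' displacement from the hold point projected on the displacement direction
#' (opposite the removed force). Trials that do not stabilize within the
#' recorded window are handled per `cap_mode`: `"exclude"` (time `NA`),
#' `"impute_2s"` (time 2.0 s), or `"uncapped"` (time to the end of the
#' record); all three flag `censored = TRUE`.
#'
#' @param tr a [trial_record()] release trial with a `release_onset` event.
#' @param cap_mode `"exclude"`, `"impute_2s"` or `"uncapped"`.
#' @param thresholds a [kin_thresholds()] list.
#' @param vel optional precomputed velocity.
#' @return list with `release_t`, `time_to_stabilization`,
#'   `path_to_stabilization`, `max_deviation`, `censored`.
#' @export
release_outcomes <- function(tr, cap_mode = c("exclude", "impute_2s",
                                              "uncapped"),
                             thresholds = kin_thresholds(), vel = NULL) {
  cap_mode <- match.arg(cap_mode)
  th <- thresholds
  if (is.null(vel)) vel <- estimate_velocity(tr)
  ev <- tr$events
  if (is.null(ev) || !"release_onset" %in% names(ev)) {
    stop(sprintf("trial %s: no release_onset event recorded",
                 tr$meta$trial_id), call. = FALSE)
  }
  t_rel <- ev[["release_onset"]]
  s <- tr$samples
  t <- s$t
  tgt <- tr$meta$target_pos
  d_tgt <- sqrt((s$x - tgt[1])^2 + (s$y - tgt[2])^2)

  from <- which(t >= t_rel - 1e-9)[1]
  below <- vel$speed < th$settle_speed
  # candidate dips: persistent speed criterion; accept the first whose dip
  # moment also satisfies the distance criterion
  i <- from
  i_stab <- NA_integer_
  repeat {
    cand <- first_persistent(below, t, th$persist_s, from = i)
    if (is.na(cand)) break
    if (d_tgt[cand] < th$endpoint_window_cm) { i_stab <- cand; break }
    i <- cand + 1L
  }

  post <- t >= t_rel - 1e-9
  ddir <- unit_deg(tr$meta$release_direction_deg + 180)
  dev <- (s$x - tgt[1]) * ddir[1] + (s$y - tgt[2]) * ddir[2]
  max_deviation <- max(dev[post])

  arc <- function(i0, i1) {
    if (i1 <= i0) return(0)
    sum(sqrt(diff(s$x[i0:i1])^2 + diff(s$y[i0:i1])^2))
  }

  if (!is.na(i_stab)) {
    list(release_t = t_rel, time_to_stabilization = t[i_stab] - t_rel,
         path_to_stabilization = arc(from, i_stab),
         max_deviation = max_deviation, censored = FALSE)
  } else {
    tts <- switch(cap_mode, exclude = NA_real_, impute_2s = 2.0,
                  uncapped = t[length(t)] - t_rel)
    list(release_t = t_rel, time_to_stabilization = tts,
         path_to_stabilization = arc(from, length(t)),
         max_deviation = max_deviation, censored = TRUE)
  }
}
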