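# Synthetic cohort generator: a planar point-mass arm with a PD reach servo
# and a resting bias field that is gated by behavioral state (off during
# movement, ramping on after movement end, or always on).

#' Canonical 5-target array
#'
#' Center target at the origin plus four targets 10 cm away at 45, 135, 225
#' and 315 degrees. The two upper targets and the center are the "distant"
#' positions (furthest from the body, which lies in the -y direction); the two
#' lower targets are "near".
#'
#' @return 5 x 2 matrix with rownames `C`, `NE`, `NW`, `SW`, `SE`.
#' @export
target_array <- function() {
  r <- 10 / sqrt(2)
  m <- rbind(C = c(0, 0), NE = c(r, r), NW = c(-r, r),
             SW = c(-r, -r), SE = c(r, -r))
  colnames(m) <- c("x", "y")
  m
}

#' Proximity class of the canonical targets
#'
#' @return named character vector: `"distant"` for the center and the two
#'   upper targets, `"near"` for the two lower targets.
#' @export
target_proximity <- function() {
  c(C = "distant", NE = "distant", NW = "distant", SW = "near", SE = "near")
}

#' Resting bias field parameters
#'
#' A convergent force field: at position `p` the bias has magnitude
#' `impairment_scale * (base_gain + distance_gain * d) * s`, where `d` is the
#' distance from `p` to `convergence_point`, and `s = support_scale` when the
#' arm is supported (airsled) and 1 otherwise. The vector points from `p`
#' toward `convergence_point` (toward the body/flexion for the default
#' convergence point below the workspace).
#'
#' @param convergence_point length-2 numeric (cm); the near-body attractor.
#' @param base_gain nonnegative, N.
#' @param distance_gain nonnegative, N/cm.
#' @param support_scale in `[0, 1]`; multiplies the gains under arm support.
#' @param impairment_scale nonnegative; 0 for an unimpaired arm. Maps to a
#'   nominal FM-UE score via `fm_ue = 66 - 52 * impairment_scale` (clamped to
#'   `[0, 66]`), recorded in the cohort ground truth.
#' @param noise_sd_force sensor force noise SD per 200 Hz sample, N.
#' @param visit_sd_force SD (N, per component, at `impairment_scale = 1`
#'   unsupported) of the slow visit-to-visit fluctuation of the expressed
#'   bias: a random constant vector per trial, scaled like the field gains.
#'   This is what makes repeated measurements at one position differ by more
#'   than sensor noise.
#' @return list of class `bias_field_params`.
#' @export
bias_field_params <- function(convergence_point = c(0, -15), base_gain = 0,
                              distance_gain = 0.32, support_scale = 0.5,
                              impairment_scale = 1, noise_sd_force = 0.3,
                              visit_sd_force = 0.6) {
  stopifnot(base_gain >= 0, distance_gain >= 0, support_scale >= 0,
            support_scale <= 1, impairment_scale >= 0, noise_sd_force >= 0,
            visit_sd_force >= 0)
  structure(list(convergence_point = as.numeric(convergence_point),
                 base_gain = base_gain, distance_gain = distance_gain,
                 support_scale = support_scale,
                 impairment_scale = impairment_scale,
                 noise_sd_force = noise_sd_force,
                 visit_sd_force = visit_sd_force),
            class = "bias_field_params")
}

#' Gating of the posture controller
#'
#' @param mode `"hold_only"` (bias off during movement, ramping on with time
#'   constant `ramp_tau` after movement end), `"always_on"` (the
#'   counterfactual in which resting biases intrude on movement), or `"off"`.
#' @param ramp_tau bias onset time constant after movement end, s (> 0 for
#'   `hold_only`).
#' @return list of class `gating_mode`.
#' @export
gating_mode <- function(mode = c("hold_only", "always_on", "off"),
                        ramp_tau = 0.3) {
  mode <- match.arg(mode)
  if (mode == "hold_only") stopifnot(ramp_tau > 0)
  structure(list(mode = mode, ramp_tau = ramp_tau), class = "gating_mode")
}

#' Reach controller parameters
#'
#' Point-mass dynamics `m xdd = u + g(t) F_bias + F_perturb - b xd + noise`
#' with `u` a PD servo tracking a minimum-jerk reference of duration
#' `reach_duration`.
#'
#' @param mass effective hand+handle mass, kg.
#' @param damping viscous damping, N.s/cm.
#' @param kp servo stiffness, N/cm.
#' @param kd servo damping, N.s/cm.
#' @param reach_duration minimum-jerk reference duration, s.
#' @param timing_window feedback window for movement duration, s (protocol
#'   constant; does not enter the dynamics).
#' @param motor_noise_sd white motor force noise SD (N, per 1 kHz step).
#' @param hold_adapt_rate rate (1/s) of the hold controller's leaky reference
#'   adaptation, which gradually absorbs static loads while holding (engaged
#'   after movement end). At an abrupt load change the stored adaptation
#'   produces the characteristic kick opposite the removed force.
#' @param hold_adapt_leak leak time constant (s) of the adaptation; a finite
#'   leak means static loads (and the resting bias) are only partially
#'   absorbed, so the bias re-expresses in the post-release response.
#' @param hold_kp_frac fraction of the servo stiffness retained in the hold
#'   state (after movement end): holding relies on the slower adaptive
#'   controller rather than the stiff reach servo.
#' @return list of class `controller_params`.
#' @export
controller_params <- function(mass = 2, damping = 0.1, kp = 4, kd = 0.35,
                              reach_duration = 0.7,
                              timing_window = c(0.6, 0.8),
                              motor_noise_sd = 0.6,
                              hold_adapt_rate = 1,
                              hold_adapt_leak = 2.5,
                              hold_kp_frac = 0.5) {
  stopifnot(mass > 0, kp > 0, hold_adapt_rate >= 0, hold_adapt_leak > 0,
            hold_kp_frac > 0, hold_kp_frac <= 1)
  structure(list(mass = mass, damping = damping, kp = kp, kd = kd,
                 reach_duration = reach_duration,
                 timing_window = timing_window,
                 motor_noise_sd = motor_noise_sd,
                 hold_adapt_rate = hold_adapt_rate,
                 hold_adapt_leak = hold_adapt_leak,
                 hold_kp_frac = hold_kp_frac),
            class = "controller_params")
}

#' Evaluate the resting bias field
#'
#' @param params a [bias_field_params()].
#' @param pos length-2 position (cm).
#' @param support `"airsled"` or `"none"`.
#' @return length-2 force vector (N); zero at the convergence point.
#' @export
bias_at <- function(params, pos, support = "none") {
  stopifnot(inherits(params, "bias_field_params"), all(is.finite(pos)))
  d_vec <- params$convergence_point - pos
  d <- sqrt(sum(d_vec^2))
  if (d < 1e-12) return(c(0, 0))
  s <- if (support == "airsled") params$support_scale else 1
  mag <- params$impairment_scale * (params$base_gain +
                                      params$distance_gain * d) * s
  mag * d_vec / d
}

# nominal FM-UE from impairment (affine rule recorded in ground truth)
impairment_to_fm <- function(impairment_scale) {
  pmin(66, pmax(0, 66 - 52 * impairment_scale))
}

#' Simulate one passive-hold (resting bias) trial
#'
#' The robot passively moves the hand along a minimum-jerk path from
#' `approach_from` to `pos` over `move_s` seconds, then holds it there for
#' `hold_s` seconds. The recorded participant force is the gated bias rising
#' with time constant `ramp_tau` after hold onset, plus an approach-velocity
#' transient decaying with time constant `tau_transient` (directed along the
#' approach), plus white sensor noise.
#'
#' @param params a [bias_field_params()].
#' @param pos held position (cm).
#' @param approach_from position the passive movement started from (cm).
#' @param gating a [gating_mode()].
#' @param support `"airsled"` or `"none"`.
#' @param seed optional integer seed (local to this trial).
#' @param transient_amp amplitude of the approach transient at hold onset, N.
#'   Default `0.8 * impairment_scale`.
#' @param tau_transient transient decay time constant, s.
#' @param move_s,hold_s passive move and hold durations, s.
#' @param fs sampling rate, Hz.
#' @param meta optional list of metadata overrides (subject_id, arm, side,
#'   block, fm_ue, group).
#' @return a [trial_record()] with a `hold_onset` event.
#' @export
simulate_posture_trial <- function(params, pos, approach_from, gating,
                                   support = "none", seed = NULL,
                                   transient_amp = NULL, tau_transient = 0.7,
                                   move_s = 5, hold_s = 5, fs = 200,
                                   meta = list()) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(transient_amp)) transient_amp <- 0.8 * params$impairment_scale
  n <- round((move_s + hold_s) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  tau <- pmin(1, pmax(0, t / move_s))
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  sd_ <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / move_s
  dvec <- pos - approach_from
  x <- approach_from[1] + dvec[1] * s
  y <- approach_from[2] + dvec[2] * s

  bias <- if (gating$mode == "off") c(0, 0) else bias_at(params, pos, support)
  if (gating$mode != "off") {
    sfac <- if (support == "airsled") params$support_scale else 1
    bias <- bias + stats::rnorm(2, 0, params$visit_sd_force *
                                  params$impairment_scale * sfac)
  }
  dlen <- sqrt(sum(dvec^2))
  udir <- if (dlen > 1e-12) dvec / dlen else c(0, 0)

  hold_onset <- move_s
  dt_hold <- pmax(0, t - hold_onset)
  in_hold <- t >= hold_onset
  ramp <- if (gating$mode == "off") rep(0, n) else
    (1 - exp(-dt_hold / gating$ramp_tau)) * in_hold
  trans <- transient_amp * ifelse(in_hold, exp(-dt_hold / tau_transient),
                                  sd_ / max(sd_, 1e-12))
  fx <- bias[1] * ramp + udir[1] * trans +
    stats::rnorm(n, 0, params$noise_sd_force)
  fy <- bias[2] * ramp + udir[2] * trans +
    stats::rnorm(n, 0, params$noise_sd_force)

  md <- utils::modifyList(
    list(subject_id = "synth", group = "patient", arm = "paretic",
         side = "right", block = 1L,
         fm_ue = impairment_to_fm(params$impairment_scale)), meta)
  m <- trial_meta(subject_id = md$subject_id, group = md$group, arm = md$arm,
                  side = md$side, support = support, experiment = "rest",
                  trial_type = "passive_hold", block = md$block,
                  start_pos = approach_from, target_pos = pos,
                  fm_ue = md$fm_ue)
  trial_record(m, data.frame(t = t, x = x, y = y, fx = fx, fy = fy),
               events = c(hold_onset = hold_onset))
}

#' Simulate one reach trial
#'
#' Integrates the point-mass arm (fixed-step RK4 at `sim_rate` Hz, recorded at
#' `fs` = 200 Hz) making a 10 cm reach from `start` to `target`, optionally
#' perturbed by a 70 ms raised-cosine force pulse (12 N peak, lateral to the
#' movement, triggered at 2 cm progress) or by a ramp-hold-release force
#' (linear 0 to 6 N over 2 s, held for a uniform 3-5 s, then stepped to 0;
#' recording continues `post_release_s` seconds after the release, mirroring
#' the acquisition window of release trials).
#'
#' Movement end is detected online with the same rule as [detect_end()]
#' (within 0.5 cm of the target at speed < 3.5 cm/s) so the simulator and the
#' analysis share one definition; the bias gate and the release schedule key
#' off that time.
#'
#' @param params a [bias_field_params()].
#' @param controller a [controller_params()].
#' @param gating a [gating_mode()].
#' @param start,target length-2 positions, cm; `|target - start|` must equal
#'   10 cm (tolerance 1e-6).
#' @param perturbation `list(type = "none")`, `list(type = "pulse",
#'   sign = "CCW"|"CW")`, or `list(type = "release", direction_deg = 45|135|
#'   225|315)`.
#' @param support `"airsled"` or `"none"` (Experiment 2 is run supported).
#' @param seed optional integer seed (local to this trial).
#' @param fs recorded sampling rate, Hz (200).
#' @param sim_rate integration rate, Hz (1000; must be a multiple of `fs`).
#' @param t_go go-cue time, s (quiescent period before the reference starts).
#' @param post_release_s recording retained after force release, s.
#' @param meta optional metadata overrides as in [simulate_posture_trial()].
#' @return a [trial_record()] with events `go_cue`, `movement_end` (as
#'   detected online), and `pulse_onset`/`release_onset` when applicable.
#' @export
simulate_reach_trial <- function(params, controller, gating, start, target,
                                 perturbation = list(type = "none"),
                                 support = "airsled", seed = NULL, fs = 200,
                                 sim_rate = 1000, t_go = 0.25,
                                 post_release_s = 2, meta = list()) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sqrt(sum((target - start)^2)) - 10) > 1e-6) {
    stop("reach must be 10 cm point-to-point", call. = FALSE)
  }
  stopifnot(sim_rate %% fs == 0)
  type <- perturbation$type
  if (!type %in% c("none", "pulse", "release")) {
    stop("unknown perturbation type: ", type, call. = FALSE)
  }

  T_reach <- controller$reach_duration
  # the subject engages holding shortly after the reference completes even if
  # the end criterion has not yet been met (the hold controller then absorbs
  # any static load and settles the hand onto the target)
  end_deadline <- t_go + T_reach + 0.5
  rel_hold <- if (type == "release") stats::runif(1, 3, 5) else 0
  settle_delay <- 0.25
  dur <- if (type == "release") {
    end_deadline + settle_delay + 2 + rel_hold + post_release_s + 0.5
  } else {
    end_deadline + 1.5
  }
  dt <- 1 / sim_rate
  n_steps <- ceiling(dur / dt)
  noise <- matrix(stats::rnorm(2 * n_steps, 0, controller$motor_noise_sd),
                  nrow = 2)

  s <- if (support == "airsled") params$support_scale else 1
  bias_scale <- params$impairment_scale * s
  gate_code <- match(gating$mode, c("off", "hold_only", "always_on")) - 1L
  pert_code <- match(type, c("none", "pulse", "release")) - 1L
  pulse_sign <- if (type == "pulse") {
    if (perturbation$sign == "CCW") 1 else -1
  } else 0
  rel_dir <- if (type == "release") perturbation$direction_deg else 0

  bias_offset <- stats::rnorm(2, 0, params$visit_sd_force * bias_scale)
  res <- .reach_sim_cpp(
    dt, n_steps, as.numeric(start), as.numeric(target), t_go, T_reach,
    controller$mass, controller$damping, controller$kp, controller$kd,
    controller$hold_adapt_rate, controller$hold_adapt_leak,
    controller$hold_kp_frac,
    params$convergence_point, params$base_gain, params$distance_gain,
    bias_scale, bias_offset, gate_code, gating$ramp_tau, pert_code,
    pulse_sign, 12, 0.070, 2, deg2rad(rel_dir), 2, rel_hold, 6, noise,
    0.5, 3.5, settle_delay, end_deadline)

  keep <- seq(1, n_steps + 1, by = sim_rate / fs)
  st <- res$state[keep, , drop = FALSE]
  ff <- res$force[keep, , drop = FALSE]
  samples <- data.frame(t = st[, 1], x = st[, 2], y = st[, 3],
                        fx = ff[, 1], fy = ff[, 2])
  if (type == "release" && !is.na(res$t_release)) {
    samples <- samples[samples$t <= res$t_release + post_release_s + 1e-9, ]
  }

  events <- c(go_cue = t_go)
  if (!is.na(res$t_end)) events <- c(events, movement_end = res$t_end)
  if (type == "pulse" && !is.na(res$t_pulse)) {
    events <- c(events, pulse_onset = res$t_pulse)
  }
  if (type == "release" && !is.na(res$t_release)) {
    events <- c(events, release_onset = res$t_release)
  }
  events <- events[events <= samples$t[nrow(samples)] + 1e-9]

  md <- utils::modifyList(
    list(subject_id = "synth", group = "patient", arm = "paretic",
         side = "right", block = 1L,
         fm_ue = impairment_to_fm(params$impairment_scale)), meta)
  trial_type <- switch(type, none = "reach_unperturbed", pulse = "reach_pulse",
                       release = "reach_hold_release")
  m <- trial_meta(subject_id = md$subject_id, group = md$group, arm = md$arm,
                  side = md$side, support = support, experiment = "reach",
                  trial_type = trial_type, block = md$block,
                  start_pos = start, target_pos = target,
                  pulse_sign = if (type == "pulse") perturbation$sign else "none",
                  release_direction_deg = if (type == "release") rel_dir else NA,
                  fm_ue = md$fm_ue)
  trial_record(m, samples, events = events)
}

#' Build one or more 96-movement block schedules
#'
#' Each block holds 12 movements in each of the 8 directions over the 5-target
#' array (out-and-back pairs along the four diagonals, chained so each
#' movement starts where the previous one ended), with 64 unperturbed, 16 CW-
#' and 16 CCW-pulse movements, and exactly one extended-hold release trial per
#' (target position, release direction) pair (20 per block, drawn from the
#' unperturbed movements).
#'
#' @param n_blocks number of blocks (>= 1).
#' @param seed optional integer seed.
#' @return data.frame with one row per movement: `block`, `trial`, `start`,
#'   `target` (target-array labels), `trial_type`, `pulse_sign`,
#'   `release_direction_deg`.
#' @export
build_schedule <- function(n_blocks = 1, seed = NULL) {
  stopifnot(n_blocks >= 1)
  if (!is.null(seed)) set.seed(seed)
  spokes <- c("NE", "NW", "SW", "SE")
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    pair_order <- sample(rep(spokes, each = 12))
    start <- character(96); target <- character(96)
    start[seq(1, 96, 2)] <- "C"; target[seq(1, 96, 2)] <- pair_order
    start[seq(2, 96, 2)] <- pair_order; target[seq(2, 96, 2)] <- "C"

    trial_type <- rep("reach_unperturbed", 96)
    pulse_sign <- rep("none", 96)
    release_dir <- rep(NA_real_, 96)

    # one release trial per (target, direction) pair, among unperturbed
    rel_idx <- integer(0)
    for (tgt in c("C", spokes)) {
      cand <- setdiff(which(target == tgt), rel_idx)
      pick <- sample(cand, 4)
      rel_idx <- c(rel_idx, pick)
      release_dir[pick] <- sample(c(45, 135, 225, 315))
    }
    trial_type[rel_idx] <- "reach_hold_release"

    pulse_idx <- sample(setdiff(seq_len(96), rel_idx), 32)
    trial_type[pulse_idx] <- "reach_pulse"
    pulse_sign[pulse_idx] <- sample(rep(c("CW", "CCW"), 16))

    out[[b]] <- data.frame(block = b, trial = seq_len(96), start = start,
                           target = target, trial_type = trial_type,
                           pulse_sign = pulse_sign,
                           release_direction_deg = release_dir,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cohort configuration for the synthetic generator
#'
#' @param subjects data.frame with columns `subject_id`, `group`
#'   (`patient`/`control`), `side` (side of the tested/paretic arm),
#'   `impairment` (>= 0; 0 for controls) and `gating`
#'   (`hold_only`/`always_on`/`off`).
#' @param n_positions Experiment-1 positions per block (15-25 in the study).
#' @param visits visits per position per block (3 in the study).
#' @param include_targets if `TRUE` the 5 canonical targets are among the
#'   Experiment-1 positions (direct lookup); otherwise all positions are
#'   random and canonical forces are interpolated.
#' @param exp1_arms,exp1_supports which Experiment-1 blocks to simulate.
#' @param exp2_blocks Experiment-2 blocks per arm (0 to skip Experiment 2).
#' @param exp2_arms which arms perform Experiment 2.
#' @param field a [bias_field_params()] template; its `impairment_scale` is
#'   replaced per subject (non-paretic arms get 10% of the paretic
#'   impairment, controls 0).
#' @param controller a [controller_params()] template. Impairment slows the
#'   reference (`reach_duration + 0.6 * impairment`) and lowers stiffness
#'   (`kp * (1 - 0.4 * min(impairment, 1))`).
#' @param ramp_tau bias onset time constant for `hold_only` gating, s.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(subjects, n_positions = 15, visits = 3,
                          include_targets = TRUE,
                          exp1_arms = c("paretic", "nonparetic"),
                          exp1_supports = c("none", "airsled"),
                          exp2_blocks = 1,
                          exp2_arms = "paretic",
                          field = bias_field_params(),
                          controller = controller_params(),
                          ramp_tau = 0.3) {
  need <- c("subject_id", "group", "side", "impairment", "gating")
  if (!is.data.frame(subjects) || !all(need %in% names(subjects))) {
    stop("subjects must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!subjects$group %in% c("patient", "control"))) {
    stop("invalid group in subjects", call. = FALSE)
  }
  if (any(!subjects$gating %in% c("hold_only", "always_on", "off"))) {
    stop("invalid gating in subjects", call. = FALSE)
  }
  if (any(subjects$impairment < 0)) stop("impairment must be >= 0",
                                         call. = FALSE)
  if (n_positions < 5 && include_targets) {
    stop("n_positions must be >= 5 when include_targets", call. = FALSE)
  }
  structure(list(subjects = subjects, n_positions = n_positions,
                 visits = visits, include_targets = include_targets,
                 exp1_arms = exp1_arms, exp1_supports = exp1_supports,
                 exp2_blocks = exp2_blocks, exp2_arms = exp2_arms,
                 field = field, controller = controller, ramp_tau = ramp_tau),
            class = "cohort_config")
}

subject_params <- function(cfg, i) {
  sub <- cfg$subjects[i, ]
  imp <- if (sub$group == "control") 0 else sub$impairment
  fld <- cfg$field
  ctl <- cfg$controller
  mk <- function(impairment) {
    f <- fld; f$impairment_scale <- impairment; f
  }
  mkc <- function(impairment) {
    c <- ctl
    c$reach_duration <- ctl$reach_duration + 0.6 * impairment
    c$kp <- ctl$kp * (1 - 0.4 * min(impairment, 1))
    # impaired feedback control: underdamped corrections, slower load
    # compensation while holding
    c$kd <- ctl$kd * (1 - 0.7 * min(impairment, 1))
    c$hold_adapt_rate <- ctl$hold_adapt_rate * (1 - 0.6 * min(impairment, 1))
    c
  }
  arm_imp <- c(paretic = imp, nonparetic = 0.1 * imp,
               `dominant-proxy` = imp)
  list(sub = sub,
       field = lapply(arm_imp, mk),
       controller = lapply(arm_imp, mkc),
       gating = gating_mode(sub$gating, ramp_tau = cfg$ramp_tau),
       fm_ue = impairment_to_fm(imp))
}

# Experiment-1 position array for one subject: canonical targets (optional)
# plus random positions over the sampled workspace.
exp1_positions <- function(cfg) {
  tgts <- target_array()
  n_extra <- cfg$n_positions - if (cfg$include_targets) nrow(tgts) else 0L
  extra <- cbind(x = stats::runif(n_extra, -12, 12),
                 y = stats::runif(n_extra, -9, 9))
  if (cfg$include_targets) rbind(tgts, extra) else extra
}

#' Simulate a full synthetic cohort
#'
#' Generates Experiment-1 passive-hold blocks (per arm x support, each
#' visiting every position `visits` times in random order, chained so each
#' trial approaches from the previous position) and Experiment-2 reach blocks
#' (per [build_schedule()]), for every subject in the configuration. Trials of
#' left-sided subjects are recorded in mirrored (left-arm) coordinates so that
#' [flip_left_to_right()] has real work to do.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the same seed yields an identical cohort.
#' @return list with elements `trials` (a [trial_set()]) and `ground_truth`
#'   (per-subject generating parameters, arm impairments, nominal FM-UE, the
#'   affine FM-UE rule, and the seed).
#' @export
simulate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  trials <- list()
  gt_subjects <- list()
  tgts <- target_array()

  for (i in seq_len(nrow(config$subjects))) {
    sp <- subject_params(config, i)
    sub <- sp$sub
    positions <- exp1_positions(config)
    arms1 <- if (sub$group == "control") "dominant-proxy" else config$exp1_arms
    arms2 <- if (sub$group == "control") "dominant-proxy" else config$exp2_arms
    md <- list(subject_id = sub$subject_id, group = sub$group,
               side = sub$side, fm_ue = if (sub$group == "control")
                 NA_real_ else sp$fm_ue)

    block <- 0L
    for (arm in arms1) {
      for (supp in config$exp1_supports) {
        block <- block + 1L
        order_idx <- as.vector(replicate(config$visits,
                                         sample(nrow(positions))))
        prev <- c(0, -10)  # rest position near the body
        for (k in order_idx) {
          pos <- positions[k, ]
          tr <- simulate_posture_trial(
            sp$field[[arm]], pos, prev, sp$gating, support = supp,
            meta = c(md, list(arm = arm, block = block)))
          trials[[length(trials) + 1L]] <- tr
          prev <- pos
        }
      }
    }

    if (config$exp2_blocks > 0) {
      for (arm in arms2) {
        sched <- build_schedule(config$exp2_blocks)
        for (j in seq_len(nrow(sched))) {
          row <- sched[j, ]
          pert <- switch(row$trial_type,
                         reach_unperturbed = list(type = "none"),
                         reach_pulse = list(type = "pulse",
                                            sign = row$pulse_sign),
                         reach_hold_release = list(
                           type = "release",
                           direction_deg = row$release_direction_deg))
          tr <- simulate_reach_trial(
            sp$field[[arm]], sp$controller[[arm]], sp$gating,
            start = tgts[row$start, ], target = tgts[row$target, ],
            perturbation = pert, support = "airsled",
            meta = c(md, list(arm = arm, block = row$block)))
          trials[[length(trials) + 1L]] <- tr
        }
      }
    }

    gt_subjects[[sub$subject_id]] <- list(
      field = sp$field, controller = sp$controller,
      gating = sp$gating, fm_ue = sp$fm_ue, side = sub$side,
      group = sub$group, positions = positions)
  }

  ts <- trial_set(trials, provenance = list(source = "simulate_cohort",
                                            seed = seed))
  # left-sided subjects are recorded in their native (mirrored) frame
  ts$trials <- lapply(ts$trials, function(tr) {
    if (tr$meta$side == "left") mirror_trial(tr) else tr
  })
  list(trials = ts,
       ground_truth = list(subjects = gt_subjects, seed = seed,
                           fm_rule = "fm_ue = 66 - 52 * impairment"))
}

# mirror a right-frame trial into left-arm native coordinates (inverse of
# flip_left_to_right up to the side label)
mirror_trial <- function(tr) {
  tr$samples$x <- -tr$samples$x
  tr$samples$fx <- -tr$samples$fx
  tr$meta$start_pos[1] <- -tr$meta$start_pos[1]
  tr$meta$target_pos[1] <- -tr$meta$target_pos[1]
  tr$meta$pulse_sign <- switch(tr$meta$pulse_sign,
                               CW = "CCW", CCW = "CW", none = "none")
  if (!is.na(tr$meta$release_direction_deg)) {
    tr$meta$release_direction_deg <-
      wrap_deg(180 - tr$meta$release_direction_deg) %% 360
  }
  tr$meta$side <- "left"
  tr
}
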