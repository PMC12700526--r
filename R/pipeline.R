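# Orchestration: stage functions (rest, move, hold) over a trial_set, the
# bias-to-outcome join, and a deterministic end-to-end runner.

#' Analyze Experiment-1 (passive hold) trials
#'
#' Mirrors left-arm trials to the right, estimates per-trial resting forces,
#' aggregates bias maps per subject x arm x support, and computes the cohort
#' summary and the measurement variance fraction.
#'
#' @param ts a [trial_set()].
#' @param qc `"auto"` (QC proxy active) or `"none"`.
#' @param window bias averaging window, s relative to hold onset.
#' @param noise_scale optional sensor-noise scale (N) for the force-stability
#'   QC check.
#' @return list with `maps` (named list of `bias_map`), `summary`
#'   ([summarize_bias()] output) and `measurement_variance_fraction`.
#' @export
analyze_rest <- function(ts, qc = c("auto", "none"), window = c(2, 5),
                         noise_scale = NULL) {
  qc <- match.arg(qc)
  ts <- flip_left_to_right(ts)
  keep <- meta_field(ts, "trial_type") == "passive_hold"
  if (!any(keep)) stop("no passive_hold trials", call. = FALSE)
  trials <- ts$trials[keep]
  key <- vapply(trials, function(tr) paste(tr$meta$subject_id, tr$meta$arm,
                                           tr$meta$support, sep = "|"), "")
  maps <- lapply(split(trials, key), aggregate_bias_map, window = window,
                 qc = qc == "auto", noise_scale = noise_scale)
  list(maps = maps, summary = summarize_bias(maps),
       measurement_variance_fraction = variance_decomposition(maps))
}

#' Analyze Experiment-2 (reach) trials
#'
#' Mirrors left-arm trials to the right and computes the per-trial outcome
#' table: reach outcomes for every trial, pulse outcomes for pulse trials, and
#' release outcomes for extended-hold trials.
#'
#' @param ts a [trial_set()].
#' @param thresholds a [kin_thresholds()] list (override entries to change the
#'   3.5 / 2.0 cm/s and 150 / 100 ms rules).
#' @param cap_mode release-trial cap handling, see [release_outcomes()].
#' @param deviation_reference see [pulse_outcomes()].
#' @return data.frame (one row per reach trial) with metadata, the movement
#'   `direction_deg` and `direction_key`, and all outcome columns.
#' @export
analyze_move <- function(ts, thresholds = kin_thresholds(),
                         cap_mode = "impute_2s",
                         deviation_reference = "line") {
  ts <- flip_left_to_right(ts)
  keep <- meta_field(ts, "experiment") == "reach"
  if (!any(keep)) stop("no reach trials", call. = FALSE)
  trials <- ts$trials[keep]
  rows <- lapply(trials, function(tr) {
    m <- tr$meta
    vel <- estimate_velocity(tr)
    dir_deg <- vec_angle_deg(m$target_pos - m$start_pos)
    base <- list(
      trial_id = m$trial_id, subject_id = m$subject_id, group = m$group,
      arm = m$arm, support = m$support, block = m$block,
      trial_type = m$trial_type, pulse_sign = m$pulse_sign,
      release_direction_deg = m$release_direction_deg,
      start_x = m$start_pos[1], start_y = m$start_pos[2],
      target_x = m$target_pos[1], target_y = m$target_pos[2],
      direction_deg = dir_deg,
      direction_key = sprintf("%.0f", round(dir_deg)),
      fm_ue = m$fm_ue,
      onset_t = NA_real_, end_t = NA_real_, time_to_target = NA_real_,
      path_length = NA_real_, theta_start = NA_real_, theta_end = NA_real_,
      outlier = NA, settling_time = NA_real_, max_lateral_dev = NA_real_,
      pulse_censored = NA, time_to_stabilization = NA_real_,
      path_to_stabilization = NA_real_, max_deviation = NA_real_,
      release_censored = NA, no_end = FALSE)
    ro <- tryCatch(reach_outcomes(tr, thresholds, vel = vel),
                   error = function(e) NULL)
    if (is.null(ro)) { base$no_end <- TRUE; return(base) }
    base[c("onset_t", "end_t", "time_to_target", "path_length",
           "theta_start", "theta_end", "outlier")] <-
      ro[c("onset_t", "end_t", "time_to_target", "path_length",
           "theta_start", "theta_end", "outlier")]
    if (m$trial_type == "reach_pulse") {
      po <- pulse_outcomes(tr, thresholds,
                           deviation_reference = deviation_reference,
                           vel = vel)
      base$settling_time <- po$settling_time
      base$max_lateral_dev <- po$max_lateral_dev
      base$pulse_censored <- po$censored
    }
    if (m$trial_type == "reach_hold_release") {
      rl <- release_outcomes(tr, cap_mode = cap_mode, thresholds = thresholds,
                             vel = vel)
      base$time_to_stabilization <- rl$time_to_stabilization
      base$path_to_stabilization <- rl$path_to_stabilization
      base$max_deviation <- rl$max_deviation
      base$release_censored <- rl$censored
    }
    base
  })
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

# nearest canonical-target label for a position (NA if > tol away)
nearest_target_label <- function(x, y, tol = 0.5) {
  tgts <- target_array()
  d <- sqrt((tgts[, 1] - x)^2 + (tgts[, 2] - y)^2)
  j <- which.min(d)
  if (d[j] <= tol) rownames(tgts)[j] else NA_character_
}

#' Join resting-bias projections to an outcome table
#'
#' Adds, per trial, the canonical resting-bias force at the start and target
#' positions (from the subject's matching arm x support bias map) and its
#' projections: `bias_start_lat` and `bias_end_lat` (lateral to the movement,
#' CCW positive), `bias_along_pulse` (positive = aligned with the pulse, for
#' pulse trials) and `bias_release_aligned` / `bias_release_resistive`
#' (for release trials).
#'
#' @param outcomes an [analyze_move()] table.
#' @param maps bias maps from [analyze_rest()] (`$maps`).
#' @return `outcomes` with the bias columns added; trials whose subject has no
#'   matching map get `NA`s.
#' @export
join_bias <- function(outcomes, maps) {
  map_key <- vapply(maps, function(m) paste(m$subject_id, m$arm, m$support,
                                            sep = "|"), "")
  names(maps) <- map_key
  n <- nrow(outcomes)
  outcomes$bias_start_lat <- NA_real_
  outcomes$bias_end_lat <- NA_real_
  outcomes$bias_along_pulse <- NA_real_
  outcomes$bias_release_aligned <- NA_real_
  outcomes$bias_release_resistive <- NA_real_
  for (i in seq_len(n)) {
    key <- paste(outcomes$subject_id[i], outcomes$arm[i],
                 outcomes$support[i], sep = "|")
    m <- maps[[key]]
    if (is.null(m)) next
    cf <- m$canonical
    lb_s <- nearest_target_label(outcomes$start_x[i], outcomes$start_y[i])
    lb_t <- nearest_target_label(outcomes$target_x[i], outcomes$target_y[i])
    geom <- list(movement_dir_deg = outcomes$direction_deg[i])
    if (!is.na(lb_s)) {
      bs <- c(cf$fx[cf$target == lb_s], cf$fy[cf$target == lb_s])
      outcomes$bias_start_lat[i] <- project_bias(bs, "reach_start", geom)
      if (outcomes$trial_type[i] == "reach_pulse") {
        sgn <- if (outcomes$pulse_sign[i] == "CCW") 1 else -1
        outcomes$bias_along_pulse[i] <- sgn * outcomes$bias_start_lat[i]
      }
    }
    if (!is.na(lb_t)) {
      bt <- c(cf$fx[cf$target == lb_t], cf$fy[cf$target == lb_t])
      outcomes$bias_end_lat[i] <- project_bias(bt, "reach_end", geom)
      if (outcomes$trial_type[i] == "reach_hold_release") {
        al <- project_bias(
          bt, "release",
          list(release_dir_deg = outcomes$release_direction_deg[i]))
        outcomes$bias_release_aligned[i] <- al
        outcomes$bias_release_resistive[i] <- -al
      }
    }
  }
  outcomes
}

# extreme-pair construct for one subject's pulse trials: returns aligned and
# opposed mean responses over the two extreme movement directions
pulse_extreme_responses <- function(d, outcome_var) {
  proj <- unique(d[!is.na(d$bias_start_lat),
                   c("direction_key", "bias_start_lat")])
  if (nrow(proj) < 2L) return(NULL)
  names(proj) <- c("direction_key", "component")
  hi <- proj$direction_key[order(-proj$component, proj$direction_key)][1]
  lo <- proj$direction_key[order(proj$component, proj$direction_key)][1]
  val <- function(key, sign) {
    v <- d[[outcome_var]][d$direction_key == key & d$pulse_sign == sign]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  # in the most-CCW-bias direction, CCW pulses are bias-aligned; in the
  # most-CW-bias direction, CW pulses are bias-aligned
  aligned <- mean(c(val(hi, "CCW"), val(lo, "CW")), na.rm = TRUE)
  opposed <- mean(c(val(hi, "CW"), val(lo, "CCW")), na.rm = TRUE)
  list(aligned = aligned, opposed = opposed)
}

#' Interaction statistics between resting biases and movement/holding
#'
#' Runs the inference layer on a bias-joined outcome table for one arm
#' (default paretic) and support condition: extreme-instance paired contrasts
#' for the unperturbed-reach angles, the pulse responses and the release
#' responses; per-subject sensitivity regressions for each context; Response
#' Asymmetry Indices (hold/release vs. pulse) for maximum deviation and
#' settling/stabilization time with their paired contrast; and the
#' resting-magnitude ANOVA (patients only).
#'
#' @param outcomes a [join_bias()]-augmented outcome table.
#' @param rest an [analyze_rest()] result (for the ANOVA magnitudes).
#' @param arm which arm to analyze.
#' @param drop_outliers drop trials with `|theta_start| >= 90` degrees.
#' @return list of class `hold_report` with elements `extremes`,
#'   `sensitivities`, `rai`, `anova`.
#' @export
analyze_hold <- function(outcomes, rest = NULL, arm = "paretic",
                         drop_outliers = TRUE) {
  d <- outcomes[outcomes$arm == arm, ]
  if (nrow(d) == 0L) stop("no trials for arm ", arm, call. = FALSE)
  if (drop_outliers) d <- d[is.na(d$outlier) | !d$outlier, ]
  subs <- unique(d$subject_id)

  # --- extreme-instance contrasts ------------------------------------------
  per_subject_extremes <- function(data, comp_col, out_col, context) {
    res <- lapply(subs, function(s) {
      ds <- data[data$subject_id == s & !is.na(data[[comp_col]]), ]
      if (nrow(ds) == 0L) return(NULL)
      proj <- unique(ds[, c("direction_key", comp_col)])
      names(proj) <- c("direction_key", "component")
      oc <- data.frame(direction_key = ds$direction_key,
                       outcome = ds[[out_col]])
      tryCatch(select_extremes(proj, oc, context = context),
               error = function(e) NULL)
    })
    names(res) <- subs
    res <- Filter(Negate(is.null), res)
    if (length(res) < 2L) return(NULL)
    hi_out <- vapply(res, function(r) r$outcome_means[1], 0)
    lo_out <- vapply(res, function(r) r$outcome_means[2], 0)
    hi_c <- vapply(res, function(r) r$component_values[1], 0)
    lo_c <- vapply(res, function(r) r$component_values[2], 0)
    ok <- !is.na(hi_out) & !is.na(lo_out)
    list(pairs = res,
         outcome_contrast = paired_contrast(hi_out[ok], lo_out[ok]),
         component_contrast = paired_contrast(hi_c[ok], lo_c[ok]),
         mean_outcomes = c(high = mean(hi_out[ok]), low = mean(lo_out[ok])))
  }

  unpert <- d[d$trial_type %in% c("reach_unperturbed", "reach_hold_release"), ]
  rel <- d[d$trial_type == "reach_hold_release", ]
  rel$release_key <- paste(nearest_labels(rel), rel$release_direction_deg)
  pul <- d[d$trial_type == "reach_pulse", ]

  extremes <- list(
    theta_start = per_subject_extremes(unpert, "bias_start_lat",
                                       "theta_start", "reach_start"),
    theta_end = per_subject_extremes(unpert, "bias_end_lat", "theta_end",
                                     "reach_end"))
  rel2 <- rel
  rel2$direction_key <- rel2$release_key
  extremes$release <- lapply(
    c(time_to_stabilization = "time_to_stabilization",
      path_to_stabilization = "path_to_stabilization",
      max_deviation = "max_deviation"),
    function(v) per_subject_extremes(rel2, "bias_release_resistive", v,
                                     "release"))

  # --- sensitivities --------------------------------------------------------
  sens_of <- function(data, bias_col, out_col) {
    dd <- data.frame(subject_id = data$subject_id, bias = data[[bias_col]],
                     outcome = data[[out_col]],
                     direction_key = data$direction_key)
    dd <- dd[!is.na(dd$bias) & !is.na(dd$outcome), ]
    if (nrow(dd) < 4L) return(NULL)
    tryCatch(sensitivity(dd), error = function(e) NULL)
  }
  sensitivities <- list(
    theta_start = sens_of(unpert, "bias_start_lat", "theta_start"),
    theta_end = sens_of(unpert, "bias_end_lat", "theta_end"),
    pulse_max_dev = sens_of(pul, "bias_along_pulse", "max_lateral_dev"),
    pulse_settling = sens_of(pul, "bias_along_pulse", "settling_time"),
    release_time = sens_of(rel, "bias_release_resistive",
                           "time_to_stabilization"),
    release_path = sens_of(rel, "bias_release_resistive",
                           "path_to_stabilization"),
    release_max_dev = sens_of(rel, "bias_release_resistive", "max_deviation"))

  # --- Response Asymmetry Indices ------------------------------------------
  rai_tab <- do.call(rbind, lapply(subs, function(s) {
    dp <- pul[pul$subject_id == s, ]
    dr <- rel2[rel2$subject_id == s, ]
    row <- data.frame(subject_id = s, rai_hold_dev = NA_real_,
                      rai_hold_time = NA_real_, rai_pulse_dev = NA_real_,
                      rai_pulse_time = NA_real_)
    hold_pair <- function(out_col) {
      proj <- unique(dr[!is.na(dr$bias_release_resistive),
                        c("direction_key", "bias_release_resistive")])
      if (nrow(proj) < 2L) return(NULL)
      names(proj) <- c("direction_key", "component")
      oc <- data.frame(direction_key = dr$direction_key,
                       outcome = dr[[out_col]])
      # native release sign: component here is already resistive, so convert
      # back to the aligned-positive scale expected by select_extremes
      proj$component <- -proj$component
      tryCatch(select_extremes(proj, oc, context = "release"),
               error = function(e) NULL)
    }
    hp <- hold_pair("max_deviation")
    if (!is.null(hp) && all(!is.na(hp$outcome_means))) {
      # outcome_means[1] = most opposed, [2] = most aligned
      r <- tryCatch(response_asymmetry_index(hp$outcome_means[2],
                                             hp$outcome_means[1]),
                    error = function(e) NULL)
      if (!is.null(r)) row$rai_hold_dev <- r$rai
    }
    hp <- hold_pair("time_to_stabilization")
    if (!is.null(hp) && all(!is.na(hp$outcome_means))) {
      r <- tryCatch(response_asymmetry_index(hp$outcome_means[2],
                                             hp$outcome_means[1]),
                    error = function(e) NULL)
      if (!is.null(r)) row$rai_hold_time <- r$rai
    }
    pe <- pulse_extreme_responses(dp, "max_lateral_dev")
    if (!is.null(pe) && is.finite(pe$aligned + pe$opposed)) {
      r <- tryCatch(response_asymmetry_index(pe$aligned, pe$opposed),
                    error = function(e) NULL)
      if (!is.null(r)) row$rai_pulse_dev <- r$rai
    }
    pe <- pulse_extreme_responses(dp, "settling_time")
    if (!is.null(pe) && is.finite(pe$aligned + pe$opposed)) {
      r <- tryCatch(response_asymmetry_index(pe$aligned, pe$opposed),
                    error = function(e) NULL)
      if (!is.null(r)) row$rai_pulse_time <- r$rai
    }
    row
  }))
  rai <- list(per_subject = rai_tab)
  ok_d <- !is.na(rai_tab$rai_hold_dev) & !is.na(rai_tab$rai_pulse_dev)
  if (sum(ok_d) >= 2) {
    rai$dev_contrast <- paired_contrast(rai_tab$rai_hold_dev[ok_d],
                                        rai_tab$rai_pulse_dev[ok_d])
  }
  ok_t <- !is.na(rai_tab$rai_hold_time) & !is.na(rai_tab$rai_pulse_time)
  if (sum(ok_t) >= 2) {
    rai$time_contrast <- paired_contrast(rai_tab$rai_hold_time[ok_t],
                                         rai_tab$rai_pulse_time[ok_t])
  }

  # --- resting-magnitude ANOVA (patients, this arm, both supports) ----------
  anova_tab <- NULL
  if (!is.null(rest)) {
    ps <- rest$summary$per_subject
    ps <- ps[ps$group == "patient" & ps$arm == arm & !is.na(ps$fm_ue), ]
    if (nrow(ps) >= 4 && length(unique(ps$support)) == 2) {
      long <- rbind(
        data.frame(subject_id = ps$subject_id, support = ps$support,
                   proximity = "distant", magnitude = ps$mag_distant,
                   fm_ue = ps$fm_ue),
        data.frame(subject_id = ps$subject_id, support = ps$support,
                   proximity = "near", magnitude = ps$mag_near,
                   fm_ue = ps$fm_ue))
      anova_tab <- tryCatch(rest_anova(long), error = function(e) NULL)
    }
  }

  structure(list(extremes = extremes, sensitivities = sensitivities,
                 rai = rai, anova = anova_tab),
            class = "hold_report")
}

nearest_labels <- function(d) {
  vapply(seq_len(nrow(d)), function(i) {
    lb <- nearest_target_label(d$target_x[i], d$target_y[i])
    if (is.na(lb)) sprintf("(%.1f,%.1f)", d$target_x[i], d$target_y[i]) else lb
  }, "")
}

#' Run configuration
#'
#' @param seed integer seed used for every random stage.
#' @param stages subset of `c("simulate", "rest", "move", "hold")`.
#' @param cohort a [cohort_config()] (required when simulating).
#' @param thresholds kinematic threshold overrides (named entries of
#'   [kin_thresholds()]).
#' @param qc_mode `"auto"` or `"none"`.
#' @param cap_mode release cap handling.
#' @param in_path optional directory with an existing trial set (alternative
#'   to simulating).
#' @param out_dir optional output directory for CSV tables and the run log.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, stages = c("simulate", "rest", "move",
                                            "hold"),
                       cohort = NULL, thresholds = list(),
                       qc_mode = "auto", cap_mode = "impute_2s",
                       in_path = NULL, out_dir = NULL) {
  stopifnot(length(stages) >= 1)
  bad <- setdiff(stages, c("simulate", "rest", "move", "hold"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(names(thresholds), names(kin_thresholds()))
  if (length(bad)) stop("unknown threshold override(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(seed = seed, stages = stages, cohort = cohort,
                 thresholds = thresholds, qc_mode = qc_mode,
                 cap_mode = cap_mode, in_path = in_path, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate (or load) -> rest -> move -> hold, deterministically under the
#' configured seed. When `out_dir` is set, writes the summary tables as CSV
#' plus a plain-text run log recording the seed, thresholds and decision
#' flags.
#'
#' @param cfg a [run_config()].
#' @return list with (depending on stages) `trials`, `ground_truth`, `rest`,
#'   `outcomes`, `hold`, and `log` (character vector).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- c(sprintf("seed: %d", cfg$seed),
           sprintf("stages: %s", paste(cfg$stages, collapse = ", ")),
           sprintf("qc_mode: %s", cfg$qc_mode),
           sprintf("cap_mode: %s", cfg$cap_mode))
  th <- utils::modifyList(kin_thresholds(), cfg$thresholds)
  for (nm in names(th)) {
    log <- c(log, sprintf("threshold %s: %g%s", nm, th[[nm]],
                          if (nm %in% names(cfg$thresholds))
                            " (override)" else ""))
  }
  out <- list()

  if ("simulate" %in% cfg$stages) {
    if (is.null(cfg$cohort)) stop("simulate stage needs cfg$cohort",
                                  call. = FALSE)
    sim <- simulate_cohort(cfg$cohort, seed = cfg$seed)
    out$trials <- sim$trials
    out$ground_truth <- sim$ground_truth
    log <- c(log, sprintf("simulated %d trials, %d subjects",
                          length(out$trials),
                          nrow(cfg$cohort$subjects)))
  } else if (!is.null(cfg$in_path)) {
    out$trials <- read_trialset(cfg$in_path)
    log <- c(log, sprintf("read %d trials from %s", length(out$trials),
                          cfg$in_path))
  } else if (any(c("rest", "move", "hold") %in% cfg$stages)) {
    stop("no input: set cfg$in_path or include the simulate stage",
         call. = FALSE)
  }

  noise_scale <- NULL
  if (!is.null(out$ground_truth)) {
    noise_scale <- cfg$cohort$field$noise_sd_force
  }
  if ("rest" %in% cfg$stages) {
    out$rest <- analyze_rest(out$trials, qc = cfg$qc_mode,
                             noise_scale = noise_scale)
    log <- c(log, sprintf("rest: %d bias maps, measurement variance %.3f",
                          length(out$rest$maps),
                          out$rest$measurement_variance_fraction))
  }
  if ("move" %in% cfg$stages) {
    out$outcomes <- analyze_move(out$trials, thresholds = th,
                                 cap_mode = cfg$cap_mode)
    log <- c(log, sprintf("move: %d trial outcomes (%d outliers)",
                          nrow(out$outcomes),
                          sum(out$outcomes$outlier, na.rm = TRUE)))
  }
  if ("hold" %in% cfg$stages) {
    if (is.null(out$rest) || is.null(out$outcomes)) {
      stop("hold stage requires the rest and move stages (missing product)",
           call. = FALSE)
    }
    out$outcomes <- join_bias(out$outcomes, out$rest$maps)
    out$hold <- analyze_hold(out$outcomes, rest = out$rest)
    log <- c(log, "hold: interaction statistics computed")
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$rest)) {
      utils::write.csv(out$rest$summary$per_subject,
                       file.path(cfg$out_dir, "rest_per_subject.csv"),
                       row.names = FALSE)
      utils::write.csv(out$rest$summary$group,
                       file.path(cfg$out_dir, "rest_group.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$outcomes)) {
      utils::write.csv(out$outcomes,
                       file.path(cfg$out_dir, "outcomes.csv"),
                       row.names = FALSE)
    }
    writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  }
  out$log <- log
  out
}
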