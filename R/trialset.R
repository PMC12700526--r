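# Canonical trial containers and file format.
#
# Coordinate convention: +x rightward, +y away from the body; positions in cm,
# participant-on-handle forces in N, time in s, nominal sampling at 200 Hz.

.meta_vocab <- list(
  group = c("patient", "control"),
  arm = c("paretic", "nonparetic", "dominant-proxy"),
  side = c("left", "right"),
  support = c("airsled", "none"),
  experiment = c("rest", "reach"),
  trial_type = c("passive_hold", "reach_unperturbed", "reach_pulse",
                 "reach_hold_release"),
  pulse_sign = c("CW", "CCW", "none"),
  release_direction_deg = c(45, 135, 225, 315, NA)
)

.format_version <- "1.0"

#' Construct trial metadata
#'
#' Validated per-trial metadata: subject, arm, side, support condition,
#' trial type, start/target positions and perturbation parameters.
#'
#' @param subject_id character token.
#' @param group `"patient"` or `"control"`.
#' @param arm `"paretic"`, `"nonparetic"` or `"dominant-proxy"`.
#' @param side `"left"` or `"right"` (which physical arm).
#' @param support `"airsled"` or `"none"`.
#' @param experiment `"rest"` or `"reach"`.
#' @param trial_type one of `"passive_hold"`, `"reach_unperturbed"`,
#'   `"reach_pulse"`, `"reach_hold_release"`.
#' @param block integer block number.
#' @param start_pos,target_pos length-2 numeric (cm). For passive-hold trials
#'   `target_pos` is the held position.
#' @param pulse_sign `"CW"`, `"CCW"` or `"none"`; must be non-`"none"` iff
#'   `trial_type == "reach_pulse"`.
#' @param release_direction_deg direction of the imposed (later released)
#'   force, one of 45, 135, 225, 315, or `NA`; non-`NA` iff
#'   `trial_type == "reach_hold_release"`.
#' @param fm_ue Fugl-Meyer Upper Extremity score (0-66) or `NA`; required for
#'   patients.
#' @param flags character vector of QC labels.
#' @param trial_id optional identifier; filled by [trial_set()] if missing.
#' @return a list of class `trial_meta`.
#' @export
trial_meta <- function(subject_id, group, arm, side, support, experiment,
                       trial_type, block = 1L,
                       start_pos = c(NA_real_, NA_real_),
                       target_pos = c(NA_real_, NA_real_),
                       pulse_sign = "none", release_direction_deg = NA,
                       fm_ue = NA_real_, flags = character(),
                       trial_id = NA_character_) {
  m <- list(trial_id = as.character(trial_id),
            subject_id = as.character(subject_id), group = group, arm = arm,
            side = side, support = support, experiment = experiment,
            trial_type = trial_type, block = as.integer(block),
            start_pos = as.numeric(start_pos),
            target_pos = as.numeric(target_pos), pulse_sign = pulse_sign,
            release_direction_deg = as.numeric(release_direction_deg),
            fm_ue = as.numeric(fm_ue), flags = as.character(flags))
  class(m) <- "trial_meta"
  validate_trial_meta(m)
  m
}

validate_trial_meta <- function(m) {
  for (f in c("group", "arm", "side", "support", "experiment", "trial_type",
              "pulse_sign")) {
    if (!(m[[f]] %in% .meta_vocab[[f]])) {
      stop(sprintf("trial %s: unknown %s token '%s'",
                   m$trial_id, f, as.character(m[[f]])), call. = FALSE)
    }
  }
  if ((m$pulse_sign != "none") != (m$trial_type == "reach_pulse")) {
    stop(sprintf("trial %s: pulse_sign must be set iff trial_type is reach_pulse",
                 m$trial_id), call. = FALSE)
  }
  if (!is.na(m$release_direction_deg) &&
      !(m$release_direction_deg %in% c(45, 135, 225, 315))) {
    stop(sprintf("trial %s: release_direction_deg must be one of 45/135/225/315",
                 m$trial_id), call. = FALSE)
  }
  if (is.na(m$release_direction_deg) != (m$trial_type != "reach_hold_release")) {
    stop(sprintf(
      "trial %s: release_direction_deg must be set iff trial_type is reach_hold_release",
      m$trial_id), call. = FALSE)
  }
  if (m$group == "patient" && is.na(m$fm_ue)) {
    stop(sprintf("trial %s: fm_ue required for patients", m$trial_id),
         call. = FALSE)
  }
  invisible(m)
}

#' Construct a trial record
#'
#' One trial's metadata plus the synchronized time series of hand position and
#' handle force, and optional named event times.
#'
#' @param meta a [trial_meta()] object.
#' @param samples data.frame with columns `t` (s, strictly increasing),
#'   `x`, `y` (cm), `fx`, `fy` (N).
#' @param events optional named numeric vector of event times
#'   (e.g. `movement_onset`, `movement_end`, `pulse_onset`, `release_onset`,
#'   `hold_onset`); must lie within the sampled time span.
#' @return a list of class `trial_record`.
#' @export
trial_record <- function(meta, samples, events = NULL) {
  stopifnot(inherits(meta, "trial_meta"), is.data.frame(samples))
  need <- c("t", "x", "y", "fx", "fy")
  if (!all(need %in% names(samples))) {
    stop(sprintf("trial %s: samples must have columns t,x,y,fx,fy",
                 meta$trial_id), call. = FALSE)
  }
  tt <- samples$t
  if (length(tt) < 1L || any(diff(tt) <= 0)) {
    stop(sprintf("trial %s: t must be strictly increasing", meta$trial_id),
         call. = FALSE)
  }
  if (!is.null(events)) {
    events <- unlist(events)
    if (is.null(names(events)) || any(!nzchar(names(events)))) {
      stop("events must be named", call. = FALSE)
    }
    ok <- is.na(events) | (events >= tt[1] & events <= tt[length(tt)])
    if (!all(ok)) {
      stop(sprintf("trial %s: event(s) %s outside sampled span", meta$trial_id,
                   paste(names(events)[!ok], collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(meta = meta, samples = samples, events = events),
            class = "trial_record")
}

#' Construct a trial set
#'
#' @param trials list of [trial_record()] objects.
#' @param provenance list describing the source (free-form); a
#'   `format_version` field is added on write.
#' @return a list of class `trial_set`.
#' @export
trial_set <- function(trials, provenance = list(source = "in-memory")) {
  stopifnot(is.list(trials))
  for (i in seq_along(trials)) {
    if (!inherits(trials[[i]], "trial_record")) {
      stop("all elements must be trial_record objects", call. = FALSE)
    }
    if (is.na(trials[[i]]$meta$trial_id)) {
      trials[[i]]$meta$trial_id <- sprintf("trial%05d", i)
    }
  }
  structure(list(trials = trials, provenance = provenance),
            class = "trial_set")
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("trial_set: %d trials (%d subjects)\n", length(x$trials),
              length(unique(vapply(x$trials, function(tr) tr$meta$subject_id,
                                   "")))))
  invisible(x)
}

meta_field <- function(ts, field) {
  vapply(ts$trials, function(tr) {
    v <- tr$meta[[field]]
    if (length(v) == 0L || is.null(v)) NA else v[1]
  }, ts$trials[[1]]$meta[[field]][1])
}

subset_trials <- function(ts, keep) {
  trial_set(ts$trials[keep], provenance = ts$provenance)
}

.meta_scalar_fields <- c("trial_id", "subject_id", "group", "arm", "side",
                         "support", "experiment", "trial_type", "block",
                         "pulse_sign", "release_direction_deg", "fm_ue")

#' Write a trial set to disk
#'
#' Writes a JSON manifest (`manifest.json`) and one time-series CSV per trial
#' (header exactly `t,x,y,fx,fy`; units s, cm, N) into `path`.
#'
#' @param ts a [trial_set()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)
  entries <- lapply(ts$trials, function(tr) {
    m <- tr$meta
    csv <- paste0(m$trial_id, ".csv")
    e <- m[.meta_scalar_fields]
    e$start_pos <- m$start_pos
    e$target_pos <- m$target_pos
    e$flags <- I(m$flags)
    e$csv <- csv
    if (!is.null(tr$events)) e$events <- as.list(tr$events)
    utils::write.csv(tr$samples[, c("t", "x", "y", "fx", "fy")],
                     file.path(path, csv), row.names = FALSE)
    e
  })
  manifest <- list(format_version = .format_version,
                   provenance = ts$provenance, trials = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a trial set from disk
#'
#' Inverse of [write_trialset()]: reads `manifest.json` plus the per-trial
#' CSVs, validating metadata tokens and time monotonicity. Unknown CSV columns
#' are preserved but ignored by the analyses.
#'
#' @param path directory containing a manifest written by [write_trialset()].
#' @return a [trial_set()].
#' @export
read_trialset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest: ", mf, call. = FALSE)
  manifest <- jsonlite::read_json(mf)
  trials <- lapply(manifest$trials, function(e) {
    csv <- file.path(path, e$csv)
    if (!file.exists(csv)) {
      stop(sprintf("trial %s: missing time-series file %s", e$trial_id, csv),
           call. = FALSE)
    }
    samples <- utils::read.csv(csv)
    meta <- trial_meta(
      subject_id = e$subject_id, group = e$group, arm = e$arm, side = e$side,
      support = e$support, experiment = e$experiment,
      trial_type = e$trial_type, block = e$block,
      start_pos = unlist(e$start_pos), target_pos = unlist(e$target_pos),
      pulse_sign = e$pulse_sign,
      release_direction_deg = if (is.null(e$release_direction_deg)) NA else
        e$release_direction_deg,
      fm_ue = if (is.null(e$fm_ue)) NA_real_ else e$fm_ue,
      flags = unlist(e$flags), trial_id = e$trial_id)
    events <- if (!is.null(e$events)) unlist(e$events) else NULL
    tryCatch(trial_record(meta, samples, events),
             error = function(err) stop(sprintf("trial %s: %s", e$trial_id,
                                                conditionMessage(err)),
                                        call. = FALSE))
  })
  prov <- manifest$provenance
  prov$format_version <- manifest$format_version
  trial_set(trials, provenance = prov)
}

#' Estimate hand velocity
#'
#' Central finite differences of position over time (one-sided at the
#' endpoints), followed by moving-average smoothing over `smooth_window`.
#'
#' @param tr a [trial_record()] with at least 3 samples.
#' @param smooth_window smoothing window in seconds (default 0.025 s).
#' @return data.frame with columns `vx`, `vy` (cm/s) and `speed` (cm/s).
#' @export
estimate_velocity <- function(tr, smooth_window = 0.025) {
  s <- tr$samples
  n <- nrow(s)
  if (n < 3L) stop("estimate_velocity needs at least 3 samples", call. = FALSE)
  t <- s$t
  vx <- vy <- numeric(n)
  idx <- 2:(n - 1)
  dt2 <- t[idx + 1L] - t[idx - 1L]
  vx[idx] <- (s$x[idx + 1L] - s$x[idx - 1L]) / dt2
  vy[idx] <- (s$y[idx + 1L] - s$y[idx - 1L]) / dt2
  vx[1] <- (s$x[2] - s$x[1]) / (t[2] - t[1])
  vy[1] <- (s$y[2] - s$y[1]) / (t[2] - t[1])
  vx[n] <- (s$x[n] - s$x[n - 1]) / (t[n] - t[n - 1])
  vy[n] <- (s$y[n] - s$y[n - 1]) / (t[n] - t[n - 1])
  dt <- stats::median(diff(t))
  k <- max(1L, round(smooth_window / dt))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > 1L && n >= k) {
    vx <- movavg_reflect(vx, k)
    vy <- movavg_reflect(vy, k)
  }
  data.frame(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

# Moving average with reflected ends (keeps length, no phase shift).
movavg_reflect <- function(v, k) {
  h <- (k - 1L) %/% 2L
  n <- length(v)
  ext <- c(v[(h + 1L):2L], v, v[(n - 1L):(n - h)])
  as.numeric(stats::filter(ext, rep(1 / k, k), sides = 2L))[(h + 1L):(h + n)]
}

#' Mirror left-arm trials to the right
#'
#' For trials recorded with the left arm, mirrors the workspace about the
#' y-axis so that left- and right-arm data can be pooled: `x -> -x`,
#' `fx -> -fx`, start/target positions mirrored, pulse signs swapped
#' (CW <-> CCW), release directions mirrored about the y-axis, and `side`
#' relabelled `"right"`. Right-side trials are returned unchanged. The
#' operation is an involution on the mirrored-label convention and preserves
#' speed and force magnitude.
#'
#' @param ts a [trial_set()]; every trial must have a known `side`.
#' @return a [trial_set()] in which all trials are right-sided.
#' @export
flip_left_to_right <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  ts$trials <- lapply(ts$trials, function(tr) {
    side <- tr$meta$side
    if (is.null(side) || is.na(side)) {
      stop(sprintf("trial %s: side is unknown", tr$meta$trial_id),
           call. = FALSE)
    }
    if (side == "right") return(tr)
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
    tr$meta$side <- "right"
    tr$meta$flags <- union(tr$meta$flags, "mirrored")
    tr
  })
  ts
}
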