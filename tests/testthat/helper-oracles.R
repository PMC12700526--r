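# Independent brute-force oracles: plain sample-by-sample scans of the stated
# rules, kept deliberately separate from the package's vectorized
# implementations.

# minimum-jerk closed forms for a reach of distance D over duration T
mj_speed <- function(t, D, T) {
  tau <- pmin(1, pmax(0, t / T))
  D * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / T
}
mj_pos <- function(t, D, T) {
  tau <- pmin(1, pmax(0, t / T))
  D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

# first time-index scan of: speed > thr (onset rule)
oracle_onset_idx <- function(speed, t, from_t, thr = 3.5) {
  for (i in seq_along(t)) {
    if (t[i] >= from_t - 1e-9 && speed[i] > thr) return(i)
  }
  NA_integer_
}

oracle_end_idx <- function(x, y, speed, t, onset_t, tgt, radius = 0.5,
                           thr = 3.5) {
  for (i in seq_along(t)) {
    if (t[i] > onset_t &&
        sqrt((x[i] - tgt[1])^2 + (y[i] - tgt[2])^2) <= radius &&
        speed[i] < thr) {
      return(i)
    }
  }
  NA_integer_
}

# persistence scan: first i >= from with cond[j] for all t[j] in [t[i], t[i]+w]
oracle_persistent_idx <- function(cond, t, w, from = 1L) {
  n <- length(t)
  for (i in from:n) {
    if (!cond[i]) next
    if (t[n] < t[i] + w - 1e-9) return(NA_integer_)
    ok <- TRUE
    j <- i
    while (j <= n && t[j] <= t[i] + w + 1e-9) {
      if (!cond[j]) { ok <- FALSE; break }
      j <- j + 1L
    }
    if (ok) return(i)
  }
  NA_integer_
}

# full per-trial oracle for reach outcomes; returns NULL when onset/end fail
oracle_reach <- function(tr, vel) {
  t <- tr$samples$t; x <- tr$samples$x; y <- tr$samples$y
  from_t <- if (!is.null(tr$events) && "go_cue" %in% names(tr$events))
    tr$events[["go_cue"]] else t[1]
  io <- oracle_onset_idx(vel$speed, t, from_t)
  if (is.na(io)) return(NULL)
  onset_t <- t[io]
  ie <- oracle_end_idx(x, y, vel$speed, t, onset_t, tr$meta$target_pos)
  if (is.na(ie)) return(NULL)
  end_t <- t[ie]
  tdir <- tr$meta$target_pos - tr$meta$start_pos

  chord <- function(t0) {
    i0 <- NA_integer_
    for (i in seq_along(t)) if (t[i] >= t0 - 1e-9) { i0 <- i; break }
    t1 <- t[i0] + 0.150
    i1 <- NA_integer_
    for (i in seq_along(t)) if (t[i] >= t1 - 1e-9) { i1 <- i; break }
    if (is.na(i1)) return(NULL)
    c(x[i1] - x[i0], y[i1] - y[i0])
  }
  ang <- function(v) {
    a <- atan2(tdir[1] * v[2] - tdir[2] * v[1],
               tdir[1] * v[1] + tdir[2] * v[2]) * 180 / pi
    a <- (a + 180) %% 360 - 180
    if (a == -180) 180 else a
  }
  ch <- chord(onset_t)
  if (is.null(ch)) return(NULL)
  theta_start <- ang(ch)
  d_tgt <- sqrt((x - tr$meta$target_pos[1])^2 + (y - tr$meta$target_pos[2])^2)
  theta_end <- NA_real_
  for (i in seq_along(t)) {
    if (t[i] >= onset_t - 1e-9 && d_tgt[i] <= 2) {
      ch2 <- chord(t[i])
      if (!is.null(ch2) && sqrt(sum(ch2^2)) > 0) theta_end <- ang(ch2)
      break
    }
  }
  i0 <- which(t >= onset_t - 1e-9)[1]
  i1 <- which(t >= end_t - 1e-9)[1]
  pl <- 0
  if (i1 > i0) for (i in (i0 + 1L):i1) {
    pl <- pl + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  }
  list(onset_t = onset_t, end_t = end_t, time_to_target = end_t - onset_t,
       path_length = pl, theta_start = theta_start, theta_end = theta_end,
       outlier = abs(theta_start) >= 90)
}

oracle_pulse <- function(tr, vel) {
  t <- tr$samples$t
  t_pulse <- tr$events[["pulse_onset"]]
  mdir <- atan2(tr$meta$target_pos[2] - tr$meta$start_pos[2],
                tr$meta$target_pos[1] - tr$meta$start_pos[1])
  ux <- -sin(mdir); uy <- cos(mdir)  # 90 deg CCW of movement
  lat_vel <- vel$vx * ux + vel$vy * uy
  lat_pos <- (tr$samples$x - tr$meta$start_pos[1]) * ux +
    (tr$samples$y - tr$meta$start_pos[2]) * uy

  ro <- oracle_reach(tr, vel)
  end_t <- if (!is.null(ro)) ro$end_t else t[length(t)]
  from <- which(t >= t_pulse - 1e-9)[1]
  i_set <- oracle_persistent_idx(abs(lat_vel) < 2, t, 0.100, from = from)
  if (!is.na(i_set) && t[i_set] <= end_t) {
    settling <- t[i_set] - t_pulse; cens <- FALSE
  } else {
    settling <- end_t - t_pulse; cens <- TRUE
  }
  sgn <- if (tr$meta$pulse_sign == "CCW") 1 else -1
  best <- -Inf
  for (i in seq_along(t)) {
    if (t[i] > t_pulse + 1e-9 && t[i] <= end_t + 1e-9) {
      v <- sgn * lat_pos[i]
      if (v > best) best <- v
    }
  }
  list(settling_time = settling, max_lateral_dev = best, censored = cens)
}

oracle_release <- function(tr, vel, cap_mode = "impute_2s") {
  t <- tr$samples$t; x <- tr$samples$x; y <- tr$samples$y
  t_rel <- tr$events[["release_onset"]]
  tgt <- tr$meta$target_pos
  d_tgt <- sqrt((x - tgt[1])^2 + (y - tgt[2])^2)
  from <- which(t >= t_rel - 1e-9)[1]
  below <- vel$speed < 2
  i <- from
  i_stab <- NA_integer_
  repeat {
    cand <- oracle_persistent_idx(below, t, 0.100, from = i)
    if (is.na(cand)) break
    if (d_tgt[cand] < 2) { i_stab <- cand; break }
    i <- cand + 1L
  }
  dd <- tr$meta$release_direction_deg + 180
  ux <- cos(dd * pi / 180); uy <- sin(dd * pi / 180)
  best <- -Inf
  for (k in seq_along(t)) {
    if (t[k] >= t_rel - 1e-9) {
      v <- (x[k] - tgt[1]) * ux + (y[k] - tgt[2]) * uy
      if (v > best) best <- v
    }
  }
  arc <- function(i0, i1) {
    s <- 0
    if (i1 > i0) for (k in (i0 + 1L):i1) {
      s <- s + sqrt((x[k] - x[k - 1])^2 + (y[k] - y[k - 1])^2)
    }
    s
  }
  if (!is.na(i_stab)) {
    list(time_to_stabilization = t[i_stab] - t_rel,
         path_to_stabilization = arc(from, i_stab),
         max_deviation = best, censored = FALSE)
  } else {
    tts <- switch(cap_mode, exclude = NA_real_, impute_2s = 2.0,
                  uncapped = t[length(t)] - t_rel)
    list(time_to_stabilization = tts,
         path_to_stabilization = arc(from, length(t)),
         max_deviation = best, censored = TRUE)
  }
}

# OLS slope by explicit normal equations
oracle_slope <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  b[2]
}

# deSolve reference integration of the same arm model (independent of the
# package's RK4): noiseless reach in two phases — the reach servo up to the
# hold-engagement time (online end rule, or reference completion + 0.5 s),
# then the hold controller (reduced stiffness, leaky reference adaptation,
# gated bias). Returns a trial_record so the package's own outcome rules can
# be applied to the reference trajectory.
oracle_ode_trial <- function(params, controller, gating_mode_chr, start,
                             target, t_go = 0.25, tail_s = 1.5,
                             ramp_tau = 0.3) {
  bias_f <- function(x, g) {
    if (g <= 0) return(c(0, 0))
    dv <- params$convergence_point - x
    d <- sqrt(sum(dv^2))
    if (d < 1e-12) return(c(0, 0))
    s <- params$support_scale  # supported reaching
    g * params$impairment_scale *
      (params$base_gain + params$distance_gain * d) * s * dv / d
  }
  T_reach <- controller$reach_duration
  deriv1 <- function(t, state, parms) {
    x <- state[1:2]; v <- state[3:4]
    tau <- (t - t_go) / T_reach
    if (tau <= 0) { r <- start; rv <- c(0, 0) }
    else if (tau >= 1) { r <- target; rv <- c(0, 0) }
    else {
      sj <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
      sdd <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / T_reach
      r <- start + (target - start) * sj
      rv <- (target - start) * sdd
    }
    u <- controller$kp * (r - x) + controller$kd * (rv - v)
    g <- if (gating_mode_chr == "always_on") 1 else 0
    a <- 100 / controller$mass *
      (u + bias_f(x, g) - controller$damping * v)
    list(c(v, a))
  }
  t_engage_max <- t_go + T_reach + 0.5
  times1 <- seq(0, t_engage_max, by = 1 / 200)
  out1 <- deSolve::ode(c(start, 0, 0), times1, deriv1, NULL,
                       method = "ode45")
  sp1 <- sqrt(out1[, 4]^2 + out1[, 5]^2)
  d1 <- sqrt((out1[, 2] - target[1])^2 + (out1[, 3] - target[2])^2)
  hit <- which(out1[, 1] > t_go & d1 <= 0.5 & sp1 < 3.5)
  i_hold <- if (length(hit)) hit[1] else nrow(out1)
  t_hold <- out1[i_hold, 1]

  deriv2 <- function(t, state, parms) {
    x <- state[1:2]; v <- state[3:4]; ro <- state[5:6]
    u <- controller$kp * controller$hold_kp_frac * (target + ro - x) -
      controller$kd * v
    g <- if (gating_mode_chr == "always_on") 1
    else if (gating_mode_chr == "hold_only")
      1 - exp(-(t - t_hold) / ramp_tau) else 0
    a <- 100 / controller$mass *
      (u + bias_f(x, g) - controller$damping * v)
    dro <- controller$hold_adapt_rate * (target - x) -
      ro / controller$hold_adapt_leak
    list(c(v, a, dro))
  }
  times2 <- seq(t_hold, t_engage_max + tail_s, by = 1 / 200)
  out2 <- deSolve::ode(c(out1[i_hold, 2:5], 0, 0), times2, deriv2, NULL,
                       method = "ode45")
  keep1 <- out1[seq_len(i_hold - 1L), , drop = FALSE]
  samples <- data.frame(
    t = c(keep1[, 1], out2[, 1]),
    x = c(keep1[, 2], out2[, 2]), y = c(keep1[, 3], out2[, 3]),
    fx = 0, fy = 0)
  meta <- trial_meta(subject_id = "oracle", group = "control",
                    arm = "dominant-proxy", side = "right",
                    support = "airsled", experiment = "reach",
                    trial_type = "reach_unperturbed",
                    start_pos = start, target_pos = target,
                    trial_id = "oracle")
  trial_record(meta, samples, events = c(go_cue = t_go))
}
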