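# Event detection and outcome metrics: threshold crossings, angles, settling
# and stabilization rules, and their invariances.

test_that("onset detection finds the first threshold crossing", {
  # stationary: no onset
  n <- 200
  expect_error(detect_onset(fix_trial_xy(rep(0, n), rep(0, n))),
               "never exceeds")

  # step to 10 cm/s at t = 1 s
  t <- seq(0, 2, by = 1 / 200)
  y <- ifelse(t < 1, 0, 10 * (t - 1))
  tr <- fix_trial_xy(numeric(length(t)), y)
  expect_equal(detect_onset(tr), 1, tolerance = 0.01)

  # minimum-jerk 10 cm / 0.7 s: crossing of 3.5 cm/s at the root of
  # 30 tau^2 - 60 tau^3 + 30 tau^4 = 3.5 T / D
  D <- 10; T <- 0.7; lead <- 0.25
  root <- uniroot(function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4 -
                    3.5 * T / D, c(1e-4, 0.3))$root
  tr_mj <- fix_mj_trial(D = D, T = T, lead = lead)
  expect_lt(abs(detect_onset(tr_mj) - (lead + root * T)), 1.5 / 200)
})

test_that("movement end requires being inside the target below threshold", {
  # clean minimum-jerk reach onto the target
  tr <- fix_mj_trial(D = 10, T = 0.7)
  onset <- detect_onset(tr)
  e <- detect_end(tr, onset)
  # analytic: the later of entering the 0.5 cm target radius and the speed
  # dropping below 3.5 cm/s on the decelerating branch
  root_d <- uniroot(function(tau) 10 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5) -
                      9.5, c(0.5, 1))$root
  root_v <- uniroot(function(tau) 10 * (30 * tau^2 - 60 * tau^3 +
                                          30 * tau^4) / 0.7 - 3.5,
                    c(0.7, 1 - 1e-9))$root
  expect_lt(abs(e - (0.25 + max(root_d, root_v) * 0.7)), 2 / 200)

  # passing through the target fast, stopping outside: no end
  t <- seq(0, 2, by = 1 / 200)
  y <- pmin(20 * t, 15)   # 20 cm/s through the target at y = 10, stop at 15
  trf <- fix_trial_xy(numeric(length(t)), y)
  expect_error(detect_end(trf, detect_onset(trf)), "never satisfied")

  # ending inside the target at 1 cm/s qualifies at that sample
  y2 <- pmin(20 * t, 9.8)
  y2[t > 0.49] <- 9.8 + 1 * (t[t > 0.49] - t[t > 0.49][1]) * 0  # hard stop
  tr2 <- fix_trial_xy(numeric(length(t)), y2)
  e2 <- detect_end(tr2, detect_onset(tr2))
  expect_lt(abs(e2 - 0.49), 0.05)
})

test_that("reach outcomes: angles, path length and the outlier rule", {
  tr <- fix_mj_trial(D = 10, T = 0.7)
  ro <- reach_outcomes(tr)
  expect_equal(ro$theta_start, 0, tolerance = 1e-6)
  expect_equal(ro$theta_end, 0, tolerance = 1e-6)
  expect_equal(ro$path_length, 10, tolerance = 0.06)
  expect_false(ro$outlier)

  # initial heading 100 degrees CCW of the target direction: outlier
  t <- seq(0, 1.5, by = 1 / 200)
  spd <- 15
  head_dir <- deg2rad(90 + 100)
  x <- ifelse(t < 0.3, spd * t * cos(head_dir), NA)
  y <- ifelse(t < 0.3, spd * t * sin(head_dir), NA)
  # then loop to the target
  i_turn <- max(which(t < 0.3))
  frac <- pmin(1, (t - 0.3) / 0.8)
  x <- ifelse(is.na(x), x[i_turn] + (0 - x[i_turn]) * frac, x)
  y <- ifelse(is.na(y), y[i_turn] + (10 - y[i_turn]) * frac, y)
  # ease the final approach to stop inside the target
  tro <- fix_trial_xy(x, y)
  oo <- tryCatch(reach_outcomes(tro), error = function(e) NULL)
  if (!is.null(oo)) expect_true(oo$outlier)
  expect_gte(abs(signed_angle_deg(c(0, 1), unit_deg(190))), 90)

  # quarter-circle path: arc length (pi/2) R vs 10 cm chord
  R <- 10
  phi <- seq(0, pi / 2, length.out = 301)
  # traverse slowly enough to start below threshold: ramp the angle
  tt <- seq(0, 1.5, length.out = 301)
  sphi <- (pi / 2) * (10 * (tt / 1.5)^3 - 15 * (tt / 1.5)^4 + 6 * (tt / 1.5)^5)
  xq <- R * sin(sphi)
  yq <- R - R * cos(sphi)
  m <- fix_meta(start_pos = c(0, 0), target_pos = c(10, 10))
  trq <- fix_trial_xy(xq, yq, meta = m)
  roq <- reach_outcomes(trq)
  # full quarter-circle arc, minus the slow lead-in/terminal pieces outside
  # the onset/end thresholds
  expect_lt(roq$path_length, (pi / 2) * R + 1e-9)
  expect_gt(roq$path_length, 0.96 * (pi / 2) * R)
  # the generated polyline itself carries the analytic arc length
  expect_equal(sum(sqrt(diff(xq)^2 + diff(yq)^2)), (pi / 2) * R,
               tolerance = 0.005)
})

test_that("lateral signals project onto the CCW normal and are rotation invariant", {
  n <- 101
  t <- (0:(n - 1)) / 200
  # movement along the reference: zero lateral signal
  m <- fix_meta(start_pos = c(0, 0), target_pos = c(0, 10))
  tr <- fix_trial_xy(numeric(n), 10 * t, meta = m)
  lat <- lateral_signal(tr, 90)
  expect_lt(max(abs(lat$lat_pos)), 1e-9)
  expect_lt(max(abs(lat$lat_vel[5:(n - 5)])), 1e-9)

  # reference up, velocity (-2, 0): lateral velocity +2 (CCW-of-up is left)
  tr2 <- fix_trial_xy(-2 * t, numeric(n), meta = m)
  lat2 <- lateral_signal(tr2, 90)
  expect_equal(lat2$lat_vel[10], 2, tolerance = 1e-9)

  # rotating trajectory and reference together leaves the signal unchanged
  ang <- 37
  Rm <- matrix(c(cos(deg2rad(ang)), sin(deg2rad(ang)),
                 -sin(deg2rad(ang)), cos(deg2rad(ang))), 2, 2, byrow = TRUE)
  xy <- cbind(0.5 * t^2, 10 * t)
  xyr <- xy %*% t(matrix(c(cos(deg2rad(ang)), -sin(deg2rad(ang)),
                           sin(deg2rad(ang)), cos(deg2rad(ang))), 2, 2,
                         byrow = TRUE))
  tr3 <- fix_trial_xy(xy[, 1], xy[, 2], meta = m)
  tr4 <- fix_trial_xy(xyr[, 1], xyr[, 2], meta = m)
  l3 <- lateral_signal(tr3, 90, origin = c(0, 0))
  l4 <- lateral_signal(tr4, 90 + ang, origin = c(0, 0))
  expect_equal(l4$lat_pos, l3$lat_pos, tolerance = 1e-9)
})

test_that("pulse settling follows the persistent-dip rule", {
  # triangle lateral velocity: 0 -> 8 cm/s over 0.1 s, back to 0 at 0.3 s;
  # |v| dips below 2 cm/s at t = 0.25 + pulse onset
  fs <- 200
  t <- seq(0, 1.2, by = 1 / fs)
  v <- ifelse(t < 0.2, 0,
              ifelse(t < 0.3, 80 * (t - 0.2),
                     ifelse(t < 0.5, 8 - 40 * (t - 0.3), 0)))
  # build x from the lateral velocity; movement along +y with constant 10 cm/s
  x <- cumsum(v) / fs
  y <- 10 * t
  m <- fix_meta(trial_type = "reach_pulse", pulse_sign = "CCW",
                start_pos = c(0, 0), target_pos = c(0, 10))
  # lateral here is -x for movement up... use CCW normal of +y = (-1, 0):
  # lateral velocity = -vx, so flip x to make the lateral excursion CCW
  tr <- trial_record(m, data.frame(t = t, x = -x, y = y, fx = 0, fy = 0),
                     events = c(pulse_onset = 0.2))
  po <- pulse_outcomes(tr)
  # analytic downward crossing of 2 cm/s: 8 - 40 (t - 0.3) = 2 -> t = 0.45,
  # i.e. 0.25 after pulse onset
  expect_lt(abs(po$settling_time - 0.25), 1.5 / fs)
  expect_false(po$censored)  # settles before the record (and movement) ends

  # lateral velocity never below 2 before movement end: censored at end
  v2 <- rep(5, length(t))
  x2 <- cumsum(v2) / fs
  tr2 <- trial_record(m, data.frame(t = t, x = -x2, y = y, fx = 0, fy = 0),
                      events = c(pulse_onset = 0.2))
  po2 <- pulse_outcomes(tr2)
  expect_true(po2$censored)
  expect_equal(po2$settling_time, t[length(t)] - 0.2, tolerance = 1e-6)

  # missing event errors
  tr3 <- trial_record(m, data.frame(t = t, x = x, y = y, fx = 0, fy = 0))
  expect_error(pulse_outcomes(tr3), "pulse_onset")
})

test_that("release stabilization combines speed persistence and distance", {
  fs <- 200
  m <- fix_meta(trial_type = "reach_hold_release", release_direction_deg = 45,
                start_pos = c(0, 0), target_pos = c(0, 0))
  # overdamped return x(t) = A exp(-t/tau) along the displacement direction
  # (225 deg); speed A/tau exp(-t/tau) < 2 at t1 = tau log(A/(2 tau)),
  # distance < 2 at t2 = tau log(A/2); stabilization at max(t1, t2)
  A <- 3; tau <- 0.3
  t <- seq(0, 3, by = 1 / fs)
  rel_t <- 0.5
  d <- ifelse(t < rel_t, 0, A * exp(-(t - rel_t) / tau))
  u <- unit_deg(225)
  tr <- trial_record(m, data.frame(t = t, x = d * u[1], y = d * u[2],
                                   fx = 0, fy = 0),
                     events = c(release_onset = rel_t))
  ro <- release_outcomes(tr)
  t1 <- tau * log(A / (2 * tau))
  t2 <- tau * log(A / 2)
  expect_equal(ro$time_to_stabilization, max(t1, t2), tolerance = 2.5 / fs)
  expect_equal(ro$max_deviation, A, tolerance = 0.02)
  expect_equal(ro$path_to_stabilization, A - 2 * min(tau, 1),
               tolerance = 0.1)

  # oscillatory: re-exceeding 2 cm/s within 100 ms postpones stabilization
  v <- function(tt) 2.3 + 1 * sin(2 * pi * tt / 0.15)  # dips below 2 briefly
  tt <- t - rel_t
  spd <- ifelse(tt < 0, 0, ifelse(tt < 0.4, v(tt), 0.5))
  pos <- cumsum(spd) / fs
  d2 <- 1.5 - pmin(pos, 1.5)  # stays within 2 cm of target throughout
  tr2 <- trial_record(m, data.frame(t = t, x = d2 * u[1], y = d2 * u[2],
                                    fx = 0, fy = 0),
                      events = c(release_onset = rel_t))
  ro2 <- release_outcomes(tr2)
  # the brief dips within the first 0.4 s never persist 100 ms; the first
  # qualifying moment is at/after the 0.4 s plateau
  expect_gte(ro2$time_to_stabilization, 0.35)

  # never stabilizing: cap modes
  d3 <- ifelse(t < rel_t, 0, 5 + 3 * sin(2 * pi * 2 * (t - rel_t)))
  tr3 <- trial_record(m, data.frame(t = t, x = d3 * u[1], y = d3 * u[2],
                                    fx = 0, fy = 0),
                      events = c(release_onset = rel_t))
  r_ex <- release_outcomes(tr3, cap_mode = "exclude")
  r_im <- release_outcomes(tr3, cap_mode = "impute_2s")
  r_un <- release_outcomes(tr3, cap_mode = "uncapped")
  expect_true(r_ex$censored && r_im$censored && r_un$censored)
  expect_true(is.na(r_ex$time_to_stabilization))
  expect_equal(r_im$time_to_stabilization, 2.0)
  expect_equal(r_un$time_to_stabilization, t[length(t)] - rel_t)

  expect_error(release_outcomes(fix_mj_trial()), "release_onset")
})

test_that("detectors are invariant to workspace rotation and translation", {
  p <- bias_field_params(impairment_scale = 0.8)
  ct <- controller_params()
  g <- gating_mode("hold_only")
  tg <- target_array()
  tr <- simulate_reach_trial(p, ct, g, tg["C", ], tg["NE", ], seed = 31)
  ro <- reach_outcomes(tr)

  ang <- 25; sh <- c(4, -7)
  R <- matrix(c(cos(deg2rad(ang)), -sin(deg2rad(ang)),
                sin(deg2rad(ang)), cos(deg2rad(ang))), 2, 2, byrow = TRUE)
  tr2 <- tr
  xy <- as.matrix(tr$samples[, c("x", "y")]) %*% t(R)
  tr2$samples$x <- xy[, 1] + sh[1]
  tr2$samples$y <- xy[, 2] + sh[2]
  tr2$meta$start_pos <- as.numeric(R %*% tr$meta$start_pos + sh)
  tr2$meta$target_pos <- as.numeric(R %*% tr$meta$target_pos + sh)
  ro2 <- reach_outcomes(tr2)
  expect_equal(ro2$onset_t, ro$onset_t)
  expect_equal(ro2$end_t, ro$end_t)
  expect_equal(ro2$theta_start, ro$theta_start, tolerance = 1e-9)
  expect_equal(ro2$theta_end, ro$theta_end, tolerance = 1e-9)
  expect_equal(ro2$path_length, ro$path_length, tolerance = 1e-9)
})

test_that("outcomes equal the brute-force oracle on clean synthetic trials", {
  p <- bias_field_params(impairment_scale = 0.9, visit_sd_force = 0)
  ct <- controller_params(motor_noise_sd = 0)
  g <- gating_mode("hold_only")
  tg <- target_array()
  for (pert in list(list(type = "none"),
                    list(type = "pulse", sign = "CW"),
                    list(type = "release", direction_deg = 315))) {
    tr <- simulate_reach_trial(p, ct, g, tg["NE", ], tg["C", ],
                               perturbation = pert, seed = 77)
    vel <- estimate_velocity(tr)
    ro <- reach_outcomes(tr, vel = vel)
    or <- oracle_reach(tr, vel)
    expect_equal(ro[c("onset_t", "end_t", "theta_start", "theta_end",
                      "path_length")],
                 or[c("onset_t", "end_t", "theta_start", "theta_end",
                      "path_length")], tolerance = 1e-12)
    if (pert$type == "pulse") {
      expect_equal(pulse_outcomes(tr, vel = vel)[c("settling_time",
                                                   "max_lateral_dev")],
                   oracle_pulse(tr, vel)[c("settling_time",
                                           "max_lateral_dev")],
                   tolerance = 1e-12)
    }
    if (pert$type == "release") {
      expect_equal(
        release_outcomes(tr, vel = vel)[c("time_to_stabilization",
                                          "path_to_stabilization",
                                          "max_deviation")],
        oracle_release(tr, vel)[c("time_to_stabilization",
                                  "path_to_stabilization", "max_deviation")],
        tolerance = 1e-12)
    }
  }
})
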