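# Resting-bias estimation, aggregation, interpolation, summaries and the
# measurement-variance decomposition.

mk_posture <- function(force, pos = c(0, 5), drift = 0, fs = 200,
                       meta = fix_meta(experiment = "rest",
                                       trial_type = "passive_hold",
                                       target_pos = c(0, 5))) {
  t <- seq(0, 10, by = 1 / fs)
  n <- length(t)
  hold <- t >= 5
  x <- rep(pos[1], n); y <- rep(pos[2], n)
  if (drift != 0) {
    # linear drift during the hold period
    y[hold] <- y[hold] + drift * (t[hold] - 5) / 5
  }
  meta$target_pos <- pos
  trial_record(meta, data.frame(t = t, x = x, y = y,
                                fx = rep(force[1], n), fy = rep(force[2], n)),
               events = c(hold_onset = 5))
}

test_that("trial bias is the window mean, with closed-form transient excess", {
  tr <- mk_posture(c(2, -3))
  e <- estimate_trial_bias(tr)
  expect_equal(e$force, c(2, -3))
  expect_false(e$rejected)

  # transient a*exp(-t/0.7) on top of (1, 0)
  a <- 1.5; tau <- 0.7
  t <- seq(0, 10, by = 1 / 200)
  hold <- t >= 5
  fx <- 1 + ifelse(hold, a * exp(-(t - 5) / tau), 0)
  tr2 <- mk_posture(c(0, 0))
  tr2$samples$fx <- fx
  e2 <- estimate_trial_bias(tr2)
  excess <- a * tau * (exp(-2 / tau) - exp(-5 / tau)) / 3
  expect_equal(e2$force[1] - 1, excess, tolerance = 0.01)

  # 2 cm drift during the hold trips the QC proxy
  e3 <- estimate_trial_bias(mk_posture(c(1, 1), drift = 2))
  expect_true(e3$rejected)
  expect_match(e3$reason, "displacement")

  # unstable force trips the SD rule when a noise scale is given
  tr4 <- mk_posture(c(1, 1))
  set.seed(1)
  tr4$samples$fx <- tr4$samples$fx + rnorm(nrow(tr4$samples), 0, 2)
  expect_true(estimate_trial_bias(tr4, noise_scale = 0.3)$rejected)
  expect_false(estimate_trial_bias(tr4, qc = FALSE,
                                   noise_scale = 0.3)$rejected)

  # window outside the trial span errors
  expect_error(estimate_trial_bias(mk_posture(c(1, 1)), window = c(2, 9)),
               "outside trial span")
  expect_error(estimate_trial_bias(fix_mj_trial()), "not a passive_hold")
})

test_that("aggregation averages retained visits per position", {
  forces <- list(c(1, 0), c(3, 0), c(2, 0))
  trials <- lapply(forces, mk_posture)
  map <- suppressWarnings(aggregate_bias_map(trials))
  expect_equal(nrow(map$measurements), 1L)
  expect_equal(c(map$measurements$fx, map$measurements$fy), c(2, 0))
  expect_equal(map$measurements$n_rejected, 0)

  # identical visits: mean equals each visit
  map2 <- suppressWarnings(
    aggregate_bias_map(lapply(1:3, function(i) mk_posture(c(1, -2)))))
  expect_equal(c(map2$measurements$fx, map2$measurements$fy), c(1, -2))

  # one rejected visit of three: mean over the remaining two
  trials3 <- list(mk_posture(c(1, 0)), mk_posture(c(3, 0)),
                  mk_posture(c(99, 0), drift = 2))
  map3 <- suppressWarnings(aggregate_bias_map(trials3))
  expect_equal(map3$measurements$fx, 2)
  expect_equal(map3$measurements$n_rejected, 1)

  # mixing conditions is refused
  t_mix <- list(mk_posture(c(1, 0)),
                mk_posture(c(1, 0),
                           meta = fix_meta(experiment = "rest",
                                           trial_type = "passive_hold",
                                           support = "none")))
  expect_error(aggregate_bias_map(t_mix), "more than one")
})

test_that("piecewise-linear interpolation reproduces nodes and linear fields", {
  # grid of measured positions with the linear field F = (x, 0)
  pts <- expand.grid(x = seq(-6, 6, by = 3), y = seq(-6, 6, by = 3))
  map <- list(measurements = data.frame(x = pts$x, y = pts$y, fx = pts$x,
                                        fy = 0))
  # exact at nodes
  f <- interpolate_bias(map, c(3, -6))
  expect_equal(as.numeric(f), c(3, 0))
  expect_identical(attr(f, "method"), "interpolated")
  # exact for linear fields at arbitrary interior points
  set.seed(2)
  for (i in 1:20) {
    q <- runif(2, -5.5, 5.5)
    expect_equal(as.numeric(interpolate_bias(map, q)), c(q[1], 0),
                 tolerance = 1e-9)
  }
  # outside the hull: nearest measurement, tagged
  fo <- interpolate_bias(map, c(20, 0))
  expect_identical(attr(fo, "method"), "extrapolated")

  # collinear support set errors
  bad <- list(measurements = data.frame(x = 1:5, y = 1:5, fx = 0, fy = 0))
  expect_error(interpolate_bias(bad, c(1, 2)), "collinear")
})

test_that("interpolation agrees with an independent dense triangulation check", {
  # smooth nonlinear field sampled on a jittered grid; the piecewise-linear
  # interpolant must agree with every triangle's plane equation evaluated by
  # brute force (scan over all triangles of the same point set)
  set.seed(5)
  pts <- expand.grid(x = seq(-8, 8, by = 4), y = seq(-8, 8, by = 4))
  pts$x <- pts$x + runif(nrow(pts), -0.5, 0.5)
  pts$y <- pts$y + runif(nrow(pts), -0.5, 0.5)
  fx <- sin(pts$x / 4) * 3 + 0.1 * pts$y
  fy <- cos(pts$y / 5) * 2
  map <- list(measurements = data.frame(x = pts$x, y = pts$y, fx = fx,
                                        fy = fy))
  interp_err <- 0
  for (i in 1:100) {
    q <- runif(2, -6, 6)
    got <- as.numeric(interpolate_bias(map, q))
    # brute force: find any triangle of measured points containing q whose
    # vertices are mutually Delaunay (reuse values, independent containment)
    best <- NULL
    n <- nrow(pts)
    for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
      A <- c(pts$x[a], pts$y[a]); B <- c(pts$x[b], pts$y[b])
      C <- c(pts$x[cc], pts$y[cc])
      det <- (B[2] - C[2]) * (A[1] - C[1]) + (C[1] - B[1]) * (A[2] - C[2])
      if (abs(det) < 1e-9) next
      l1 <- ((B[2] - C[2]) * (q[1] - C[1]) +
               (C[1] - B[1]) * (q[2] - C[2])) / det
      l2 <- ((C[2] - A[2]) * (q[1] - C[1]) +
               (A[1] - C[1]) * (q[2] - C[2])) / det
      l3 <- 1 - l1 - l2
      if (min(l1, l2, l3) < -1e-9) next
      # circumradius as a tightness score: smaller triangles approximate the
      # Delaunay interpolant; keep the containing triangle with the smallest
      # perimeter
      per <- sum(sqrt(sum((A - B)^2)), sqrt(sum((B - C)^2)),
                 sqrt(sum((A - C)^2)))
      val <- c(l1 * fx[a] + l2 * fx[b] + l3 * fx[cc],
               l1 * fy[a] + l2 * fy[b] + l3 * fy[cc])
      if (is.null(best) || per < best$per) best <- list(per = per, val = val)
    }
    interp_err <- max(interp_err, max(abs(got - best$val)))
  }
  # both are piecewise-linear on triangles of the same point set; the field is
  # smooth, so any two reasonable triangulations agree within the
  # second-order term h^2 * max|curvature|
  expect_lt(interp_err, 0.35)
})

test_that("cohort summaries aggregate magnitudes and circular directions", {
  mk_map <- function(id, f, support = "none") {
    tg <- target_array()
    list(subject_id = id, arm = "paretic", support = support,
         group = "patient", fm_ue = 30,
         canonical = data.frame(target = rownames(tg), x = tg[, 1],
                                y = tg[, 2], fx = f[1], fy = f[2],
                                source = "direct"))
  }
  s1 <- summarize_bias(list(mk_map("a", c(0, -5))))
  expect_equal(s1$per_subject$mag_all, 5)
  expect_equal(s1$per_subject$dir_deg, -90)

  # two subjects at -80 and -100 degrees: circular mean -90
  s2 <- summarize_bias(list(
    mk_map("a", 5 * unit_deg(-80)), mk_map("b", 5 * unit_deg(-100))))
  expect_equal(s2$group$dir_deg, -90)
  expect_equal(s2$group$mag_all, 5)
  expect_error(summarize_bias(list()), "empty")
})

test_that("noiseless cohorts recover the generating field nearly exactly", {
  cfg <- fix_cohort_cfg(n = 2, exp2_blocks = 0, n_positions = 7,
                        field = bias_field_params(noise_sd_force = 0,
                                                  visit_sd_force = 0))
  sim <- simulate_cohort(cfg, seed = 9)
  rest <- analyze_rest(sim$trials)
  for (m in rest$maps) {
    gt <- sim$ground_truth$subjects[[m$subject_id]]
    fld <- gt$field[[m$arm]]
    for (i in seq_len(nrow(m$measurements))) {
      b <- bias_at(fld, c(m$measurements$x[i], m$measurements$y[i]),
                   m$support)
      got <- c(m$measurements$fx[i], m$measurements$fy[i])
      # the only residual is the (deterministic) approach transient tail
      expect_lt(max(abs(got - b)), 0.02)
    }
  }
  # support monotonicity per subject
  ps <- rest$summary$per_subject
  for (s in unique(ps$subject_id)) {
    expect_lt(ps$mag_all[ps$subject_id == s & ps$support == "airsled"],
              ps$mag_all[ps$subject_id == s & ps$support == "none"])
  }
})

test_that("QC-flagged trials barely move the cohort summary on clean data", {
  cfg <- fix_cohort_cfg(n = 2, exp2_blocks = 0, n_positions = 7)
  sim <- simulate_cohort(cfg, seed = 14)
  with_qc <- analyze_rest(sim$trials, qc = "auto", noise_scale = 0.3)
  without <- analyze_rest(sim$trials, qc = "none")
  d <- abs(with_qc$summary$per_subject$mag_all -
             without$summary$per_subject$mag_all)
  # visit-level SEM scale of the magnitudes
  sem_scale <- 0.6 / sqrt(3)
  expect_lt(max(d), sem_scale)
})

test_that("variance decomposition matches hand-computed sums of squares", {
  mk_map_visits <- function(v) list(visits = v)
  v1 <- data.frame(x = c(0, 0, 1, 1), y = 0,
                   fx = c(3, 5, 7, 9), fy = 0, rejected = FALSE)
  frac <- variance_decomposition(list(mk_map_visits(v1)))
  mags <- c(3, 5, 7, 9)
  cells <- c(1, 1, 2, 2)
  ssw <- sum((mags - ave(mags, cells))^2)
  sst <- sum((mags - mean(mags))^2)
  expect_equal(frac, ssw / sst)

  # identical visits: fraction 0
  v2 <- data.frame(x = c(0, 0, 1, 1), y = 0, fx = c(2, 2, 5, 5), fy = 0,
                   rejected = FALSE)
  expect_equal(variance_decomposition(list(mk_map_visits(v2))), 0)

  # visits differ but positions share one true magnitude: fraction 1
  v3 <- data.frame(x = c(0, 0, 1, 1), y = 0, fx = c(2, 4, 4, 2), fy = 0,
                   rejected = FALSE)
  expect_equal(variance_decomposition(list(mk_map_visits(v3))), 1)

  # no replicated positions: error
  v4 <- data.frame(x = c(0, 1), y = 0, fx = c(1, 2), fy = 0,
                   rejected = FALSE)
  expect_error(variance_decomposition(list(mk_map_visits(v4))),
               "replicated")
})
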