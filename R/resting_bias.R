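# Experiment-1 analysis: per-trial resting-force estimation, per-position
# aggregation with visit replicates, interpolation at the canonical target
# array, cohort summaries, and measurement-variance decomposition.

#' Estimate the resting force bias of one passive-hold trial
#'
#' Averages the recorded force over the window `window` (seconds, relative to
#' the `hold_onset` event; default the last 3 s of the 5 s hold, i.e. [2, 5],
#' skipping the first 2 s over which approach-velocity effects dissipate).
#' An automated QC proxy flags the trial as rejected when the hand moves more
#' than `disp_limit` cm during the hold, or (when `noise_scale` is supplied)
#' when the within-window force SD exceeds `sd_mult * noise_scale`.
#'
#' @param tr a [trial_record()] passive-hold trial with a `hold_onset` event.
#' @param window numeric length-2, seconds relative to hold onset.
#' @param qc apply the QC proxy (`TRUE`) or never reject (`FALSE`).
#' @param noise_scale sensor-noise scale (N) for the force-stability check;
#'   `NULL` skips that check.
#' @param disp_limit hold-displacement limit, cm.
#' @param sd_mult multiple of `noise_scale` tolerated for the force SD.
#' @return list with `force` (length-2, N), `rejected` (logical), `reason`.
#' @export
estimate_trial_bias <- function(tr, window = c(2, 5), qc = TRUE,
                                noise_scale = NULL, disp_limit = 1,
                                sd_mult = 3) {
  if (tr$meta$trial_type != "passive_hold") {
    stop(sprintf("trial %s: not a passive_hold trial", tr$meta$trial_id),
         call. = FALSE)
  }
  ev <- tr$events
  if (is.null(ev) || !"hold_onset" %in% names(ev)) {
    stop(sprintf("trial %s: no hold_onset event", tr$meta$trial_id),
         call. = FALSE)
  }
  h0 <- ev[["hold_onset"]]
  t <- tr$samples$t
  lo <- h0 + window[1]; hi <- h0 + window[2]
  if (lo < t[1] - 1e-9 || hi > t[length(t)] + 1e-9) {
    stop(sprintf("trial %s: bias window [%g, %g] outside trial span",
                 tr$meta$trial_id, lo, hi), call. = FALSE)
  }
  w <- t >= lo - 1e-9 & t <= hi + 1e-9
  force <- c(mean(tr$samples$fx[w]), mean(tr$samples$fy[w]))

  rejected <- FALSE; reason <- NA_character_
  if (qc) {
    hold <- t >= h0 - 1e-9
    x0 <- tr$samples$x[which(hold)[1]]; y0 <- tr$samples$y[which(hold)[1]]
    disp <- max(sqrt((tr$samples$x[hold] - x0)^2 +
                       (tr$samples$y[hold] - y0)^2))
    if (disp > disp_limit) {
      rejected <- TRUE; reason <- "hold displacement"
    } else if (!is.null(noise_scale)) {
      fsd <- max(stats::sd(tr$samples$fx[w]), stats::sd(tr$samples$fy[w]))
      if (fsd > sd_mult * noise_scale) {
        rejected <- TRUE; reason <- "unstable force"
      }
    }
  }
  list(force = force, rejected = rejected, reason = reason)
}

#' Aggregate passive-hold trials into a bias map
#'
#' Averages retained visit forces per position for one subject x arm x support
#' condition, then fills the canonical 5-target forces by direct lookup (a
#' measured position within `direct_tol` cm of the target) or by
#' piecewise-linear interpolation ([interpolate_bias()]); targets outside the
#' convex hull of the measured positions fall back to the nearest measurement
#' and are tagged `extrapolated` (with a warning).
#'
#' @param trials list of passive-hold [trial_record()]s from one
#'   subject x arm x support condition.
#' @param window,qc,noise_scale,disp_limit,sd_mult passed to
#'   [estimate_trial_bias()].
#' @param direct_tol direct-lookup tolerance, cm.
#' @param canonical matrix of canonical positions (default [target_array()]).
#' @return object of class `bias_map`: list with `subject_id`, `arm`,
#'   `support`, `group`, `fm_ue`, `measurements` (data.frame: position, mean
#'   force, n_visits, n_rejected), `visits` (data.frame of retained visit
#'   forces), and `canonical` (data.frame with the 5 target forces and their
#'   `source` tag).
#' @export
aggregate_bias_map <- function(trials, window = c(2, 5), qc = TRUE,
                               noise_scale = NULL, disp_limit = 1,
                               sd_mult = 3, direct_tol = 0.5,
                               canonical = target_array()) {
  stopifnot(length(trials) >= 1L)
  meta <- trials[[1]]$meta
  key <- vapply(trials, function(tr) paste(tr$meta$subject_id, tr$meta$arm,
                                           tr$meta$support), "")
  if (length(unique(key)) != 1L) {
    stop("trials span more than one subject x arm x support condition",
         call. = FALSE)
  }

  est <- lapply(trials, estimate_trial_bias, window = window, qc = qc,
                noise_scale = noise_scale, disp_limit = disp_limit,
                sd_mult = sd_mult)
  pos <- t(vapply(trials, function(tr) tr$meta$target_pos, numeric(2)))
  visits <- data.frame(x = pos[, 1], y = pos[, 2],
                       fx = vapply(est, function(e) e$force[1], 0),
                       fy = vapply(est, function(e) e$force[2], 0),
                       rejected = vapply(est, function(e) e$rejected, TRUE))

  pkey <- paste(round(visits$x, 6), round(visits$y, 6))
  upos <- !duplicated(pkey)
  meas <- do.call(rbind, lapply(pkey[upos], function(k) {
    v <- visits[pkey == k, ]
    keep <- v[!v$rejected, ]
    if (nrow(keep) == 0L) keep <- v  # no retained visit: fall back, flag all
    data.frame(x = v$x[1], y = v$y[1],
               fx = mean(keep$fx), fy = mean(keep$fy),
               n_visits = nrow(v), n_rejected = sum(v$rejected))
  }))

  map <- structure(list(subject_id = meta$subject_id, arm = meta$arm,
                        support = meta$support, group = meta$group,
                        fm_ue = meta$fm_ue, measurements = meas,
                        visits = visits, canonical = NULL),
                   class = "bias_map")
  map$canonical <- canonical_forces(map, direct_tol = direct_tol,
                                    canonical = canonical)
  map
}

canonical_forces <- function(map, direct_tol = 0.5,
                             canonical = target_array()) {
  meas <- map$measurements
  if (is.null(map$.tri) && nrow(meas) >= 3) {
    map$.tri <- tryCatch(
      delaunay_triangulate(as.matrix(meas[, c("x", "y")])),
      error = function(e) NULL)
  }
  out <- data.frame(target = rownames(canonical), x = canonical[, 1],
                    y = canonical[, 2], fx = NA_real_, fy = NA_real_,
                    source = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    d <- sqrt((meas$x - out$x[i])^2 + (meas$y - out$y[i])^2)
    j <- which.min(d)
    if (d[j] <= direct_tol) {
      out$fx[i] <- meas$fx[j]; out$fy[i] <- meas$fy[j]
      out$source[i] <- "direct"
    } else {
      f <- tryCatch(interpolate_bias(map, c(out$x[i], out$y[i])),
                    error = function(e) {
                      # too few / collinear positions: nearest measurement
                      v <- c(meas$fx[j], meas$fy[j])
                      attr(v, "method") <- "extrapolated"
                      v
                    })
      out$fx[i] <- f[1]; out$fy[i] <- f[2]
      out$source[i] <- attr(f, "method")
      if (out$source[i] == "extrapolated") {
        warning(sprintf("%s %s %s: canonical target %s outside measured hull",
                        map$subject_id, map$arm, map$support, out$target[i]),
                call. = FALSE)
      }
    }
  }
  out
}

# ---- Delaunay triangulation (Bowyer-Watson) --------------------------------
# Small n (15-25 measured positions); returns a matrix of vertex index
# triples. Used for piecewise-linear interpolation of the bias field.

delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  # collinearity check
  a <- pts[2, ] - pts[1, ]
  cr <- abs(a[1] * (pts[, 2] - pts[1, 2]) - a[2] * (pts[, 1] - pts[1, 1]))
  scale <- max(1, max(abs(pts)))
  if (all(cr < 1e-9 * scale^2)) {
    stop("measured positions are collinear; cannot triangulate",
         call. = FALSE)
  }

  mid <- colMeans(pts)
  r <- max(sqrt((pts[, 1] - mid[1])^2 + (pts[, 2] - mid[2])^2)) * 20 + 1
  sup <- rbind(mid + c(0, 2 * r), mid + c(-1.8 * r, -r), mid + c(1.8 * r, -r))
  all_pts <- rbind(pts, sup)
  tris <- list(c(n + 1L, n + 2L, n + 3L))

  circum_contains <- function(tri, p) {
    a <- all_pts[tri[1], ]; b <- all_pts[tri[2], ]; c_ <- all_pts[tri[3], ]
    ax <- a[1] - p[1]; ay <- a[2] - p[2]
    bx <- b[1] - p[1]; by <- b[2] - p[2]
    cx <- c_[1] - p[1]; cy <- c_[2] - p[2]
    det <- (ax * ax + ay * ay) * (bx * cy - cx * by) -
      (bx * bx + by * by) * (ax * cy - cx * ay) +
      (cx * cx + cy * cy) * (ax * by - bx * ay)
    orient <- (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])
    if (orient < 0) det <- -det
    det > 0
  }

  for (ip in seq_len(n)) {
    p <- pts[ip, ]
    bad <- vapply(tris, circum_contains, TRUE, p = p)
    # boundary polygon: edges of bad triangles not shared by two bad triangles
    edges <- do.call(rbind, lapply(tris[bad], function(tr) {
      rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))
    }))
    if (is.null(edges)) next
    ek <- paste(edges[, 1], edges[, 2])
    keep <- !(ek %in% ek[duplicated(ek)])
    boundary <- edges[keep, , drop = FALSE]
    tris <- tris[!bad]
    for (e in seq_len(nrow(boundary))) {
      tris[[length(tris) + 1L]] <- c(boundary[e, 1], boundary[e, 2], ip)
    }
  }
  tris <- Filter(function(tr) all(tr <= n), tris)
  if (length(tris) == 0L) {
    stop("triangulation degenerate", call. = FALSE)
  }
  do.call(rbind, tris)
}

barycentric <- function(p, a, b, c_) {
  det <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
  if (abs(det) < 1e-14) return(NULL)
  l1 <- ((b[2] - c_[2]) * (p[1] - c_[1]) + (c_[1] - b[1]) * (p[2] - c_[2])) /
    det
  l2 <- ((c_[2] - a[2]) * (p[1] - c_[1]) + (a[1] - c_[1]) * (p[2] - c_[2])) /
    det
  c(l1, l2, 1 - l1 - l2)
}

#' Interpolate a bias map at an arbitrary position
#'
#' Component-wise piecewise-linear (barycentric) interpolation on a Delaunay
#' triangulation of the measured positions. Queries outside the convex hull
#' fall back to the nearest measurement and are tagged `"extrapolated"`
#' (attribute `method`); interior queries are tagged `"interpolated"`.
#' Exact on linear fields and at the measured positions.
#'
#' @param map a [aggregate_bias_map()] result (or any list with a
#'   `measurements` data.frame of x, y, fx, fy).
#' @param q length-2 query position (cm).
#' @return length-2 force (N) with attribute `method`.
#' @export
interpolate_bias <- function(map, q) {
  meas <- map$measurements
  if (nrow(meas) < 3L) stop("need >= 3 measured positions", call. = FALSE)
  pts <- as.matrix(meas[, c("x", "y")])
  tris <- map$.tri
  if (is.null(tris)) tris <- delaunay_triangulate(pts)
  tol <- -1e-9
  for (k in seq_len(nrow(tris))) {
    tr <- tris[k, ]
    lam <- barycentric(q, pts[tr[1], ], pts[tr[2], ], pts[tr[3], ])
    if (is.null(lam)) next
    if (all(lam >= tol)) {
      f <- c(sum(lam * meas$fx[tr]), sum(lam * meas$fy[tr]))
      attr(f, "method") <- "interpolated"
      return(f)
    }
  }
  d <- sqrt((meas$x - q[1])^2 + (meas$y - q[2])^2)
  j <- which.min(d)
  f <- c(meas$fx[j], meas$fy[j])
  attr(f, "method") <- "extrapolated"
  f
}

#' Summarize bias maps across a cohort
#'
#' Per subject (map): mean canonical force magnitude within each proximity
#' class (distant = center + two upper targets, near = two lower targets) and
#' overall, and the circular mean direction over the five targets. Cohort rows
#' aggregate subjects within group x arm x support with plain mean +/- SEM for
#' magnitudes and circular mean +/- SEM for directions.
#'
#' @param maps list of `bias_map` objects.
#' @return list with `per_subject` and `group` data.frames.
#' @export
summarize_bias <- function(maps) {
  if (length(maps) == 0L) stop("empty cohort", call. = FALSE)
  prox <- target_proximity()
  per <- do.call(rbind, lapply(maps, function(m) {
    cf <- m$canonical
    mag <- sqrt(cf$fx^2 + cf$fy^2)
    ang <- vec_angle_deg(cbind(cf$fx, cf$fy))
    data.frame(subject_id = m$subject_id, group = m$group, arm = m$arm,
               support = m$support, fm_ue = m$fm_ue,
               mag_distant = mean(mag[prox[cf$target] == "distant"]),
               mag_near = mean(mag[prox[cf$target] == "near"]),
               mag_all = mean(mag),
               dir_deg = circ_mean_sem(ang)$mean_deg,
               stringsAsFactors = FALSE)
  }))
  gkey <- interaction(per$group, per$arm, per$support, drop = TRUE)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  grp <- do.call(rbind, lapply(levels(gkey), function(g) {
    d <- per[gkey == g, ]
    cm <- circ_mean_sem(d$dir_deg)
    data.frame(group = d$group[1], arm = d$arm[1], support = d$support[1],
               n = nrow(d),
               mag_distant = mean(d$mag_distant),
               mag_distant_sem = sem(d$mag_distant),
               mag_near = mean(d$mag_near), mag_near_sem = sem(d$mag_near),
               mag_all = mean(d$mag_all), mag_all_sem = sem(d$mag_all),
               dir_deg = cm$mean_deg, dir_sem = cm$sem_deg,
               stringsAsFactors = FALSE)
  }))
  list(per_subject = per, group = grp)
}

#' Fraction of variance attributable to repeated measurement
#'
#' One-way decomposition on visit-level bias magnitudes: the within-position
#' (measurement) sum of squares over the total sum of squares, pooling all
#' positions, conditions and subjects. Rejected visits are excluded.
#'
#' @param maps list of `bias_map` objects with visit-level forces.
#' @return fraction in `[0, 1]`.
#' @export
variance_decomposition <- function(maps) {
  rows <- do.call(rbind, lapply(seq_along(maps), function(i) {
    v <- maps[[i]]$visits
    v <- v[!v$rejected, ]
    if (nrow(v) == 0L) return(NULL)
    data.frame(cell = paste(i, round(v$x, 6), round(v$y, 6)),
               mag = sqrt(v$fx^2 + v$fy^2))
  }))
  counts <- table(rows$cell)
  if (!any(counts >= 2)) {
    stop("no position with replicated retained visits", call. = FALSE)
  }
  grand <- mean(rows$mag)
  cell_means <- tapply(rows$mag, rows$cell, mean)
  ss_within <- sum((rows$mag - cell_means[rows$cell])^2)
  ss_total <- sum((rows$mag - grand)^2)
  if (ss_total == 0) return(0)
  ss_within / ss_total
}
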