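# Inference layer: bias projections onto movement/perturbation geometry,
# extreme-instance selection, paired contrasts, per-subject sensitivity
# regressions, the Response Asymmetry Index, circular statistics, and the
# Experiment-1 mixed ANOVA.

#' Project a resting bias onto movement or perturbation geometry
#'
#' Lateral contexts (`reach_start`, `reach_end`, `pulse`): dot product of the
#' bias with the unit vector 90 degrees CCW of the movement direction (CCW
#' positive). Release context: dot product with the unit vector of the
#' displacement direction (opposite the removed force); positive = aligned
#' with the perturbing displacement. The resistive component used by the
#' release-context sensitivity analyses is minus this value.
#'
#' @param bias length-2 force (N).
#' @param context one of `"reach_start"`, `"reach_end"`, `"pulse"`,
#'   `"release"`.
#' @param geometry list with `movement_dir_deg` (lateral contexts) or
#'   `release_dir_deg` (the imposed-force direction; release context).
#' @return signed component, N.
#' @export
project_bias <- function(bias, context = c("reach_start", "reach_end",
                                           "pulse", "release"),
                         geometry) {
  context <- match.arg(context)
  if (context == "release") {
    if (is.null(geometry$release_dir_deg) || is.na(geometry$release_dir_deg)) {
      stop("release context needs geometry$release_dir_deg", call. = FALSE)
    }
    u <- unit_deg(geometry$release_dir_deg + 180)
  } else {
    if (is.null(geometry$movement_dir_deg) ||
        is.na(geometry$movement_dir_deg)) {
      stop("lateral context needs geometry$movement_dir_deg", call. = FALSE)
    }
    u <- unit_deg(geometry$movement_dir_deg + 90)
  }
  sum(bias * u)
}

#' Select the extreme-instance pair
#'
#' For lateral contexts, picks the direction keys whose projected bias
#' component is the most CCW (maximum) and the most CW (minimum); for the
#' release context, projections are first negated to the resistive scale so
#' the pair is (most opposed, most aligned). Outcome means are per-instance
#' trial means of `outcome`. Ties are broken by lexicographic direction key.
#'
#' @param projected data.frame with columns `direction_key` and `component`
#'   (signed N, per [project_bias()]'s native sign for the context).
#' @param outcomes data.frame with columns `direction_key` and `outcome`
#'   (one row per trial).
#' @param context as in [project_bias()].
#' @return list of class `extreme_pair`: `extreme_high`/`extreme_low`
#'   direction keys (high = most CCW, or most opposed for release),
#'   `component_values` (on the context's ordering scale: lateral CCW+, or
#'   resistive+ for release), `outcome_means`, `n_trials`.
#' @export
select_extremes <- function(projected, outcomes, context = "reach_start") {
  stopifnot(all(c("direction_key", "component") %in% names(projected)),
            all(c("direction_key", "outcome") %in% names(outcomes)))
  if (nrow(projected) < 2L) stop("need >= 2 direction keys", call. = FALSE)
  comp <- projected$component
  if (context == "release") comp <- -comp  # resistive scale
  if (diff(range(comp)) < 1e-12) {
    stop("degenerate selection: all projected components equal",
         call. = FALSE)
  }
  ord <- order(-comp, projected$direction_key)  # lexicographic tie-break
  hi <- projected$direction_key[ord[1]]
  ord2 <- order(comp, projected$direction_key)
  lo <- projected$direction_key[ord2[1]]
  mean_of <- function(key) {
    v <- outcomes$outcome[outcomes$direction_key == key]
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
  }
  mh <- mean_of(hi); ml <- mean_of(lo)
  structure(list(extreme_high = hi, extreme_low = lo,
                 component_values = c(comp[ord[1]], comp[ord2[1]]),
                 outcome_means = c(mh["mean"], ml["mean"]),
                 n_trials = c(mh["n"], ml["n"])),
            class = "extreme_pair")
}

#' Paired within-subject contrast
#'
#' Classical paired t-test on `a - b`, two-sided.
#'
#' @param values_a,values_b per-subject values, paired by position.
#' @return list with `mean_diff`, `t`, `df`, `p`.
#' @export
paired_contrast <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2L)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(mean_diff = 0, t = 0,
                                 df = length(d) - 1L, p = 1))
    stop("zero variance of paired differences (exact ties); t undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Per-subject sensitivity (slope) of an outcome to the projected bias
#'
#' Ordinary least-squares slope per subject over all trials (or over
#' direction means with `mode = "direction_means"`), followed by a one-sample
#' t-test of the subject slopes against zero. Subjects with a constant bias
#' regressor are dropped with a warning.
#'
#' @param data data.frame with columns `subject_id`, `bias` (N) and
#'   `outcome` (one row per trial; `direction_key` required for the
#'   direction-means mode).
#' @param mode `"trials"` (default) or `"direction_means"`.
#' @return list of class `sensitivity_result`: `slopes` (named per subject),
#'   `mean`, `sem`, `t`, `df`, `p`.
#' @export
sensitivity <- function(data, mode = c("trials", "direction_means")) {
  mode <- match.arg(mode)
  stopifnot(all(c("subject_id", "bias", "outcome") %in% names(data)))
  data <- data[!is.na(data$outcome) & !is.na(data$bias), ]
  if (mode == "direction_means") {
    stopifnot("direction_key" %in% names(data))
    agg <- stats::aggregate(cbind(bias, outcome) ~ subject_id + direction_key,
                            data = data, FUN = mean)
    data <- agg
  }
  subs <- unique(data$subject_id)
  slopes <- vapply(subs, function(s) {
    d <- data[data$subject_id == s, ]
    if (nrow(d) < 2L || stats::var(d$bias) == 0) return(NA_real_)
    stats::cov(d$bias, d$outcome) / stats::var(d$bias)
  }, 0)
  names(slopes) <- subs
  if (anyNA(slopes)) {
    warning(sprintf("dropping %d subject(s) with constant bias regressor",
                    sum(is.na(slopes))), call. = FALSE)
    slopes <- slopes[!is.na(slopes)]
  }
  n <- length(slopes)
  if (n < 2L) stop("need >= 2 subjects with estimable slopes", call. = FALSE)
  m <- mean(slopes); s <- stats::sd(slopes)
  if (s <= 1e-10 * max(1, abs(m))) {
    return(structure(list(slopes = slopes, mean = m, sem = 0,
                          t = if (m == 0) 0 else Inf, df = n - 1L,
                          p = if (m == 0) 1 else 0),
                     class = "sensitivity_result"))
  }
  tt <- stats::t.test(slopes, mu = 0)
  structure(list(slopes = slopes, mean = m, sem = s / sqrt(n),
                 t = unname(tt$statistic), df = n - 1L, p = tt$p.value),
            class = "sensitivity_result")
}

#' Response Asymmetry Index
#'
#' `RAI = (r_aligned - r_opposed) / (r_aligned + r_opposed)`, where
#' `r_aligned` is the (nonnegative) response magnitude in the instance where
#' the resting bias is most aligned with the perturbation and `r_opposed`
#' where it is most opposed. Scale-invariant; in `[-1, 1]` for nonnegative
#' responses; positive values indicate larger responses when the bias is
#' aligned with the perturbation (i.e. the bias interacts with the response).
#'
#' @param r_aligned,r_opposed nonnegative response magnitudes (deviation cm or
#'   settling time s).
#' @return list with `r_aligned`, `r_opposed`, `rai`.
#' @export
response_asymmetry_index <- function(r_aligned, r_opposed) {
  if (!is.finite(r_aligned + r_opposed) || r_aligned + r_opposed <= 0) {
    stop("RAI needs r_aligned + r_opposed > 0", call. = FALSE)
  }
  list(r_aligned = r_aligned, r_opposed = r_opposed,
       rai = (r_aligned - r_opposed) / (r_aligned + r_opposed))
}

#' Circular mean and SEM of angles
#'
#' Mean direction from the mean resultant vector; SEM is the circular standard
#' deviation `sqrt(-2 log(Rbar))` divided by `sqrt(n)`, in degrees.
#'
#' @param angles_deg angles in degrees.
#' @return list with `mean_deg` (in (-180, 180]), `sem_deg`, `rbar`.
#' @export
circ_mean_sem <- function(angles_deg) {
  n <- length(angles_deg)
  stopifnot(n >= 1L)
  a <- deg2rad(angles_deg)
  cs <- mean(cos(a)); sn <- mean(sin(a))
  rbar <- sqrt(cs^2 + sn^2)
  if (rbar < 1e-12) {
    stop("circular mean undefined: zero resultant length", call. = FALSE)
  }
  list(mean_deg = wrap_deg(rad2deg(atan2(sn, cs))),
       sem_deg = rad2deg(sqrt(-2 * log(min(rbar, 1)))) / sqrt(n),
       rbar = rbar)
}

#' Mixed ANOVA of resting-bias magnitudes
#'
#' Repeated-measures ANOVA with within-subject factors Support and Proximity,
#' the continuous between-subject covariate FM-UE, and all two-way
#' interactions, with subject as the error stratum for the between-subject
#' effect (`aov` with `Error(subject)`). Effect sizes are classical eta
#' squared (`SS_effect / SS_total` with the total pooled over all strata);
#' partial eta squared is also reported.
#'
#' @param data data.frame with columns `subject_id`, `support`
#'   (`airsled`/`none`), `proximity` (`distant`/`near`), `magnitude` (N) and
#'   `fm_ue` (constant within subject); one row per subject x support x
#'   proximity cell (balanced 2 x 2 within design).
#' @return data.frame with one row per effect: `term`, `df`, `ss`, `F`, `p`,
#'   `eta_sq`, `eta_sq_partial`.
#' @export
rest_anova <- function(data) {
  need <- c("subject_id", "support", "proximity", "magnitude", "fm_ue")
  stopifnot(all(need %in% names(data)))
  tab <- table(data$subject_id, data$support, data$proximity)
  if (any(tab != 1)) {
    stop("design must have exactly one magnitude per subject x support x proximity cell",
         call. = FALSE)
  }
  d <- data.frame(subject = factor(data$subject_id),
                  support = factor(data$support),
                  proximity = factor(data$proximity),
                  fm_ue = as.numeric(data$fm_ue),
                  magnitude = as.numeric(data$magnitude))
  fit <- stats::aov(magnitude ~ fm_ue * support + fm_ue * proximity +
                      support * proximity + Error(subject), data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    terms <- trimws(rownames(st))
    for (k in seq_along(terms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        term = terms[k], df = st[k, "Df"], ss = st[k, "Sum Sq"],
        F = if ("F value" %in% colnames(st)) st[k, "F value"] else NA_real_,
        p = if ("Pr(>F)" %in% colnames(st)) st[k, "Pr(>F)"] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ss_total <- sum(out$ss)
  degenerate <- ss_total < sqrt(.Machine$double.eps)
  out$eta_sq <- if (!degenerate) out$ss / ss_total else 0
  # partial eta^2: SS_effect / (SS_effect + SS_error of the effect's stratum)
  strata_resid <- vapply(sm, function(stratum) {
    st <- stratum[[1]]
    r <- trimws(rownames(st)) == "Residuals"
    if (any(r)) st[r, "Sum Sq"] else NA_real_
  }, 0)
  stratum_of <- rep(seq_along(sm), vapply(sm, function(s) nrow(s[[1]]), 0L))
  denom <- out$ss + strata_resid[stratum_of]
  out$eta_sq_partial <- ifelse(!degenerate & denom > 0, out$ss / denom, 0)
  out[out$term != "Residuals", c("term", "df", "ss", "F", "p", "eta_sq",
                                 "eta_sq_partial")]
}
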