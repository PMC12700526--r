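# Small fixture builders used across test files.

fix_meta <- function(...) {
  args <- utils::modifyList(
    list(subject_id = "S1", group = "control", arm = "dominant-proxy",
         side = "right", support = "airsled", experiment = "reach",
         trial_type = "reach_unperturbed", block = 1L,
         start_pos = c(0, 0), target_pos = c(0, 10), trial_id = "t1"),
    list(...))
  do.call(trial_meta, args)
}

# trial record from explicit position series at 200 Hz (zero forces)
fix_trial_xy <- function(x, y, fs = 200, meta = fix_meta(), events = NULL,
                         fx = NULL, fy = NULL) {
  n <- length(x)
  if (is.null(fx)) fx <- numeric(n)
  if (is.null(fy)) fy <- numeric(n)
  trial_record(meta, data.frame(t = (seq_len(n) - 1) / fs, x = x, y = y,
                                fx = fx, fy = fy), events = events)
}

# a clean minimum-jerk reach trial along +y, D cm over T s, with lead-in
# and trailing hold
fix_mj_trial <- function(D = 10, T = 0.7, lead = 0.25, trail = 0.5,
                         fs = 200, meta = fix_meta()) {
  t <- seq(0, lead + T + trail, by = 1 / fs)
  y <- mj_pos(pmax(0, t - lead), D, T)
  fix_trial_xy(numeric(length(t)), y, fs = fs, meta = meta,
               events = c(go_cue = lead))
}

# small patient cohort config for pipeline tests
fix_cohort_cfg <- function(n = 2, gating = "hold_only", exp2_blocks = 1,
                           n_positions = 7, impairment = NULL, ...) {
  if (is.null(impairment)) impairment <- seq(0.5, 1, length.out = n)
  subs <- data.frame(subject_id = sprintf("P%02d", seq_len(n)),
                     group = "patient", side = "right",
                     impairment = impairment, gating = gating)
  cohort_config(subs, n_positions = n_positions, visits = 3,
                exp2_blocks = exp2_blocks, exp1_arms = "paretic",
                exp1_supports = c("none", "airsled"), exp2_arms = "paretic",
                ...)
}
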