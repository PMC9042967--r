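# Shared fixtures, generated in code and memoized across test files.

.fix <- new.env(parent = emptyenv())

fix_config <- function() trial_config(duration_s = 30,
                                      duration_range_s = c(20, 30))

# Small two-end cohort: 4 experts + 4 novices, 2 trials each, 20-30 s.
fix_cohort <- function() {
  if (is.null(.fix$cohort)) {
    des <- cohort_design(data.frame(
      label = c("expert", "novice"), n_participants = c(4L, 4L),
      skill_mean = c(0.8, -0.8), skill_sd = c(0.1, 0.1)), 2L)
    streams <- simulate_cohort(des, fix_config(), seed = 7L)
    .fix$cohort <- lapply(streams, function(s) extract_metrics(regularize(s)))
  }
  .fix$cohort
}

fix_split <- function() {
  if (is.null(.fix$split))
    .fix$split <- split_by_participant(fix_cohort(), seed = 3L)
  .fix$split
}

# Briefly trained expertise model over the small cohort.
fix_model <- function() {
  if (is.null(.fix$model))
    .fix$model <- train_expertise_model(
      fix_cohort(), fix_split(), training_schedule(epochs = 15, seed = 11L))
  .fix$model
}

# Briefly trained risk model predicting the bleeding-rate trajectory.
fix_risk_model <- function() {
  if (is.null(.fix$risk))
    .fix$risk <- train_feedback_model(
      "bleeding_rate", fix_cohort(), fix_split(),
      training_schedule(epochs = 40, seed = 13L))
  .fix$risk
}

# Hand-built raw stream from channel vectors (defaults: everything quiet).
make_stream <- function(time, pos_dom = NULL, pos_nd = NULL,
                        force_dom = 0, force_nd = 0,
                        active_dom = TRUE, active_nd = FALSE,
                        tumor = 0, blood = 0, damage = 0,
                        group = "expert", pid = "X01") {
  n <- length(time)
  if (is.null(pos_dom)) pos_dom <- matrix(0, n, 3)
  if (is.null(pos_nd)) pos_nd <- matrix(0, n, 3)
  rec <- function(x) if (length(x) == 1) rep(x, n) else x
  structure(data.frame(
    time = time,
    pos_dom_x = pos_dom[, 1], pos_dom_y = pos_dom[, 2],
    pos_dom_z = pos_dom[, 3],
    pos_nd_x = pos_nd[, 1], pos_nd_y = pos_nd[, 2], pos_nd_z = pos_nd[, 3],
    force_dom = rec(force_dom), force_nd = rec(force_nd),
    active_dom = rec(active_dom), active_nd = rec(active_nd),
    tumor_removed = rec(tumor), blood_present = rec(blood),
    healthy_damage = rec(damage)),
    class = c("raw_stream", "data.frame"),
    participant_id = pid, trial_index = 1L, group_label = group,
    skill = NA_real_, seed = NA_integer_)
}

# Random wiggly fixture stream for oracle-equivalence checks.
random_stream <- function(seed, duration_s = 2) {
  set.seed(seed)
  n <- round(duration_s / 0.02)
  t <- (seq_len(n) - 1) * 0.02
  wig <- function() cbind(cumsum(rnorm(n)), cumsum(rnorm(n)),
                          cumsum(rnorm(n)))
  make_stream(t, pos_dom = wig(), pos_nd = wig() + 5,
              force_dom = abs(rnorm(n)), force_nd = abs(rnorm(n)),
              active_dom = runif(n) > 0.5, active_nd = runif(n) > 0.5,
              tumor = cumsum(abs(rnorm(n)) * 1e-4),
              blood = abs(cumsum(rnorm(n)) * 0.01),
              damage = cumsum(abs(rnorm(n)) * 1e-4))
}

# Synthetic score series with prescribed scores.
make_score_series <- function(scores, pid = "P01", trial = 1L,
                              group = "expert") {
  structure(data.frame(time = (seq_along(scores) - 1) * 0.2, score = scores),
            class = c("score_series", "data.frame"),
            task_average = mean(scores), participant_id = pid,
            trial_index = trial, group_label = group)
}
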