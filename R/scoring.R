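# Scoring: apply a trained expertise model to a trial, aggregate to task and
# participant averages, and export flagged low-score intervals.

#' Score one trial with a trained expertise model
#'
#' Normalizes the trial with the model's stored training-set statistics and
#' emits one expertise score per 0.2 s metric row.  Scores are deliberately
#' unclipped: values above +1 or below -1 pass through.  The arithmetic mean
#' of the per-timestep scores is attached as the task average.
#'
#' @param model a `trained_model`.
#' @param trial an unnormalized `metric_series` whose manifest matches the
#'   model's.
#' @return a `score_series` data.frame (`time`, `score`) with attributes
#'   `task_average`, `participant_id`, `trial_index`, `group_label`.
#' @export
score_trial <- function(model, trial) {
  stopifnot(inherits(model, "trained_model"))
  if (isTRUE(attr(trial, "normalized")))
    stop("trial is already normalized; score_trial applies the model's stats")
  check_manifest(trial, model$stats$metric_names)
  x <- metric_matrix(apply_normalization(trial, model$stats))
  score <- as.numeric(lstm_forward_cpp(x, model$weights))
  structure(data.frame(time = trial$time, score = score),
            class = c("score_series", "data.frame"),
            task_average = mean(score),
            participant_id = attr(trial, "participant_id"),
            trial_index = attr(trial, "trial_index"),
            group_label = attr(trial, "group_label"),
            skill = attr(trial, "skill"))
}

#' Task average of a score series
#' @param series a `score_series`.
#' @return the trial's mean per-timestep score.
#' @export
task_average <- function(series) attr(series, "task_average")

#' Average task scores across a participant's trials
#'
#' Unweighted mean of the available task averages; missing trials are simply
#' absent (no imputation).
#'
#' @param series list of `score_series` from one participant.
#' @return a `participant_score` list: `participant_id`, `trial_averages`,
#'   `participant_average`, `n_trials_used`.
#' @export
participant_average <- function(series) {
  if (length(series) == 0) stop("no trials: cannot average an empty list")
  avgs <- vapply(series, task_average, numeric(1))
  structure(list(participant_id = attr(series[[1]], "participant_id"),
                 group_label = attr(series[[1]], "group_label"),
                 trial_averages = avgs,
                 participant_average = mean(avgs),
                 n_trials_used = length(avgs)),
            class = "participant_score")
}

#' Score a whole cohort and summarize per participant
#'
#' @param model a `trained_model`.
#' @param trials list of unnormalized `metric_series`.
#' @return list of `participant_score`, one per participant, in first-seen
#'   order.
#' @export
score_cohort <- function(model, trials) {
  scored <- lapply(trials, score_trial, model = model)
  pids <- vapply(scored, function(s) attr(s, "participant_id"), character(1))
  lapply(split(scored, factor(pids, levels = unique(pids))),
         participant_average)
}

#' Flag contiguous intervals of less-skilled performance
#'
#' Maximal runs of consecutive 0.2 s steps whose score falls below the
#' threshold, returned as half-open `[start_s, end_s)` intervals relative to
#' the trial clock.
#'
#' @param series a `score_series`.
#' @param threshold score threshold; default 0, the expert/novice midpoint.
#' @return data.frame with columns `start_s`, `end_s` (possibly 0 rows).
#' @export
flag_intervals <- function(series, threshold = 0) {
  below <- series$score < threshold
  step <- if (nrow(series) > 1) series$time[2] - series$time[1] else 0.2
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start_s = series$time[1] + (starts[keep] - 1) * step,
             end_s = series$time[1] + ends[keep] * step)
}
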