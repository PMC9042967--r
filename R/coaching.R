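# Inverse models: the same sequence architecture run "in reverse" to predict
# one performance metric from the remaining fifteen plus an expertise-level
# input channel.  Coaching mode forces that channel to the expert code (1) to
# produce an expert-level target trajectory; risk mode sets it to the user's
# own level code to predict bleeding / healthy-tissue-injury trajectories.

#' The five inverse models
#'
#' Three coaching models (aspirator force, bipolar forceps force, instrument
#' tip separation) and two risk models (bleeding, healthy-tissue injury).
#'
#' @return data.frame with columns `model`, `target_metric`, `mode`.
#' @export
feedback_roster <- function() {
  data.frame(
    model = c("aspirator_force", "bipolar_force", "tip_separation",
              "bleeding", "tissue_injury"),
    target_metric = c("force_aspirator", "force_bipolar", "tip_separation",
                      "bleeding_rate", "healthy_damage"),
    mode = c("coaching", "coaching", "coaching", "risk", "risk"),
    stringsAsFactors = FALSE)
}

#' Expertise level codes for the risk models
#'
#' Closed vocabulary: expert 1, senior 0.33, junior -0.33, novice (medical
#' student) -1.
#'
#' @param level level name, or a number already equal to one of the codes.
#' @return the numeric code.
#' @export
expertise_level_code <- function(level) {
  codes <- c(expert = 1, senior = 0.33, junior = -0.33,
             novice = -1, `medical student` = -1)
  if (is.numeric(level)) {
    if (length(level) == 1 && any(abs(level - codes) < 1e-9))
      return(level)
    stop("invalid expertise level: ", level)
  }
  key <- tolower(as.character(level))
  if (!key %in% names(codes)) stop("invalid expertise level: ", level)
  unname(codes[key])
}

#' Input metric set of an inverse model
#'
#' All manifest metrics except the target itself and any metric reduced from
#' the same raw channel (the blood-volume level and the bleeding rate are
#' both reductions of the blood channel, so each is excluded from the
#' other's inputs -- predicting bleeding from a copy of the bleeding signal
#' would be leakage and would mask the expertise input).
#'
#' @param target_metric metric name from the manifest.
#' @return character vector of input metric names (the expertise channel is
#'   appended separately at model build time).
#' @export
feedback_input_metrics <- function(target_metric) {
  man <- metric_manifest()
  if (!target_metric %in% man$name)
    stop("manifest error: unknown target metric '", target_metric, "'")
  siblings <- list(bleeding_rate = "blood_volume",
                   blood_volume = "bleeding_rate")
  setdiff(man$name, c(target_metric, siblings[[target_metric]]))
}

# T x (k+1) input matrix: normalized input metrics + expertise channel.
feedback_input_matrix <- function(trial_norm, input_metrics, level_value) {
  x <- as.matrix(trial_norm[, input_metrics, drop = FALSE])
  cbind(x, expertise = rep(level_value, nrow(x)))
}

#' Train an inverse feedback model
#'
#' Sequence-to-sequence regressor predicting the (normalized) target metric
#' at each 0.2 s step from the other fifteen metrics plus a per-trial
#' constant expertise channel (+1 for expert trials, -1 for novice trials at
#' training time).  Same layer stack, node rule (inputs + 1 = 17 hidden
#' units) and schedule family as the assessment model.
#'
#' @param target_metric metric name from the manifest.
#' @param trials list of unnormalized expert/novice `metric_series`.
#' @param split a [split_by_participant()] over `trials`.
#' @param schedule a [training_schedule()].
#' @param dropout_rate dropout after each LSTM layer.
#' @return a `feedback_model`.
#' @export
train_feedback_model <- function(target_metric, trials, split, schedule,
                                 dropout_rate = 0.2) {
  man <- metric_manifest()
  input_metrics <- feedback_input_metrics(target_metric)
  stopifnot(inherits(split, "split"))
  idx_tr <- split$subsets$train
  stats <- fit_normalization(trials[idx_tr])
  prep <- function(idx) {
    xs <- list(); ys <- list()
    for (tr in trials[idx]) {
      z <- apply_normalization(tr, stats)
      lev <- expertise_level_code(attr(tr, "group_label"))
      xs[[length(xs) + 1]] <- feedback_input_matrix(z, input_metrics, lev)
      ys[[length(ys) + 1]] <- z[[target_metric]]
    }
    list(xs = xs, ys = ys)
  }
  tr <- prep(idx_tr)
  va <- prep(split$subsets$validation)
  if (is.null(schedule$minibatch_size))
    schedule$minibatch_size <- minibatch_size(length(idx_tr), 6)
  spec <- build_model(length(input_metrics) + 1L, dropout_rate)
  fit <- train_sequence_model(tr$xs, tr$ys, spec, schedule, va$xs, va$ys)
  mode <- feedback_roster()$mode[match(target_metric,
                                       feedback_roster()$target_metric)]
  structure(list(weights = fit$weights, spec = spec, schedule = schedule,
                 stats = stats, manifest = man,
                 target_metric = target_metric,
                 input_metrics = input_metrics,
                 mode = if (is.na(mode)) "coaching" else mode,
                 history = fit$history),
            class = "feedback_model")
}

feedback_predict <- function(model, trial, level_value, capture_inputs) {
  check_manifest(trial, model$stats$metric_names)
  z <- apply_normalization(trial, model$stats)
  x <- feedback_input_matrix(z, model$input_metrics, level_value)
  pred_norm <- as.numeric(lstm_forward_cpp(x, model$weights))
  tm <- model$target_metric
  value <- pred_norm * model$stats$sd[[tm]] + model$stats$mean[[tm]]
  out <- structure(data.frame(time = trial$time, value = value),
                   class = c("feedback_series", "data.frame"),
                   target_metric = tm, expertise_level = level_value,
                   participant_id = attr(trial, "participant_id"),
                   trial_index = attr(trial, "trial_index"))
  if (capture_inputs) attr(out, "model_inputs") <- x
  out
}

#' Expert-level coaching trajectory for one metric
#'
#' Runs the inverse model with the expertise channel forced to the expert
#' code (1) at every timestep, regardless of the performer's own group, and
#' returns the predicted target-metric trajectory in original units.
#'
#' @param model a coaching-mode `feedback_model`.
#' @param trial an unnormalized `metric_series`.
#' @param capture_inputs if TRUE, attach the exact input matrix seen by the
#'   network as attribute `model_inputs` (instrumentation hook).
#' @return a `feedback_series` (`time`, `value`), `mode = "coaching"`.
#' @export
coach <- function(model, trial, capture_inputs = FALSE) {
  stopifnot(inherits(model, "feedback_model"))
  out <- feedback_predict(model, trial, 1, capture_inputs)
  attr(out, "mode") <- "coaching"
  out
}

#' Risk trajectory at the user's expertise level
#'
#' Runs the inverse model with the expertise channel set to the user's level
#' code at every timestep, predicting the bleeding or healthy-tissue-injury
#' trajectory expected of a performer at that level.
#'
#' @param model a risk-mode `feedback_model`.
#' @param trial an unnormalized `metric_series`.
#' @param level one of "expert", "senior", "junior", "novice"
#'   / "medical student" (or the corresponding code).
#' @param capture_inputs instrumentation hook, as in [coach()].
#' @return a `feedback_series`, `mode = "risk"`.
#' @export
assess_risk <- function(model, trial, level, capture_inputs = FALSE) {
  stopifnot(inherits(model, "feedback_model"))
  out <- feedback_predict(model, trial, expertise_level_code(level),
                          capture_inputs)
  attr(out, "mode") <- "risk"
  out
}

#' Warning intervals from a risk prediction
#'
#' Flags half-open intervals where the predicted trajectory at the user's
#' level exceeds the expert-level prediction on the same trial by a
#' configurable factor.
#'
#' @param user_series,expert_series `feedback_series` from [assess_risk()]
#'   at the user's level and at expert level, on the same trial.
#' @param factor warning multiplier; default 2.
#' @return data.frame `start_s`, `end_s`.
#' @export
risk_warnings <- function(user_series, expert_series, factor = 2) {
  stopifnot(nrow(user_series) == nrow(expert_series))
  exceed <- user_series$value > factor * expert_series$value
  step <- if (nrow(user_series) > 1)
    user_series$time[2] - user_series$time[1] else 0.2
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start_s = user_series$time[1] + (starts[keep] - 1) * step,
             end_s = user_series$time[1] + ends[keep] * step)
}
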