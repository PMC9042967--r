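# Expertise model: participant-grouped splitting, the two-layer LSTM
# sequence-to-sequence regressor, Adam training with step-decayed learning
# rate, and RMSE monitoring.

trial_pid <- function(trial) attr(trial, "participant_id")

#' Split trials into train/validation/test by participant
#'
#' Every trial of a participant stays in the same subset.  Participants are
#' shuffled under `seed` and assigned greedily: each participant goes to the
#' subset whose trial count is furthest below its target fraction (ties break
#' in the order train, validation, test).
#'
#' @param trials list of trials (any objects carrying a `participant_id`
#'   attribute).
#' @param fractions length-3 target trial fractions summing to 1.
#' @param seed integer shuffle seed.
#' @return a `split` object: `assignment` (participant -> subset) and
#'   `subsets` (list of trial indices for train/validation/test).
#' @export
split_by_participant <- function(trials, fractions = c(0.70, 0.15, 0.15),
                                 seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  pids <- vapply(trials, trial_pid, character(1))
  upid <- unique(pids)
  if (length(upid) < 3)
    stop("cannot split: need at least 3 participants")
  set.seed(as.integer(seed))
  upid <- sample(upid)
  subs <- c("train", "validation", "test")
  target <- fractions * length(trials)
  count <- c(0, 0, 0)
  assignment <- character(0)
  for (p in upid) {
    k <- which.max(target - count)   # ties -> first, i.e. subset order
    assignment[p] <- subs[k]
    count[k] <- count[k] + sum(pids == p)
  }
  subsets <- lapply(subs, function(s) which(assignment[pids] == s))
  names(subsets) <- subs
  structure(list(assignment = assignment, subsets = subsets,
                 fractions = fractions, seed = as.integer(seed)),
            class = "split")
}

#' Model specification (layer stack and node rule)
#'
#' Sequence input, two unidirectional LSTM layers each followed by dropout, a
#' one-unit fully connected layer, and a per-timestep mean-squared-error
#' regression output.  The LSTM width is always the number of input metrics
#' plus one.
#'
#' @param n_features number of input channels (>= 1).
#' @param dropout_rate dropout probability after each LSTM layer; default 0.2.
#' @return a `model_spec`.
#' @export
build_model <- function(n_features, dropout_rate = 0.2) {
  if (!is.numeric(n_features) || length(n_features) != 1 || n_features < 1)
    stop("invalid spec: n_features must be a positive integer")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("invalid spec: dropout_rate must be in [0, 1)")
  n_features <- as.integer(n_features)
  structure(list(
    n_features = n_features,
    lstm_units = n_features + 1L,
    dropout_rate = dropout_rate,
    layers = c("sequence_input", "lstm", "dropout", "lstm", "dropout",
               "fully_connected_1", "regression_mse")),
    class = "model_spec")
}

#' Minibatch size rule
#'
#' Number of training trials divided by the repeats performed per person,
#' floored, with a minimum of 1.  With 108 training trials and 6 repeats per
#' person this gives 18.
#'
#' @param n_training_trials,repeats_per_person positive integers.
#' @return integer minibatch size.
#' @export
minibatch_size <- function(n_training_trials, repeats_per_person) {
  if (n_training_trials <= 0 || repeats_per_person <= 0)
    stop("invalid argument: both inputs must be positive")
  max(1L, as.integer(floor(n_training_trials / repeats_per_person)))
}

#' Training schedule
#'
#' Adam optimization with a step-decayed learning rate:
#' `lr(epoch) = initial_lr * lr_decay_factor^floor((epoch - 1)/lr_decay_every)`
#' (1e-3 decreased tenfold every 25 epochs by default), minibatches
#' reshuffled every epoch, 1000 epochs by default.
#'
#' @param epochs number of passes over the training set.
#' @param initial_lr starting learning rate.
#' @param lr_decay_factor multiplicative decay.
#' @param lr_decay_every epochs between decays.
#' @param minibatch_size sequences per minibatch (see [minibatch_size()]);
#'   `NULL` lets the trainer derive it from the data.
#' @param clipnorm global gradient-norm clip; 0 (default) disables clipping.
#' @param seed RNG seed governing weight init, shuffling and dropout.
#' @return a `training_schedule`.
#' @export
training_schedule <- function(epochs = 1000L, initial_lr = 1e-3,
                              lr_decay_factor = 0.1, lr_decay_every = 25L,
                              minibatch_size = NULL, clipnorm = 0,
                              seed = 1L) {
  stopifnot(epochs >= 1, initial_lr > 0, lr_decay_factor > 0,
            lr_decay_every >= 1, is.null(minibatch_size) || minibatch_size >= 1)
  structure(list(optimizer = "adam", epochs = as.integer(epochs),
                 initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 minibatch_size = minibatch_size, shuffle = TRUE,
                 clipnorm = clipnorm, seed = as.integer(seed)),
            class = "training_schedule")
}

#' Learning rate at a given (1-based) epoch
#' @param schedule a [training_schedule()].
#' @param epoch epoch number, starting at 1.
#' @return the learning rate in effect during that epoch.
#' @export
learning_rate <- function(schedule, epoch) {
  schedule$initial_lr *
    schedule$lr_decay_factor^floor((epoch - 1) / schedule$lr_decay_every)
}

#' Root-mean-squared error pooled over all timesteps
#' @param predictions,targets equal-length numeric vectors.
#' @return `sqrt(mean((predictions - targets)^2))`.
#' @export
rmse <- function(predictions, targets) {
  if (length(predictions) == 0 || length(predictions) != length(targets))
    stop("invalid argument: inputs must be nonempty and of equal length")
  sqrt(mean((predictions - targets)^2))
}

#' Per-timestep label sequence for a trial
#'
#' Expert trials are labelled +1 and novice trials -1 at every 0.2 s step.
#'
#' @param trial a `metric_series`.
#' @param group optional group label; defaults to the trial's `group_label`.
#' @return numeric vector of +1/-1 with one entry per metric row.
#' @export
label_sequence <- function(trial, group = attr(trial, "group_label")) {
  lab <- switch(as.character(group), expert = 1, novice = -1,
                stop("label encoding defined only for expert/novice groups"))
  rep(lab, nrow(trial))
}

init_weights <- function(spec) {
  H <- spec$lstm_units
  F <- spec$n_features
  u <- function(nr, nc) matrix(runif(nr * nc, -1, 1) / sqrt(H), nr, nc)
  b1 <- matrix(0, 4 * H, 1); b1[(H + 1):(2 * H), 1] <- 1  # forget bias 1
  b2 <- b1
  list(W1 = u(4 * H, F), U1 = u(4 * H, H), b1 = b1,
       W2 = u(4 * H, H), U2 = u(4 * H, H), b2 = b2,
       Wd = u(1, H), bd = matrix(0, 1, 1))
}

#' Train a sequence-to-sequence regressor (generic core)
#'
#' Low-level trainer shared by the expertise model and the inverse feedback
#' models: per-timestep MSE over variable-length sequences, Adam with the
#' step-decay schedule, reshuffling every epoch, optional per-epoch
#' validation RMSE.
#'
#' @param inputs list of T x F numeric matrices (already normalized).
#' @param targets list of length-T numeric target vectors.
#' @param spec a [build_model()] spec with `n_features = ncol(inputs[[i]])`.
#' @param schedule a [training_schedule()].
#' @param val_inputs,val_targets optional held-out sequences monitored per
#'   epoch.
#' @return list with `weights`, and `history` (`train`, `validation` RMSE per
#'   epoch).
#' @export
train_sequence_model <- function(inputs, targets, spec, schedule,
                                 val_inputs = list(), val_targets = list()) {
  stopifnot(inherits(spec, "model_spec"), inherits(schedule, "training_schedule"),
            length(inputs) >= 1, length(inputs) == length(targets))
  for (i in seq_along(inputs))
    if (nrow(inputs[[i]]) != length(targets[[i]]))
      stop("target length must match sequence length (trial ", i, ")")
  mb <- schedule$minibatch_size
  if (is.null(mb)) mb <- length(inputs)
  set.seed(schedule$seed)
  w0 <- init_weights(spec)
  fit <- lstm_train_cpp(inputs, targets, w0, schedule$epochs,
                        schedule$initial_lr, schedule$lr_decay_factor,
                        schedule$lr_decay_every, as.integer(mb),
                        spec$dropout_rate, schedule$clipnorm,
                        val_inputs, val_targets)
  if (fit$diverged_epoch > 0)
    stop("training diverged (non-finite loss) at epoch ", fit$diverged_epoch)
  list(weights = fit$weights,
       history = list(train = as.numeric(fit$train_rmse),
                      validation = as.numeric(fit$val_rmse)))
}

#' Train the expertise assessment model
#'
#' End-to-end trainer for the continuous expertise score: fits z-score
#' normalization on the training subset, encodes constant +1/-1 label
#' sequences for expert/novice trials, trains the two-layer LSTM with the
#' minibatch rule (training trials divided by repeats per person), and
#' reports train/validation RMSE per epoch plus a final test RMSE.
#'
#' @param trials list of unnormalized `metric_series` from expert and novice
#'   performers.
#' @param split a [split_by_participant()] result over `trials`.
#' @param schedule a [training_schedule()].
#' @param dropout_rate dropout after each LSTM layer.
#' @param repeats_per_person repeats used by the minibatch rule; `NULL`
#'   infers the per-participant trial count from the training subset.
#' @return a `trained_model` carrying weights, spec, schedule, normalization
#'   stats, the metric manifest, the training seed and the RMSE history.
#' @export
train_expertise_model <- function(trials, split, schedule,
                                  dropout_rate = 0.2,
                                  repeats_per_person = NULL) {
  stopifnot(inherits(split, "split"))
  idx_tr <- split$subsets$train
  if (length(idx_tr) < 1) stop("empty training subset")
  stats <- fit_normalization(trials[idx_tr])
  prep <- function(idx) {
    xs <- lapply(trials[idx], function(tr)
      metric_matrix(apply_normalization(tr, stats)))
    ys <- lapply(trials[idx], label_sequence)
    list(xs = xs, ys = ys)
  }
  tr <- prep(idx_tr)
  va <- prep(split$subsets$validation)
  if (is.null(repeats_per_person)) {
    pids <- vapply(trials[idx_tr], trial_pid, character(1))
    repeats_per_person <- max(table(pids))
  }
  if (is.null(schedule$minibatch_size))
    schedule$minibatch_size <- minibatch_size(length(idx_tr),
                                              repeats_per_person)
  spec <- build_model(length(stats$metric_names), dropout_rate)
  fit <- train_sequence_model(tr$xs, tr$ys, spec, schedule, va$xs, va$ys)
  test_rmse <- NA_real_
  if (length(split$subsets$test) > 0) {
    te <- prep(split$subsets$test)
    preds <- unlist(lapply(te$xs, lstm_forward_cpp, weights = fit$weights))
    test_rmse <- rmse(preds, unlist(te$ys))
  }
  structure(list(weights = fit$weights, spec = spec, schedule = schedule,
                 stats = stats, manifest = metric_manifest(),
                 seed = schedule$seed,
                 history = c(fit$history, list(test = test_rmse))),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  ep <- length(x$history$train)
  cat("Expertise model: 2-layer LSTM (", x$spec$lstm_units, " units, ",
      x$spec$n_features, " features), ", ep, " epochs\n", sep = "")
  cat(sprintf("final RMSE  train %.4f  validation %.4f  test %.4f\n",
              x$history$train[ep], x$history$validation[ep],
              x$history$test))
  invisible(x)
}
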