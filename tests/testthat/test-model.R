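# Participant-grouped splitting, model spec, schedule, RMSE, LSTM training.

test_that("every participant's trials land in exactly one subset", {
  trials <- fix_cohort()
  sp <- fix_split()
  pids <- sapply(trials, function(t) attr(t, "participant_id"))
  for (s in names(sp$subsets)) {
    for (other in setdiff(names(sp$subsets), s)) {
      expect_length(intersect(pids[sp$subsets[[s]]],
                              pids[sp$subsets[[other]]]), 0)
    }
  }
  expect_setequal(unlist(sp$subsets), seq_along(trials))
  # deterministic under a fixed seed
  expect_identical(sp, split_by_participant(trials, seed = 3L))
})

test_that("greedy split lands within one participant-block of the 70/15/15 targets", {
  cfg <- trial_config(duration_s = 5, duration_range_s = c(4, 6))
  des <- cohort_design(data.frame(label = "expert", n_participants = 10L,
                                  skill_mean = 0.5, skill_sd = 0.2), 6L)
  streams <- simulate_cohort(des, cfg, seed = 1)
  sp <- split_by_participant(streams, seed = 42)
  counts <- lengths(sp$subsets)
  expect_equal(sum(counts), 60)
  expect_lte(abs(counts[["train"]] - 42), 6)
  expect_lte(abs(counts[["validation"]] - 9), 6)
  expect_lte(abs(counts[["test"]] - 9), 6)
})

test_that("fewer than 3 participants cannot be split", {
  trials <- fix_cohort()
  pids <- sapply(trials, function(t) attr(t, "participant_id"))
  two <- trials[pids %in% unique(pids)[1:2]]
  expect_error(split_by_participant(two, seed = 1), "cannot split")
})

test_that("LSTM node rule adds one to the feature count", {
  expect_equal(build_model(16)$lstm_units, 17)
  expect_equal(build_model(1)$lstm_units, 2)
  expect_error(build_model(0), "invalid spec")
  spec <- build_model(16)
  expect_equal(sum(spec$layers == "lstm"), 2)
  expect_equal(sum(spec$layers == "dropout"), 2)
})

test_that("minibatch rule floors the trials-per-repeats quotient with minimum 1", {
  expect_equal(minibatch_size(108, 6), 18)
  expect_equal(minibatch_size(6, 6), 1)
  expect_equal(minibatch_size(7, 6), 1)
  expect_error(minibatch_size(0, 6), "invalid argument")
  expect_error(minibatch_size(10, -1), "invalid argument")
})

test_that("learning rate decays tenfold every 25 epochs from 1e-3", {
  sched <- training_schedule()
  expect_equal(sapply(c(1, 25, 26, 51), learning_rate, schedule = sched),
               c(1e-3, 1e-3, 1e-4, 1e-5))
})

test_that("rmse matches a loop oracle and rejects bad input", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(rep(0, 5), rep(1, 5)), 1)
  set.seed(8)
  p <- rnorm(100); y <- rnorm(100)
  acc <- 0
  for (i in 1:100) acc <- acc + (p[i] - y[i])^2
  expect_equal(rmse(p, y), sqrt(acc / 100), tolerance = 1e-12)
  expect_error(rmse(numeric(0), numeric(0)), "invalid argument")
  expect_error(rmse(1:3, 1:4), "invalid argument")
})

test_that("label sequences are constant +/-1 with one entry per metric row", {
  trials <- fix_cohort()
  for (tr in trials) {
    lab <- label_sequence(tr)
    expect_length(lab, nrow(tr))
    expect_length(unique(lab), 1)
    expect_true(unique(lab) %in% c(-1, 1))
    expect_equal(unique(lab),
                 if (attr(tr, "group_label") == "expert") 1 else -1)
  }
})

test_that("training beats the constant-zero predictor and logs full RMSE history", {
  model <- fix_model()
  ep <- length(model$history$train)
  expect_equal(ep, model$schedule$epochs)
  # constant-zero predictor has RMSE exactly 1.0 on +/-1 labels
  expect_lt(model$history$train[ep], 1.0)
  expect_lt(model$history$test, 1.0)
  expect_equal(length(model$history$validation), ep)
})

test_that("single-sequence training for one epoch gives a one-entry history", {
  x <- list(matrix(rnorm(50 * 3), 50, 3))
  y <- list(rep(1, 50))
  fit <- train_sequence_model(x, y, build_model(3),
                              training_schedule(epochs = 1, seed = 2))
  expect_length(fit$history$train, 1)
})

test_that("training is reproducible under a fixed seed", {
  x <- lapply(1:4, function(i) matrix(rnorm(30 * 2), 30, 2))
  y <- lapply(1:4, function(i) rep(c(-1, 1)[i %% 2 + 1], 30))
  sched <- training_schedule(epochs = 5, minibatch_size = 2, seed = 21)
  f1 <- train_sequence_model(x, y, build_model(2), sched)
  f2 <- train_sequence_model(x, y, build_model(2), sched)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("held-out experts outscore held-out novices across seeds (capacity sanity)", {
  cfg <- fix_config()
  ok <- sapply(1:5, function(seed) {
    des <- cohort_design(data.frame(label = c("expert", "novice"),
                                    n_participants = c(4L, 4L),
                                    skill_mean = c(0.8, -0.8),
                                    skill_sd = c(0.1, 0.1)), 2L)
    trials <- lapply(simulate_cohort(des, cfg, seed = seed),
                     function(s) extract_metrics(regularize(s)))
    sp <- split_by_participant(trials, seed = seed)
    mod <- train_expertise_model(trials, sp,
                                 training_schedule(epochs = 15, seed = seed))
    held <- c(sp$subsets$validation, sp$subsets$test)
    avg <- sapply(trials[held], function(t) task_average(score_trial(mod, t)))
    grp <- sapply(trials[held], function(t) attr(t, "group_label"))
    if (all(c("expert", "novice") %in% grp))
      mean(avg[grp == "expert"]) > mean(avg[grp == "novice"])
    else NA
  })
  expect_true(all(ok, na.rm = TRUE))
})

test_that("mismatched target lengths are rejected", {
  x <- list(matrix(0, 10, 2))
  y <- list(rep(1, 9))
  expect_error(train_sequence_model(x, y, build_model(2),
                                    training_schedule(epochs = 1)),
               "length")
})
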