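# Inverse models: coaching targets and risk prediction.

test_that("the five-model roster is fixed: three coaching, two risk", {
  r <- feedback_roster()
  expect_equal(r$target_metric[r$mode == "coaching"],
               c("force_aspirator", "force_bipolar", "tip_separation"))
  expect_equal(r$model[r$mode == "risk"], c("bleeding", "tissue_injury"))
  expect_true(all(r$target_metric %in% metric_manifest()$name))
})

test_that("expertise level codes map exactly and the vocabulary is closed", {
  expect_equal(expertise_level_code("expert"), 1)
  expect_equal(expertise_level_code("senior"), 0.33)
  expect_equal(expertise_level_code("junior"), -0.33)
  expect_equal(expertise_level_code("novice"), -1)
  expect_equal(expertise_level_code("medical student"), -1)
  expect_error(expertise_level_code("attending"), "invalid expertise level")
  expect_error(expertise_level_code(0.5), "invalid expertise level")
})

test_that("coaching models take 15 metrics + expertise, giving 17 hidden units", {
  for (target in c("force_aspirator", "force_bipolar", "tip_separation")) {
    inputs <- feedback_input_metrics(target)
    expect_length(inputs, 15)
    expect_false(target %in% inputs)
    expect_equal(build_model(length(inputs) + 1)$lstm_units, 17)
  }
  expect_error(feedback_input_metrics("not_a_metric"), "manifest error")
})

test_that("risk models exclude the target and its same-channel sibling", {
  m <- fix_risk_model()
  expect_false(m$target_metric %in% m$input_metrics)
  expect_false("blood_volume" %in% m$input_metrics)  # leakage guard
  expect_length(m$input_metrics, 14)
  expect_equal(m$spec$lstm_units, length(m$input_metrics) + 2)
  expect_error(train_feedback_model("not_a_metric", fix_cohort(),
                                    fix_split(), training_schedule(epochs = 1)),
               "manifest error")
})

test_that("coaching forces the expertise channel to 1 regardless of performer", {
  m <- fix_risk_model()
  trials <- fix_cohort()
  grp <- sapply(trials, function(t) attr(t, "group_label"))
  nov <- trials[[which(grp == "novice")[1]]]
  fb <- coach(m, nov, capture_inputs = TRUE)
  x <- attr(fb, "model_inputs")
  expect_true(all(x[, "expertise"] == 1))
  expect_equal(nrow(fb), nrow(nov))
  expect_equal(attr(fb, "mode"), "coaching")
})

test_that("coach() output is bit-identical across performer groups on identical metrics", {
  m <- fix_risk_model()
  tr <- fix_cohort()[[1]]
  as_expert <- tr; attr(as_expert, "group_label") <- "expert"
  as_novice <- tr; attr(as_novice, "group_label") <- "novice"
  attr(as_novice, "participant_id") <- "other"
  f1 <- coach(m, as_expert)
  f2 <- coach(m, as_novice)
  expect_identical(f1$value, f2$value)
})

test_that("assess_risk uses the user's level code and rejects unknown levels", {
  m <- fix_risk_model()
  tr <- fix_cohort()[[2]]
  fb <- assess_risk(m, tr, "senior", capture_inputs = TRUE)
  expect_true(all(attr(fb, "model_inputs")[, "expertise"] == 0.33))
  expect_equal(attr(fb, "mode"), "risk")
  fb2 <- assess_risk(m, tr, "medical student", capture_inputs = TRUE)
  expect_true(all(attr(fb2, "model_inputs")[, "expertise"] == -1))
  expect_error(assess_risk(m, tr, "attending"), "invalid expertise level")
})

test_that("predicted bleeding is at least as high at novice level as at expert level", {
  m <- fix_risk_model()
  trials <- fix_cohort()[seq(1, 16, by = 3)]
  gaps <- sapply(trials, function(tr) {
    mean(assess_risk(m, tr, "novice")$value) -
      mean(assess_risk(m, tr, "expert")$value)
  })
  expect_gte(mean(gaps), 0)
})

test_that("an expertise-driven target is learned better than the constant-mean baseline", {
  # fixture: target metric is an affine function of the expertise channel
  # alone; every other metric is noise.
  set.seed(5)
  mk <- function(pid, group) {
    tr <- extract_metrics(regularize(random_stream(
      seed = match(pid, paste0("p", 1:8)), duration_s = 4)))
    lev <- if (group == "expert") 1 else -1
    tr$force_aspirator <- 2 + 0.8 * lev + rnorm(nrow(tr), sd = 0.01)
    attr(tr, "participant_id") <- pid
    attr(tr, "group_label") <- group
    tr
  }
  trials <- c(lapply(paste0("p", 1:4), mk, group = "expert"),
              lapply(paste0("p", 5:8), mk, group = "novice"))
  sp <- split_by_participant(trials, seed = 9)
  fm <- train_feedback_model("force_aspirator", trials, sp,
                             training_schedule(epochs = 40, seed = 2))
  held <- c(sp$subsets$validation, sp$subsets$test)
  stats <- fm$stats
  err_model <- err_base <- c()
  for (tr in trials[held]) {
    lev <- if (attr(tr, "group_label") == "expert") "expert" else "novice"
    pred <- assess_risk(fm, tr, lev)$value
    err_model <- c(err_model, pred - tr$force_aspirator)
    err_base <- c(err_base, stats$mean[["force_aspirator"]] -
                    tr$force_aspirator)
  }
  expect_lt(sqrt(mean(err_model^2)), sqrt(mean(err_base^2)))
})

test_that("risk warnings flag intervals where the user prediction exceeds expert x factor", {
  t <- (0:9) * 0.2
  mk_fb <- function(v) structure(data.frame(time = t, value = v),
                                 class = c("feedback_series", "data.frame"))
  user <- mk_fb(c(1, 1, 5, 5, 1, 1, 1, 5, 1, 1))
  expert <- mk_fb(rep(1, 10))
  w <- risk_warnings(user, expert, factor = 2)
  expect_equal(w$start_s, c(0.4, 1.4))
  expect_equal(w$end_s, c(0.8, 1.6))
})
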