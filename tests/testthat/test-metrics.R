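# Regularization and 16-metric extraction.

test_that("a stream already on the exact grid is returned unchanged", {
  tr <- simulate_trial(trial_config(duration_s = 5), 0, seed = 1)
  expect_identical(regularize(tr), tr)
})

test_that("off-grid samples interpolate linearly; activation is carried forward", {
  raw <- make_stream(time = c(0, 0.04),
                     pos_dom = rbind(c(0, 0, 0), c(2, 0, 0)),
                     active_dom = c(TRUE, FALSE))
  reg <- regularize(raw)
  expect_equal(reg$time, c(0, 0.02, 0.04))
  expect_equal(reg$pos_dom_x, c(0, 1, 2))     # midpoint of 0 and 2 mm
  expect_equal(reg$active_dom, c(TRUE, TRUE, FALSE))
})

test_that("duplicate or non-monotone timestamps raise a malformed-stream error", {
  bad <- make_stream(time = c(0, 0, 0.02))
  expect_error(regularize(bad), "malformed stream")
  bad2 <- make_stream(time = c(0, 0.04, 0.02))
  expect_error(regularize(bad2), "malformed stream")
})

test_that("regularization preserves monotone channels", {
  set.seed(4)
  t_irr <- sort(runif(200, 0, 4))
  raw <- make_stream(time = t_irr, tumor = sort(runif(200)),
                     damage = cumsum(abs(rnorm(200))))
  reg <- regularize(raw)
  expect_true(all(diff(reg$tumor_removed) >= 0))
  expect_true(all(diff(reg$healthy_damage) >= 0))
})

test_that("a 120 s trial yields 600 metric rows (5 decisions per second)", {
  tr <- simulate_trial(trial_config(duration_s = 120), 0, seed = 1)
  m <- extract_metrics(tr)
  expect_equal(nrow(m), 600)
  expect_equal(ncol(m) - 1, 16)
  expect_equal(diff(m$time)[1], 0.2)
})

test_that("window accounting: rows = floor(duration/0.2), trailing partial dropped", {
  for (dur in c(2, 2.1, 2.38, 10.02)) {
    tr <- simulate_trial(trial_config(duration_s = dur), 0, seed = 2)
    expect_equal(nrow(extract_metrics(tr)),
                 floor(round(dur / 0.02) * 0.02 / 0.2 + 1e-9))
  }
  short <- make_stream(time = c(0, 0.02, 0.04))
  expect_error(extract_metrics(short), "too-short")
})

test_that("stationary tips give zero velocity and acceleration; 3-4-5 separation", {
  t <- (0:19) * 0.02
  raw <- make_stream(t, pos_dom = matrix(0, 20, 3),
                     pos_nd = matrix(rep(c(3, 4, 0), each = 20), 20, 3))
  m <- extract_metrics(raw)
  expect_equal(m$velocity_aspirator, rep(0, 2))
  expect_equal(m$accel_bipolar, rep(0, 2))
  expect_equal(m$tip_separation, rep(5, 2))
})

test_that("extraction matches the sample-by-sample brute-force oracle", {
  for (s in 1:20) {
    raw <- random_stream(seed = s, duration_s = 2)
    got <- extract_metrics(raw)
    want <- oracle_metrics(raw)
    expect_equal(as.matrix(got[, colnames(want)]), want,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("unit coherence: doubling positions doubles kinematic metrics only", {
  raw <- random_stream(seed = 31)
  raw2 <- raw
  for (ch in grep("^pos_", names(raw), value = TRUE))
    raw2[[ch]] <- 2 * raw[[ch]]
  m1 <- extract_metrics(raw); m2 <- extract_metrics(raw2)
  kinematic <- c("tip_separation", "velocity_aspirator", "velocity_bipolar",
                 "accel_aspirator", "accel_bipolar", "path_length_aspirator",
                 "path_length_bipolar", "relative_velocity")
  for (ch in kinematic) expect_equal(m2[[ch]], 2 * m1[[ch]])
  for (ch in c("force_aspirator", "force_bipolar", "blood_volume",
               "tumor_removed", "active_fraction_aspirator"))
    expect_equal(m2[[ch]], m1[[ch]])
})

test_that("z-score statistics use the population convention and round-trip", {
  trials <- fix_cohort()[1:4]
  stats <- fit_normalization(trials)
  pooled <- do.call(rbind, lapply(trials, function(tr)
    as.matrix(apply_normalization(tr, stats)[, stats$metric_names])))
  expect_equal(unname(colMeans(pooled)), rep(0, 16), tolerance = 1e-8)
  expect_equal(unname(sqrt(colMeans(pooled^2))), rep(1, 16),
               tolerance = 1e-8)
  # two-point case: values {1, 3} -> mean 2, population sd 1
  x <- c(1, 3)
  expect_equal(mean(x), 2)
  expect_equal(sqrt(mean((x - mean(x))^2)), 1)
  # round trip
  tr <- trials[[1]]
  back <- invert_normalization(apply_normalization(tr, stats), stats)
  expect_equal(as.matrix(back[, stats$metric_names]),
               as.matrix(tr[, stats$metric_names]), tolerance = 1e-10)
})

test_that("degenerate (constant) features are rejected by name", {
  t <- (0:199) * 0.02
  quiet <- make_stream(t, force_dom = 1)   # constant everything
  m <- extract_metrics(quiet)
  expect_error(fit_normalization(list(m, m)), "degenerate feature")
  expect_error(fit_normalization(list(m, m)), "force_aspirator")
  expect_error(fit_normalization(list(m)), "at least 2")
})

test_that("normalization refuses a mismatched manifest", {
  stats <- fit_normalization(fix_cohort()[1:4])
  tr <- fix_cohort()[[5]]
  man <- attr(tr, "manifest")
  attr(tr, "manifest")$name <- rev(man$name)
  expect_error(apply_normalization(tr, stats), "feature-order")
})
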