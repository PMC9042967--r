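# Metric extraction: regularize raw 50 Hz streams onto an exact 0.02 s grid,
# then reduce each half-open 0.2 s window to the 16 performance metrics.

#' The 16-metric manifest
#'
#' Ordered metric table used everywhere downstream; the order is fixed and
#' must match between extraction, normalization and model weights.  Ten
#' metrics follow directly from the recorded channels (tip separation, per
#' instrument force / velocity / acceleration, tumor removed, blood volume,
#' healthy-tissue damage); six more are reconstructed from the five standard
#' performance categories and flagged `reconstructed` (per-window path length
#' and pedal-active fraction per instrument, bleeding rate, inter-tip
#' relative velocity).
#'
#' Reduction rules over a window: `mean` of per-sample values; `delta` =
#' end-of-window minus end-of-previous-window for cumulative channels;
#' `posrate` = summed positive increments per second; `pathlen` = summed step
#' lengths; `fraction` = mean of a 0/1 channel.
#'
#' @return data.frame with columns `name`, `unit`, `category`, `reduction`,
#'   `reconstructed`, `direction` (sign of the skill dependence under the
#'   bundled generator).
#' @export
metric_manifest <- function() {
  m <- data.frame(
    name = c("tip_separation", "force_aspirator", "force_bipolar",
             "velocity_aspirator", "velocity_bipolar",
             "accel_aspirator", "accel_bipolar",
             "tumor_removed", "blood_volume", "healthy_damage",
             "path_length_aspirator", "path_length_bipolar",
             "active_fraction_aspirator", "active_fraction_bipolar",
             "bleeding_rate", "relative_velocity"),
    unit = c("mm", "N", "N", "mm/s", "mm/s", "mm/s2", "mm/s2",
             "fraction", "mL", "mL", "mm", "mm", "fraction", "fraction",
             "mL/s", "mm/s"),
    category = c("bimanual_cognitive", "safety", "safety",
                 "movement", "movement", "movement", "movement",
                 "quality", "safety", "safety",
                 "movement", "movement", "efficiency", "efficiency",
                 "safety", "bimanual_cognitive"),
    reduction = c("mean", "mean", "mean", "mean", "mean", "mean", "mean",
                  "delta", "mean", "delta", "pathlen", "pathlen",
                  "fraction", "fraction", "posrate", "mean"),
    reconstructed = c(rep(FALSE, 10), rep(TRUE, 6)),
    stringsAsFactors = FALSE)
  m$direction <- unname(skill_directions()[m$name])
  m
}

stream_time_ok <- function(time) {
  length(time) >= 2 && all(diff(time) > 0)
}

#' Regularize a raw stream onto an exact 0.02 s grid
#'
#' Interpolation step applied before metric extraction: continuous channels
#' are linearly interpolated, activation channels carry the most recent
#' earlier sample.  A stream already on the exact grid is returned unchanged.
#'
#' @param raw a `raw_stream`.
#' @param dt target grid step in seconds (default 0.02).
#' @return a `raw_stream` on the exact grid.
#' @export
regularize <- function(raw, dt = 0.02) {
  stopifnot(is.data.frame(raw), "time" %in% names(raw))
  t <- raw$time
  if (!stream_time_ok(t))
    stop("malformed stream: timestamps must be strictly increasing (>= 2 samples)")
  n_out <- floor((t[length(t)] - t[1]) / dt + 1e-9) + 1
  grid <- t[1] + (seq_len(n_out) - 1) * dt
  if (length(t) == n_out && max(abs(t - grid)) < 1e-9) return(raw)
  stepwise <- c("active_dom", "active_nd")
  out <- data.frame(time = grid)
  for (ch in setdiff(names(raw), "time")) {
    if (ch %in% stepwise) {
      out[[ch]] <- approx(t, as.numeric(raw[[ch]]), xout = grid,
                          method = "constant", f = 0, rule = 2)$y > 0.5
    } else {
      out[[ch]] <- approx(t, raw[[ch]], xout = grid, rule = 2)$y
    }
  }
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       attributes(raw)[setdiff(names(attributes(raw)),
                                               c("names", "row.names"))])
  out
}

#' Extract the 16 performance metrics on a 0.2 s grid
#'
#' Reduces each half-open window `[t, t + 0.2)` of a regularized stream to
#' one metric row.  Velocity is the per-sample first difference of tip
#' position divided by the raw step (first sample 0), acceleration the first
#' difference of the velocity vector, both window-averaged as magnitudes;
#' tip separation is the Euclidean inter-tip distance; cumulative channels
#' (tumor, damage) enter as per-window deltas so features stay roughly
#' stationary in trial time.  A trailing partial window is dropped.
#'
#' @param raw a regularized `raw_stream`.
#' @param window_s metric window in seconds (default 0.2).
#' @return a `metric_series` data.frame (`time` + 16 metric columns) carrying
#'   the manifest and trial metadata as attributes.
#' @export
extract_metrics <- function(raw, window_s = 0.2) {
  stopifnot(is.data.frame(raw))
  t <- raw$time
  if (!stream_time_ok(t)) stop("malformed stream: bad timestamps")
  dt <- t[2] - t[1]
  if (max(abs(diff(t) - dt)) > 1e-9)
    stop("malformed stream: regularize() the stream first")
  spw <- round(window_s / dt)
  if (abs(spw * dt - window_s) > 1e-9)
    stop("window_s must be a multiple of the raw step")
  n <- nrow(raw)
  n_win <- floor(n * dt / window_s + 1e-9)
  if (n_win < 1) stop("too-short trial: shorter than one metric window")

  pd <- as.matrix(raw[, c("pos_dom_x", "pos_dom_y", "pos_dom_z")])
  pn <- as.matrix(raw[, c("pos_nd_x", "pos_nd_y", "pos_nd_z")])
  vstep <- function(p) rbind(0, diff(p) / dt)          # velocity vectors
  vd <- vstep(pd); vn <- vstep(pn)
  ad <- vstep(vd); an <- vstep(vn)                     # acceleration vectors
  norms <- function(m) sqrt(rowSums(m^2))
  per_sample <- list(
    tip_separation = norms(pd - pn),
    force_aspirator = raw$force_dom,
    force_bipolar = raw$force_nd,
    velocity_aspirator = norms(vd),
    velocity_bipolar = norms(vn),
    accel_aspirator = norms(ad),
    accel_bipolar = norms(an),
    blood_volume = raw$blood_present,
    active_fraction_aspirator = as.numeric(raw$active_dom),
    active_fraction_bipolar = as.numeric(raw$active_nd),
    relative_velocity = norms(vd - vn))
  steplen <- list(path_length_aspirator = c(0, norms(diff(pd))),
                  path_length_bipolar = c(0, norms(diff(pn))))

  used <- seq_len(n_win * spw)
  bywin <- function(x, f) f(matrix(x[used], nrow = spw))
  man <- metric_manifest()
  out <- data.frame(time = t[1] + (seq_len(n_win) - 1) * window_s)
  ends <- used[seq(spw, length(used), by = spw)]       # last sample per window
  for (j in seq_len(nrow(man))) {
    nm <- man$name[j]
    out[[nm]] <- switch(man$reduction[j],
      mean = ,
      fraction = bywin(per_sample[[nm]], colMeans),
      pathlen = bywin(steplen[[nm]], colSums),
      delta = {
        ch <- switch(nm, tumor_removed = raw$tumor_removed,
                     healthy_damage = raw$healthy_damage)
        diff(c(ch[1], ch[ends]))
      },
      posrate = bywin(pmax(0, c(0, diff(raw$blood_present))),
                      colSums) / window_s)
  }
  structure(out, class = c("metric_series", "data.frame"),
            manifest = man, window_s = window_s, raw_dt = dt,
            normalized = FALSE,
            participant_id = attr(raw, "participant_id"),
            trial_index = attr(raw, "trial_index"),
            group_label = attr(raw, "group_label"),
            skill = attr(raw, "skill"))
}

metric_matrix <- function(trial) {
  as.matrix(trial[, metric_manifest()$name, drop = FALSE])
}

#' Fit z-score normalization statistics on training trials
#'
#' Per-metric mean and standard deviation pooled over every timestep of every
#' training trial.  The standard deviation uses the population convention
#' (divide by n) so that re-applying the statistics to the pooled training
#' rows gives exactly mean 0, sd 1.  Validation, test and trainee trials must
#' always be normalized with these training-set statistics.
#'
#' @param training_trials list of `metric_series` (>= 2 trials).
#' @return a `normalization_stats` list with named `mean` and `sd` vectors.
#' @export
fit_normalization <- function(training_trials) {
  if (length(training_trials) < 2) stop("need at least 2 training trials")
  pooled <- do.call(rbind, lapply(training_trials, metric_matrix))
  if (nrow(pooled) < 2) stop("need at least 2 pooled rows")
  mu <- colMeans(pooled)
  sdv <- sqrt(colMeans(sweep(pooled, 2, mu)^2))   # population sd
  if (any(sdv <= 1e-12))
    stop("degenerate feature (constant over the training pool): ",
         paste(names(sdv)[sdv <= 1e-12], collapse = ", "))
  structure(list(mean = mu, sd = sdv, metric_names = names(mu)),
            class = "normalization_stats")
}

check_manifest <- function(trial, names_expected) {
  got <- attr(trial, "manifest")$name
  if (!identical(got, names_expected))
    stop("feature-order error: trial manifest does not match expected order")
}

#' Apply (or invert) z-score normalization
#'
#' @param trial a `metric_series`.
#' @param stats a `normalization_stats` fitted on the training subset.
#' @return the trial with each metric transformed to `(x - mean)/sd`
#'   (`apply_normalization`) or back to original units
#'   (`invert_normalization`).
#' @export
apply_normalization <- function(trial, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  check_manifest(trial, stats$metric_names)
  for (nm in stats$metric_names)
    trial[[nm]] <- (trial[[nm]] - stats$mean[[nm]]) / stats$sd[[nm]]
  attr(trial, "normalized") <- TRUE
  trial
}

#' @rdname apply_normalization
#' @export
invert_normalization <- function(trial, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  check_manifest(trial, stats$metric_names)
  for (nm in stats$metric_names)
    trial[[nm]] <- trial[[nm]] * stats$sd[[nm]] + stats$mean[[nm]]
  attr(trial, "normalized") <- FALSE
  trial
}
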