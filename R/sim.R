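# Synthetic bimanual-trial generator.
#
# Stand-in for a virtual-reality neurosurgical simulator: each trial records,
# at 50 Hz, the 3D tip position (mm), applied force (N) and pedal activation
# of two instruments -- an ultrasonic aspirator in the dominant hand and a
# bipolar forceps in the non-dominant hand -- plus tissue state (fraction of
# tumor removed, blood volume present, cumulative healthy-tissue damage).
# A scalar skill parameter in [-1, 1] controls every skill-sensitive knob
# through affine maps (see skill_directions() for the resulting direction of
# each downstream metric).

#' Trial configuration for the synthetic simulator
#'
#' @param duration_s trial length in seconds (used by [simulate_trial()]).
#' @param raw_dt raw sampling interval in seconds; default 0.02 (50 Hz).
#' @param workspace_extent_mm approximate workspace half-width in mm.
#' @param noise_scale global multiplier on motion/force innovation scales.
#' @param event_rates named per-second base rates for `bleeding` and `damage`
#'   events and the `tumor` removal rate constant.
#' @param duration_range_s range (seconds) from which cohort trial durations
#'   are drawn uniformly, forcing variable-length sequences downstream.
#' @return a `trial_config` list.
#' @export
trial_config <- function(duration_s = 120, raw_dt = 0.02,
                         workspace_extent_mm = 50, noise_scale = 1,
                         event_rates = c(bleeding = 0.25, damage = 0.12,
                                         tumor = 0.012),
                         duration_range_s = c(90, 180)) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0)
    stop("invalid config: duration_s must be a positive number")
  if (!is.numeric(raw_dt) || length(raw_dt) != 1 || raw_dt <= 0)
    stop("invalid config: raw_dt must be a positive number")
  if (round(duration_s / raw_dt) < 2)
    stop("invalid config: duration_s/raw_dt must yield at least 2 samples")
  if (workspace_extent_mm <= 0 || noise_scale <= 0)
    stop("invalid config: extent and noise_scale must be positive")
  need <- c("bleeding", "damage", "tumor")
  if (!all(need %in% names(event_rates)) || any(event_rates[need] < 0))
    stop("invalid config: event_rates needs nonnegative bleeding/damage/tumor")
  structure(list(duration_s = duration_s, raw_dt = raw_dt,
                 workspace_extent_mm = workspace_extent_mm,
                 noise_scale = noise_scale,
                 event_rates = event_rates[need],
                 duration_range_s = sort(duration_range_s)),
            class = "trial_config")
}

# Affine skill-to-parameter maps.  `skill` in [-1, 1]; every map is monotone
# so the direction of each metric's skill dependence is fixed by design.
skill_params <- function(skill, config) {
  ns <- config$noise_scale
  er <- config$event_rates
  list(
    sigma_pos   = ns * (4.0 - 1.6 * skill),    # mm/sqrt(s): motion dispersion
    sep_offset  = 8.0 - 3.0 * skill,           # mm: mean inter-tip distance
    force_mean  = c(dom = 1.2 - 0.5 * skill, nd = 0.9 - 0.35 * skill),  # N
    force_sd    = ns * (0.35 - 0.12 * skill),  # N
    active_frac = c(dom = 0.55 + 0.20 * skill, nd = 0.35 + 0.15 * skill),
    bleed_rate  = er[["bleeding"]] * (1 - 0.6 * skill),  # events/s
    damage_rate = er[["damage"]] * (1 - 0.6 * skill),    # events/s
    tumor_rate  = er[["tumor"]] * (1 + 0.7 * skill)      # 1/s removal const
  )
}

#' Documented direction of each metric's dependence on skill
#'
#' Part of the generator's manifest: for every downstream performance metric,
#' `+1` means its population mean increases with skill, `-1` decreases.
#' Higher skill gives smoother, slower motion, lower and steadier forces,
#' closer bimanual coordination, more pedal engagement, less bleeding and
#' tissue damage, and faster tumor removal.
#'
#' @return named numeric vector over the 16 metric names.
#' @export
skill_directions <- function() {
  c(tip_separation = -1,
    force_aspirator = -1, force_bipolar = -1,
    velocity_aspirator = -1, velocity_bipolar = -1,
    accel_aspirator = -1, accel_bipolar = -1,
    tumor_removed = +1, blood_volume = -1, healthy_damage = -1,
    path_length_aspirator = -1, path_length_bipolar = -1,
    active_fraction_aspirator = +1, active_fraction_bipolar = +1,
    bleeding_rate = -1, relative_velocity = -1)
}

# Mean-reverting (AR(1)/discrete Ornstein-Uhlenbeck) path via stats::filter.
ou_path <- function(n, dt, theta, sigma, target, x0) {
  a <- 1 - theta * dt
  innov <- theta * dt * target + sigma * sqrt(dt) * rnorm(n)
  as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
}

# Alternating-renewal on/off pedal process with exponential dwell times.
activation_path <- function(n, dt, frac, rate_total = 1.0) {
  frac <- min(max(frac, 0.02), 0.98)
  q_on <- rate_total * frac        # entering ON at rate prop. to target frac
  q_off <- rate_total * (1 - frac) # leaving ON
  state <- runif(1) < frac
  out <- logical(0)
  while (length(out) < n) {
    rate <- if (state) q_off else q_on
    dwell <- max(1L, round(rexp(1, rate) / dt))
    out <- c(out, rep(state, dwell))
    state <- !state
  }
  out[seq_len(n)]
}

#' Simulate one raw bimanual trial
#'
#' Generates a 50 Hz multichannel record of a single simulated tumor-resection
#' attempt.  Tip trajectories are mean-reverting smoothed random walks whose
#' innovation scale shrinks with skill; forces are nonnegative mean-reverting
#' processes with skill-dependent mean and spread; bleeding and healthy-tissue
#' damage are Poisson event processes with intensity decreasing in skill;
#' tumor removal accrues while the aspirator is active, with efficiency
#' increasing in skill.  Identical `(config, skill, seed)` give bit-identical
#' streams.
#'
#' @param config a [trial_config()].
#' @param skill ground-truth expertise in \[-1, 1\].
#' @param seed integer RNG seed for this trial.
#' @param participant_id,trial_index,group_label metadata carried on the
#'   returned stream.
#' @return a `raw_stream` data.frame: `time`, per-instrument `*_x/_y/_z` tip
#'   position (mm), `force_*` (N), `active_*`, and tissue channels
#'   `tumor_removed` (fraction, nondecreasing), `blood_present` (mL),
#'   `healthy_damage` (mL, nondecreasing).
#' @export
simulate_trial <- function(config, skill, seed, participant_id = "P01",
                           trial_index = 1L, group_label = NA_character_) {
  stopifnot(inherits(config, "trial_config"))
  if (!is.numeric(skill) || length(skill) != 1 || skill < -1 || skill > 1)
    stop("skill must be a single number in [-1, 1]")
  set.seed(as.integer(seed))
  dt <- config$raw_dt
  n <- round(config$duration_s / dt)
  if (n < 2) stop("invalid config: fewer than 2 samples")
  time <- (seq_len(n) - 1) * dt
  p <- skill_params(skill, config)
  ext <- config$workspace_extent_mm

  centers <- list(dom = c(0, 0, 0), nd = c(p$sep_offset, 0, 0))
  pos <- list()
  for (inst in c("dom", "nd")) {
    xyz <- sapply(1:3, function(ax) {
      x0 <- centers[[inst]][ax] + runif(1, -ext / 10, ext / 10)
      mu <- ou_path(n, dt, theta = 0.5, sigma = 1.5,
                    target = centers[[inst]][ax], x0 = x0)
      ou_path(n, dt, theta = 2.0, sigma = p$sigma_pos, target = mu, x0 = x0)
    })
    colnames(xyz) <- c("x", "y", "z")
    pos[[inst]] <- xyz
  }
  force <- list()
  for (inst in c("dom", "nd")) {
    f <- ou_path(n, dt, theta = 1.5, sigma = p$force_sd,
                 target = p$force_mean[[inst]], x0 = p$force_mean[[inst]])
    force[[inst]] <- pmax(0, f)
  }
  active_dom <- activation_path(n, dt, p$active_frac[["dom"]])
  active_nd <- activation_path(n, dt, p$active_frac[["nd"]])

  # Bleeding: events add volume; clearance rate rises while aspirating.
  bleed_ev <- (runif(n) < p$bleed_rate * dt) * rexp(n, rate = 1 / 0.4)
  decay <- cumsum((0.2 + 0.8 * active_dom) * dt)
  blood <- exp(-decay) * cumsum(bleed_ev * exp(decay))
  # Healthy-tissue damage: cumulative Poisson event magnitudes.
  dmg_ev <- (runif(n) < p$damage_rate * dt) * rexp(n, rate = 1 / 0.15)
  damage <- cumsum(dmg_ev)
  # Tumor removal: exact solution of dT = r * active * (1 - T) dt.
  tumor <- 1 - exp(-p$tumor_rate * cumsum(active_dom) * dt)

  out <- data.frame(
    time = time,
    pos_dom_x = pos$dom[, "x"], pos_dom_y = pos$dom[, "y"],
    pos_dom_z = pos$dom[, "z"],
    pos_nd_x = pos$nd[, "x"], pos_nd_y = pos$nd[, "y"],
    pos_nd_z = pos$nd[, "z"],
    force_dom = force$dom, force_nd = force$nd,
    active_dom = active_dom, active_nd = active_nd,
    tumor_removed = tumor, blood_present = blood, healthy_damage = damage)
  structure(out, class = c("raw_stream", "data.frame"),
            participant_id = participant_id, trial_index = trial_index,
            group_label = group_label, skill = skill, seed = as.integer(seed))
}

#' Cohort design
#'
#' @param groups data.frame with columns `label`, `n_participants`,
#'   `skill_mean`, `skill_sd` (per-participant skill is drawn once from a
#'   normal truncated to \[-1, 1\] and shared across that participant's
#'   trials).
#' @param trials_per_participant trials performed by each participant
#'   (default 6).
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(groups, trials_per_participant = 6L) {
  stopifnot(is.data.frame(groups),
            all(c("label", "n_participants", "skill_mean", "skill_sd") %in%
                  names(groups)))
  if (any(groups$n_participants < 0) || trials_per_participant < 1)
    stop("invalid design: counts must be nonnegative, trials >= 1")
  structure(list(groups = groups,
                 trials_per_participant = as.integer(trials_per_participant)),
            class = "cohort_design")
}

#' Standard cohort designs
#'
#' `dev_cohort_design()` mirrors the development cohort (14 experts +
#' 12 novices, 6 trials each, 156 trials); `trainee_cohort_design()` the
#' 24-trainee test cohort (14 seniors + 10 juniors, 144 trials);
#' `four_group_design()` both together; `skill_ladder_design()` a ladder of
#' fixed skill levels for monotonicity checks.  Group skill distributions:
#' experts N(0.8, 0.1), seniors N(0.33, 0.15), juniors N(-0.33, 0.15),
#' novices N(-0.8, 0.1), truncated to \[-1, 1\]; the 0.33 anchors match the
#' risk-module expertise level codes.
#'
#' @param n_experts,n_novices,n_seniors,n_juniors group sizes.
#' @param trials_per_participant trials per participant (default 6).
#' @param levels skill levels of the ladder, one synthetic performer each.
#' @return a [cohort_design()].
#' @export
dev_cohort_design <- function(n_experts = 14L, n_novices = 12L,
                              trials_per_participant = 6L) {
  cohort_design(data.frame(
    label = c("expert", "novice"),
    n_participants = c(n_experts, n_novices),
    skill_mean = c(0.8, -0.8), skill_sd = c(0.1, 0.1)),
    trials_per_participant)
}

#' @rdname dev_cohort_design
#' @export
trainee_cohort_design <- function(n_seniors = 14L, n_juniors = 10L,
                                  trials_per_participant = 6L) {
  cohort_design(data.frame(
    label = c("senior", "junior"),
    n_participants = c(n_seniors, n_juniors),
    skill_mean = c(0.33, -0.33), skill_sd = c(0.15, 0.15)),
    trials_per_participant)
}

#' @rdname dev_cohort_design
#' @export
four_group_design <- function(n_experts = 14L, n_seniors = 14L,
                              n_juniors = 10L, n_novices = 12L,
                              trials_per_participant = 6L) {
  cohort_design(data.frame(
    label = c("expert", "senior", "junior", "novice"),
    n_participants = c(n_experts, n_seniors, n_juniors, n_novices),
    skill_mean = c(0.8, 0.33, -0.33, -0.8),
    skill_sd = c(0.1, 0.15, 0.15, 0.1)),
    trials_per_participant)
}

#' @rdname dev_cohort_design
#' @export
skill_ladder_design <- function(levels = seq(-1, 1, by = 0.25),
                                trials_per_participant = 6L) {
  cohort_design(data.frame(
    label = sprintf("skill%+0.2f", levels),
    n_participants = 1L, skill_mean = levels, skill_sd = 0),
    trials_per_participant)
}

rtrunc_norm <- function(mean, sd, lo = -1, hi = 1) {
  if (sd == 0) return(min(max(mean, lo), hi))
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Simulate a full cohort
#'
#' Draws one skill value per participant (shared across that participant's
#' trials), a trial duration uniform in `config$duration_range_s` per trial,
#' and a child seed per trial, then generates every stream.  A pure function
#' of `(design, config, seed)`.
#'
#' @param design a [cohort_design()].
#' @param config a [trial_config()]; per-trial durations override
#'   `config$duration_s`.
#' @param seed integer master seed.
#' @return list of `raw_stream` objects (possibly empty).
#' @export
simulate_cohort <- function(design, config, seed) {
  stopifnot(inherits(design, "cohort_design"), inherits(config, "trial_config"))
  set.seed(as.integer(seed))
  plan <- list()
  for (g in seq_len(nrow(design$groups))) {
    grp <- design$groups[g, ]
    if (grp$n_participants == 0) next
    for (i in seq_len(grp$n_participants)) {
      pid <- sprintf("%s_%02d", grp$label, i)
      skill <- rtrunc_norm(grp$skill_mean, grp$skill_sd)
      for (k in seq_len(design$trials_per_participant)) {
        plan[[length(plan) + 1]] <- list(
          pid = pid, group = grp$label, skill = skill, trial = k,
          duration = runif(1, config$duration_range_s[1],
                           config$duration_range_s[2]),
          seed = sample.int(.Machine$integer.max - 1, 1))
      }
    }
  }
  lapply(plan, function(tr) {
    cfg <- config
    cfg$duration_s <- tr$duration
    simulate_trial(cfg, tr$skill, tr$seed, participant_id = tr$pid,
                   trial_index = tr$trial, group_label = tr$group)
  })
}
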