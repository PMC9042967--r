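# End-to-end synthetic validation study: train the assessment model on the
# two skill extremes and test whether the continuous score recovers the
# latent skill of unseen intermediate performers.

#' Two-end training with skill-ladder and four-group evaluation
#'
#' For each seed: simulates a two-end development cohort (experts ~ skill
#' 0.8, novices ~ -0.8), splits it 70/15/15 by participant, trains the
#' expertise model, then scores (a) a held-out nine-level skill ladder
#' (skill -1 to +1 in steps of 0.25, six trials per level) and (b) a
#' held-out four-group cohort (expert/senior/junior/novice).  Reports the
#' Spearman rank correlation between true skill and mean predicted score on
#' the ladder, and whether the four group means come out in the expected
#' order.
#'
#' @param seeds integer vector, one study repetition per seed.
#' @param epochs training epochs per repetition (default 100, a scaled-down
#'   schedule suited to the strongly separable synthetic cohorts).
#' @param n_experts,n_novices development-cohort group sizes.
#' @param config a [trial_config()]; its `duration_range_s` governs trial
#'   lengths.
#' @param four_group a [cohort_design()] for the held-out group comparison.
#' @return list with `per_seed` (data.frame: seed, spearman, ordered, group
#'   means, test RMSE), `mean_spearman`, `ordering_fraction`, and the last
#'   seed's scored four-group cohort as `group_scores` (named list of
#'   participant averages, for downstream statistics).
#' @export
expertise_validation_study <- function(seeds = 1:5, epochs = 100,
                                       n_experts = 10, n_novices = 10,
                                       config = trial_config(
                                         duration_range_s = c(60, 120)),
                                       four_group = four_group_design()) {
  dev <- cohort_design(data.frame(
    label = c("expert", "novice"),
    n_participants = c(n_experts, n_novices),
    skill_mean = c(0.8, -0.8), skill_sd = c(0.1, 0.1)), 6L)
  rows <- list()
  group_scores <- NULL
  for (s in seeds) {
    streams <- simulate_cohort(dev, config, seed = s)
    trials <- lapply(streams, function(x) extract_metrics(regularize(x)))
    sp <- split_by_participant(trials, seed = s)
    model <- train_expertise_model(trials, sp,
                                   training_schedule(epochs = epochs,
                                                     seed = s))
    ladder <- lapply(simulate_cohort(skill_ladder_design(), config,
                                     seed = s + 1000L),
                     function(x) extract_metrics(regularize(x)))
    lps <- score_cohort(model, ladder)
    lavg <- vapply(lps, `[[`, numeric(1), "participant_average")
    lskill <- vapply(ladder[!duplicated(vapply(ladder, trial_pid,
                                               character(1)))],
                     function(t) attr(t, "skill"), numeric(1))
    rho <- cor(lskill, lavg, method = "spearman")
    fg <- lapply(simulate_cohort(four_group, config, seed = s + 2000L),
                 function(x) extract_metrics(regularize(x)))
    fps <- score_cohort(model, fg)
    favg <- vapply(fps, `[[`, numeric(1), "participant_average")
    fgrp <- vapply(fps, `[[`, character(1), "group_label")
    gm <- tapply(favg, fgrp, mean)
    ordered <- gm[["expert"]] > gm[["senior"]] &&
      gm[["senior"]] > gm[["junior"]] && gm[["junior"]] > gm[["novice"]]
    group_scores <- split(unname(favg), fgrp)
    rows[[length(rows) + 1]] <- data.frame(
      seed = s, spearman = rho, ordered = ordered,
      expert = gm[["expert"]], senior = gm[["senior"]],
      junior = gm[["junior"]], novice = gm[["novice"]],
      test_rmse = model$history$test)
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       mean_spearman = mean(per_seed$spearman),
       ordering_fraction = mean(per_seed$ordered),
       group_scores = group_scores)
}
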