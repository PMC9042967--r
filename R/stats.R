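# Statistical validation harness: one-way ANOVA with Tukey-Kramer post hoc
# and assumption checks on participant-average scores, plus ordinary least
# squares of score on year of neurosurgical training.

#' Compare participant-average scores across expertise groups
#'
#' Classical one-way ANOVA with Tukey-Kramer honestly-significant-difference
#' post hoc (valid for unequal group sizes), per-group Shapiro-Wilk normality
#' checks and a median-centered Levene (Brown-Forsythe) homogeneity test.
#' Group means carry t-based 95% confidence intervals.  When the
#' between-group sum of squares is exactly zero (all group means equal) the
#' F statistic is reported as 0 with p = 1.
#'
#' @param scores named list, one numeric vector of participant averages per
#'   group (>= 2 groups, each n >= 2).
#' @param conf_level confidence level for intervals; default 0.95.
#' @return a `validation_report` with elements `groups` (mean, CI, n,
#'   shapiro_p), `anova` (F, df, p, sums of squares), `tukey` (pairwise
#'   differences, CI, adjusted p) and `levene_p`.
#' @export
group_comparison <- function(scores, conf_level = 0.95) {
  if (!is.list(scores) || length(scores) < 2 || is.null(names(scores)))
    stop("scores must be a named list with at least 2 groups")
  ns <- lengths(scores)
  if (any(ns < 2))
    stop("insufficient group: every group needs n >= 2 (violated by ",
         paste(names(scores)[ns < 2], collapse = ", "), ")")
  df <- data.frame(
    value = unlist(scores, use.names = FALSE),
    group = factor(rep(names(scores), ns), levels = names(scores)))
  fit <- aov(value ~ group, data = df)
  an <- suppressWarnings(anova(fit))
  ss_between <- an$`Sum Sq`[1]
  ss_within <- an$`Sum Sq`[2]
  # Degenerate data: when the between-group variation is zero at working
  # precision, report F = 0 rather than a 0/0 rounding artifact.
  scale <- sum(df$value^2) + 1
  if (ss_between <= 1e-12 * scale || !is.finite(an$`F value`[1])) {
    ss_between <- 0
    f_stat <- 0; p_val <- 1
  } else {
    f_stat <- an$`F value`[1]; p_val <- an$`Pr(>F)`[1]
  }
  tk <- TukeyHSD(fit, conf.level = conf_level)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  alpha <- 1 - conf_level
  groups <- do.call(rbind, lapply(names(scores), function(g) {
    x <- scores[[g]]
    se <- sd(x) / sqrt(length(x))
    hw <- qt(1 - alpha / 2, length(x) - 1) * se
    data.frame(group = g, n = length(x), mean = mean(x),
               ci_lwr = mean(x) - hw, ci_upr = mean(x) + hw,
               shapiro_p = if (length(x) >= 3 && sd(x) > 0)
                 shapiro.test(x)$p.value else NA_real_)
  }))
  lev <- car::leveneTest(value ~ group, data = df, center = stats::median)
  structure(list(groups = groups,
                 anova = list(F = f_stat, df = unname(an$Df), p = p_val,
                              ss_between = ss_between, ss_within = ss_within),
                 tukey = tukey,
                 levene_p = lev$`Pr(>F)`[1],
                 conf_level = conf_level),
            class = "validation_report")
}

#' Regress average score on year of neurosurgical training
#'
#' Ordinary least squares of a trainee's average performance score on the
#' year of training (fellows conventionally coded as year 7).  Reports the
#' slope with its confidence interval, the overall F test, and (adjusted)
#' R-squared.  When the response is constant the fit is reported with slope
#' 0 and R-squared 0.
#'
#' @param participant_scores numeric vector of per-trainee average scores.
#' @param years_in_training numeric vector of training years, same length.
#' @param conf_level confidence level for the slope interval; default 0.95.
#' @return a `validation_report` with element `regression`.
#' @export
training_year_regression <- function(participant_scores, years_in_training,
                                     conf_level = 0.95) {
  y <- participant_scores; x <- years_in_training
  if (length(y) != length(x) || length(y) < 3)
    stop("need >= 3 paired observations")
  if (sd(x) == 0)
    stop("degenerate regression: years_in_training is constant")
  fit <- suppressWarnings(lm(y ~ x))
  sm <- suppressWarnings(summary(fit))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    r2 <- 0; adj_r2 <- 0; f_stat <- 0; p_val <- 1
  } else {
    r2 <- sm$r.squared; adj_r2 <- sm$adj.r.squared
    f_stat <- unname(sm$fstatistic[1])
    p_val <- pf(f_stat, sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
  }
  ci <- suppressWarnings(confint(fit, "x", level = conf_level))
  structure(list(regression = list(
    slope = unname(coef(fit)["x"]), intercept = unname(coef(fit)[1]),
    slope_ci = c(ci[1], ci[2]), F = f_stat,
    df = c(1, length(y) - 2), p = p_val,
    r_squared = r2, adj_r_squared = adj_r2, n = length(y)),
    conf_level = conf_level),
    class = "validation_report")
}

#' Code training years for a trainee roster (fellows as year 7)
#' @param group_labels character vector of group labels.
#' @param years numeric years for residents; `NA` entries with label
#'   "fellow" are coded 7.
#' @return numeric years vector.
#' @export
code_training_years <- function(group_labels, years) {
  years[is.na(years) & group_labels == "fellow"] <- 7
  years
}

#' @export
print.validation_report <- function(x, ...) {
  if (!is.null(x$groups)) {
    cat("Group comparison (one-way ANOVA, Tukey-Kramer post hoc)\n")
    for (i in seq_len(nrow(x$groups)))
      cat(sprintf("  %-10s n=%2d  mean %+.3f  %d%% CI [%+.3f, %+.3f]\n",
                  x$groups$group[i], x$groups$n[i], x$groups$mean[i],
                  round(100 * x$conf_level),
                  x$groups$ci_lwr[i], x$groups$ci_upr[i]))
    cat(sprintf("  F(%d,%d) = %.3f, p = %.4g\n", x$anova$df[1],
                x$anova$df[2], x$anova$F, x$anova$p))
    cat(sprintf("  Levene (median-centered) p = %.3f\n", x$levene_p))
    for (i in seq_len(nrow(x$tukey)))
      cat(sprintf("  %-20s diff %+.3f  CI [%+.3f, %+.3f]  p = %.4g\n",
                  x$tukey$pair[i], x$tukey$diff[i], x$tukey$lwr[i],
                  x$tukey$upr[i], x$tukey$p_adj[i]))
  }
  if (!is.null(x$regression)) {
    r <- x$regression
    cat(sprintf(paste0("Training-year regression: slope %+.3f/yr ",
                       "[%+.3f, %+.3f], F(%d,%d) = %.2f, p = %.4g, ",
                       "R2 = %.3f (adj %.3f)\n"),
                r$slope, r$slope_ci[1], r$slope_ci[2], r$df[1], r$df[2],
                r$F, r$p, r$r_squared, r$adj_r_squared))
  }
  invisible(x)
}
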