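# Independent brute-force oracles, deliberately loop-based with no shared
# code paths with the package implementation.

# Sample-by-sample recomputation of the 16-metric table.
oracle_metrics <- function(raw, window_s = 0.2) {
  n <- nrow(raw)
  dt <- raw$time[2] - raw$time[1]
  spw <- round(window_s / dt)
  n_win <- floor(n * dt / window_s + 1e-9)
  pd <- cbind(raw$pos_dom_x, raw$pos_dom_y, raw$pos_dom_z)
  pn <- cbind(raw$pos_nd_x, raw$pos_nd_y, raw$pos_nd_z)
  vd <- matrix(0, n, 3); vn <- matrix(0, n, 3)
  ad <- matrix(0, n, 3); an <- matrix(0, n, 3)
  for (i in 2:n) {
    for (k in 1:3) {
      vd[i, k] <- (pd[i, k] - pd[i - 1, k]) / dt
      vn[i, k] <- (pn[i, k] - pn[i - 1, k]) / dt
    }
  }
  for (i in 2:n) {
    for (k in 1:3) {
      ad[i, k] <- (vd[i, k] - vd[i - 1, k]) / dt
      an[i, k] <- (vn[i, k] - vn[i - 1, k]) / dt
    }
  }
  nrm <- function(v) sqrt(sum(v^2))
  out <- matrix(NA_real_, n_win, 16)
  colnames(out) <- metric_manifest()$name
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * spw + 1):(w * spw)
    sep <- vsd <- vsn <- asd <- asn <- fda <- fdb <- blv <- afa <- afb <-
      rlv <- pla <- plb <- brt <- 0
    for (i in idx) {
      sep <- sep + nrm(pd[i, ] - pn[i, ])
      vsd <- vsd + nrm(vd[i, ]); vsn <- vsn + nrm(vn[i, ])
      asd <- asd + nrm(ad[i, ]); asn <- asn + nrm(an[i, ])
      fda <- fda + raw$force_dom[i]; fdb <- fdb + raw$force_nd[i]
      blv <- blv + raw$blood_present[i]
      afa <- afa + as.numeric(raw$active_dom[i])
      afb <- afb + as.numeric(raw$active_nd[i])
      rlv <- rlv + nrm(vd[i, ] - vn[i, ])
      if (i > 1) {
        pla <- pla + nrm(pd[i, ] - pd[i - 1, ])
        plb <- plb + nrm(pn[i, ] - pn[i - 1, ])
        brt <- brt + max(0, raw$blood_present[i] - raw$blood_present[i - 1])
      }
    }
    # path/bleeding steps with i == 1 contribute 0 by convention
    e_prev <- if (w == 1) raw$tumor_removed[1] else
      raw$tumor_removed[(w - 1) * spw]
    d_prev <- if (w == 1) raw$healthy_damage[1] else
      raw$healthy_damage[(w - 1) * spw]
    out[w, "tip_separation"] <- sep / spw
    out[w, "force_aspirator"] <- fda / spw
    out[w, "force_bipolar"] <- fdb / spw
    out[w, "velocity_aspirator"] <- vsd / spw
    out[w, "velocity_bipolar"] <- vsn / spw
    out[w, "accel_aspirator"] <- asd / spw
    out[w, "accel_bipolar"] <- asn / spw
    out[w, "tumor_removed"] <- raw$tumor_removed[w * spw] - e_prev
    out[w, "blood_volume"] <- blv / spw
    out[w, "healthy_damage"] <- raw$healthy_damage[w * spw] - d_prev
    out[w, "path_length_aspirator"] <- pla
    out[w, "path_length_bipolar"] <- plb
    out[w, "active_fraction_aspirator"] <- afa / spw
    out[w, "active_fraction_bipolar"] <- afb / spw
    out[w, "bleeding_rate"] <- brt / window_s
    out[w, "relative_velocity"] <- rlv / spw
  }
  out
}

# Textbook one-way ANOVA from explicit sums of squares.
oracle_anova <- function(groups) {
  allv <- unlist(groups)
  gm <- mean(allv)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - gm)^2
    for (x in g) ssw <- ssw + (x - mean(g))^2
  }
  df1 <- length(groups) - 1
  df2 <- length(allv) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df = c(df1, df2), ss_between = ssb, ss_within = ssw,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# Closed-form simple OLS via normal equations.
oracle_ols <- function(y, x, conf_level = 0.95) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tcrit <- qt(1 - (1 - conf_level) / 2, n - 2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(resid^2) / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  f <- (tss - sum(resid^2)) / (sum(resid^2) / (n - 2))
  list(slope = slope, intercept = intercept,
       slope_ci = c(slope - tcrit * se, slope + tcrit * se),
       r_squared = r2, adj_r_squared = adj, F = f)
}
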