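# Independent oracles and fixture builders shared across tests.

# noiseless cosinor series on a zeitgeber grid
make_cosinor_series <- function(times = seq(0, 20, by = 4), n_rep = 3,
                                mesor = 2, amplitude = 1, phase = 8,
                                period = 24, trend = 0, noise_sd = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- rep(times, each = n_rep)
  mu <- mesor + trend * (t - mean(times)) +
    amplitude * cos(2 * pi * (t - phase) / period)
  y <- if (noise_sd > 0) mu + rnorm(length(t), 0, noise_sd) else mu
  data.frame(time_h = t, value = y)
}

# brute-force (period, phase) grid scan with lm(); same grid and tie rule,
# independent code path
oracle_grid_scan <- function(series, period_grid = seq(20, 28, by = 0.5),
                             phase_step = 0.25) {
  best <- NULL
  for (P in period_grid) {
    for (phi in seq(0, P - phase_step, by = phase_step)) {
      d <- data.frame(y = series$value,
                      tr = series$time_h - mean(series$time_h),
                      am = cos(2 * pi * (series$time_h - phi) / P))
      sse <- sum(residuals(lm(y ~ tr + am, data = d))^2)
      if (is.null(best) || sse < best$sse - 1e-12 ||
          (abs(sse - best$sse) <= 1e-12 &&
             (abs(P - 24) < abs(best$period - 24) - 1e-12 ||
                (abs(abs(P - 24) - abs(best$period - 24)) <= 1e-12 &&
                   phi < best$phase))))
        best <- list(phase = phi, period = P, sse = sse)
    }
  }
  # same acrophase convention: flip phase by half a period if the cosine
  # coefficient comes out negative
  d <- data.frame(y = series$value,
                  tr = series$time_h - mean(series$time_h),
                  am = cos(2 * pi * (series$time_h - best$phase) / best$period))
  if (coef(lm(y ~ tr + am, data = d))["am"] < 0)
    best$phase <- (best$phase + best$period / 2) %% best$period
  best
}

# classical two-way repeated-measures ANOVA (between = condition, within =
# time) from explicit sums of squares, for complete balanced data
oracle_rm_anova <- function(d) {
  # d: condition, animal, time, y; balanced and complete
  a <- length(unique(d$condition)); n <- length(unique(d$animal)) / a
  tt <- length(unique(d$time))
  gm <- mean(d$y)
  mc <- tapply(d$y, d$condition, mean)
  ms <- tapply(d$y, d$animal, mean)
  mt <- tapply(d$y, d$time, mean)
  mct <- tapply(d$y, list(d$condition, d$time), mean)
  ss_c <- tt * n * sum((mc - gm)^2)
  cond_of_animal <- tapply(as.character(d$condition), d$animal, `[`, 1)
  ss_s <- tt * sum((ms - mc[cond_of_animal])^2)
  ss_t <- a * n * sum((mt - gm)^2)
  ss_ct <- n * sum((sweep(sweep(mct, 1, mc, "-"), 2, mt, "-") + gm)^2)
  ss_tot <- sum((d$y - gm)^2)
  ss_e <- ss_tot - ss_c - ss_s - ss_t - ss_ct
  df_c <- a - 1; df_s <- a * (n - 1); df_t <- tt - 1
  df_ct <- df_c * df_t; df_e <- df_s * df_t
  list(
    F_condition = (ss_c / df_c) / (ss_s / df_s),
    p_condition = pf((ss_c / df_c) / (ss_s / df_s), df_c, df_s, lower.tail = FALSE),
    F_time = (ss_t / df_t) / (ss_e / df_e),
    F_interaction = (ss_ct / df_ct) / (ss_e / df_e),
    df = c(condition = df_s, error = df_e))
}

# hypergeometric over-representation tail by exhaustive enumeration
oracle_hyper_tail <- function(overlap, term_size, query_size, universe_size) {
  ks <- overlap:min(term_size, query_size)
  sum(choose(term_size, ks) * choose(universe_size - term_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y); n <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)]) # rank sum of group x
  combs <- combn(length(pooled), n)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# pooled-variance two-sample t statistic and p, textbook formula
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, df = nx + ny - 2,
       p = 2 * pt(-abs(tstat), nx + ny - 2))
}
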