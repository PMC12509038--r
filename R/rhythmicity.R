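#' @title Cosinor rhythmometry of clock-gene expression series
#' @description Tools to estimate the phase and period of replicated
#'   relative-expression (2^-ddCt) time series sampled at zeitgeber times,
#'   and to fit the trend + amplitude linear model
#'   \deqn{y = b_0 + b_1 (t - \bar t) + b_2 \cos(2\pi (t - \phi)/P) + e}
#'   per gene and condition. Phase and period come from an exhaustive
#'   least-squares scan over a (period, phase) grid; the selected (phi, P)
#'   then parameterize the ordinary least-squares fit. Replicates enter as
#'   independent rows; no pre-averaging.
#' @name rhythmicity
NULL

#' Relative expression (2^-ddCt)
#'
#' @param ct_target Ct of the target gene.
#' @param ct_reference Ct of the reference (housekeeping) gene in the same
#'   sample.
#' @param delta_ct_calibrator dCt of the calibrator condition
#'   (target - reference), default 0.
#' @return 2^-((ct_target - ct_reference) - delta_ct_calibrator), always > 0.
#' @export
relative_expression <- function(ct_target, ct_reference, delta_ct_calibrator = 0) {
  if (any(!is.finite(c(ct_target, ct_reference, delta_ct_calibrator))))
    stop("Ct values must be finite")
  2^-((ct_target - ct_reference) - delta_ct_calibrator)
}

#' Cosinor design regressors
#'
#' Builds the two regressors of the trend + amplitude model: the centered
#' time trend t - mean(t) and the cosine amplitude term
#' cos(2*pi*(t - phase)/period).
#'
#' @param times sampling times in hours.
#' @param phase_h acrophase in hours.
#' @param period_h period in hours, > 0.
#' @param center optional centering constant; defaults to `mean(times)`.
#'   Supply the original grid mean when predicting at new times.
#' @return List with numeric vectors `trend` and `amplitude`.
#' @export
make_regressors <- function(times, phase_h, period_h, center = mean(times)) {
  if (length(times) < 1) stop("at least one time is required")
  if (!is.finite(period_h) || period_h <= 0) stop("period_h must be > 0")
  list(trend = times - center,
       amplitude = cos(2 * pi * (times - phase_h) / period_h))
}

#' Grid-scan phase and period estimation
#'
#' Exhaustive least-squares cosinor: for every (period, phase) grid point
#' the trend + amplitude model is fit by OLS and the residual sum of
#' squares recorded; the minimizing grid point is returned. Ties are broken
#' toward the period closest to 24 h, then the smallest phase. A constant
#' series is flagged arrhythmic (amplitude has no information) instead of
#' returning an arbitrary phase.
#'
#' @param series data frame with columns `time_h` and `value` (replicates
#'   as separate rows), or the output element of [gen_clock_series()].
#' @param period_grid candidate periods in hours (default 20-28 h step 0.5).
#' @param phase_resolution_h phase grid step in hours (default 0.25).
#' @return Object of class `rhythm_estimate`: list with `phase_h`,
#'   `period_h`, `sse`, `arrhythmic` flag.
#' @export
estimate_phase_period <- function(series, period_grid = seq(20, 28, by = 0.5),
                                  phase_resolution_h = 0.25) {
  series <- as.data.frame(series)
  stopifnot(all(c("time_h", "value") %in% names(series)))
  t <- series$time_h; y <- series$value
  if (length(unique(t)) < 4)
    stop("estimate_phase_period needs >= 4 distinct times")
  if (any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(y) == 0) {
    return(structure(list(phase_h = NA_real_, period_h = NA_real_,
                          sse = 0, arrhythmic = TRUE),
                     class = "rhythm_estimate"))
  }
  best <- list(sse = Inf, phase = NA_real_, period = NA_real_)
  trend <- t - mean(t)
  for (P in period_grid) {
    phases <- seq(0, P - phase_resolution_h, by = phase_resolution_h)
    for (phi in phases) {
      X <- cbind(1, trend, cos(2 * pi * (t - phi) / P))
      sse <- sum(stats::lm.fit(X, y)$residuals^2)
      better <- sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 &&
           (abs(P - 24) < abs(best$period - 24) - 1e-12 ||
              (abs(abs(P - 24) - abs(best$period - 24)) <= 1e-12 &&
                 phi < best$phase)))
      if (better) best <- list(sse = sse, phase = phi, period = P)
    }
  }
  # the scan is blind to the sign of the cosine coefficient (phi and
  # phi + P/2 give identical fits); report the acrophase, i.e. the phase
  # with a positive amplitude coefficient
  Xb <- cbind(1, trend, cos(2 * pi * (t - best$phase) / best$period))
  if (stats::lm.fit(Xb, y)$coefficients[3] < 0)
    best$phase <- (best$phase + best$period / 2) %% best$period
  structure(list(phase_h = best$phase, period_h = best$period,
                 sse = best$sse, arrhythmic = FALSE),
            class = "rhythm_estimate")
}

#' Fit the trend + amplitude cosinor linear model
#'
#' OLS of expression on intercept, centered time trend, and the cosine
#' amplitude regressor at a given (phase, period).
#'
#' @param series data frame with `time_h` and `value` columns; `gene` and
#'   `condition` columns, if present, are carried into the fit.
#' @param phase_h acrophase in hours (e.g. from [estimate_phase_period()]).
#' @param period_h period in hours.
#' @return Object of class `cosinor_fit`: coefficients `beta_intercept`,
#'   `beta_trend`, `beta_amp`, plus `phase_h`, `period_h`, `time_center`,
#'   `residual_variance`, `r_squared`, `fitted`, `n`.
#' @export
fit_trend_amplitude_model <- function(series, phase_h, period_h) {
  series <- as.data.frame(series)
  stopifnot(all(c("time_h", "value") %in% names(series)))
  if (nrow(series) < 3) stop("need >= 3 observations")
  reg <- make_regressors(series$time_h, phase_h, period_h)
  X <- cbind(intercept = 1, trend = reg$trend, amplitude = reg$amplitude)
  if (qr(X)$rank < 3)
    stop("collinear design: trend and amplitude regressors are not identifiable")
  fit <- stats::lm.fit(X, series$value)
  res <- fit$residuals
  dfres <- nrow(series) - 3
  tss <- sum((series$value - mean(series$value))^2)
  structure(list(
    gene = if ("gene" %in% names(series)) series$gene[1] else NA_character_,
    condition = if ("condition" %in% names(series)) series$condition[1] else NA_character_,
    phase_h = phase_h, period_h = period_h,
    time_center = mean(series$time_h),
    beta_intercept = unname(fit$coefficients["intercept"]),
    beta_trend = unname(fit$coefficients["trend"]),
    beta_amp = unname(fit$coefficients["amplitude"]),
    residual_variance = if (dfres > 0) sum(res^2) / dfres else 0,
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    fitted = unname(fit$fitted.values), n = nrow(series)),
    class = "cosinor_fit")
}

#' Predict expression from a cosinor fit
#'
#' Evaluates the fitted trend + amplitude model at arbitrary times (e.g. a
#' dense sub-sampling grid). The trend term keeps the centering constant of
#' the original fit.
#'
#' @param fit a `cosinor_fit`.
#' @param times hours at which to evaluate.
#' @return Numeric vector of predicted expression values.
#' @export
predict_expression <- function(fit, times) {
  stopifnot(inherits(fit, "cosinor_fit"))
  reg <- make_regressors(times, fit$phase_h, fit$period_h,
                         center = fit$time_center)
  fit$beta_intercept + fit$beta_trend * reg$trend + fit$beta_amp * reg$amplitude
}

#' Estimate-then-fit convenience wrapper
#'
#' Runs [estimate_phase_period()] then [fit_trend_amplitude_model()] on one
#' gene/condition series.
#'
#' @inheritParams estimate_phase_period
#' @return A `cosinor_fit`, or an arrhythmic `rhythm_estimate` when the
#'   series is constant.
#' @export
cosinor_fit <- function(series, period_grid = seq(20, 28, by = 0.5),
                        phase_resolution_h = 0.25) {
  est <- estimate_phase_period(series, period_grid, phase_resolution_h)
  if (est$arrhythmic) return(est)
  fit_trend_amplitude_model(series, est$phase_h, est$period_h)
}

#' Rhythm divergence between two conditions
#'
#' Quantifies desynchronization between two cosinor fits of the same gene:
#' the circular phase difference (b minus a, reported in
#' (-period/2, period/2]), the amplitude ratio |beta_amp_b| / |beta_amp_a|,
#' and the mesor (intercept) ratio.
#'
#' @param fit_a,fit_b `cosinor_fit` objects for the same gene with the same
#'   period convention.
#' @return List with `gene`, `delta_phase_h`, `amplitude_ratio`,
#'   `mesor_ratio`, `flag` ("zero_reference_amplitude" when fit_a has no
#'   amplitude, in which case the ratio is NA).
#' @export
rhythm_divergence <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "cosinor_fit"), inherits(fit_b, "cosinor_fit"))
  if (!isTRUE(all.equal(fit_a$period_h, fit_b$period_h)))
    stop("fits must share the same period")
  P <- fit_a$period_h
  d <- (fit_b$phase_h - fit_a$phase_h) %% P
  if (d > P / 2) d <- d - P  # map into (-P/2, P/2]
  flag <- NA_character_
  amp_ratio <- if (fit_a$beta_amp == 0) {
    flag <- "zero_reference_amplitude"
    NA_real_
  } else abs(fit_b$beta_amp) / abs(fit_a$beta_amp)
  list(gene = fit_a$gene, delta_phase_h = d, amplitude_ratio = amp_ratio,
       mesor_ratio = fit_b$beta_intercept / fit_a$beta_intercept, flag = flag)
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("Cosinor fit%s%s: phase %.2f h, period %.1f h\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene),
              if (is.na(x$gene)) "" else paste0(" / ", x$condition, "]"),
              x$phase_h, x$period_h))
  cat(sprintf("  mesor %.4g, trend %.4g /h, amplitude %.4g (R^2 = %.3f, n = %d)\n",
              x$beta_intercept, x$beta_trend, x$beta_amp, x$r_squared, x$n))
  invisible(x)
}
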