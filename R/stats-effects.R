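#' Eta-squared effect size from a t statistic
#'
#' Converts an unpaired two-sample t statistic and its degrees of freedom
#' (Welch-Satterthwaite fractional df allowed) into eta squared, the
#' proportion of total variance explained by the group factor:
#' \deqn{\eta^2 = t^2 / (t^2 + df)}
#'
#' @param t_stat t statistic (any sign; only its magnitude matters).
#' @param df degrees of freedom, > 0.
#' @return Eta squared in [0, 1). Vectorised over both arguments.
#' @examples
#' eta_squared_from_t(3.050, 23)
#' @export
eta_squared_from_t <- function(t_stat, df) {
  stopifnot(is.numeric(t_stat), is.numeric(df))
  if (any(!is.finite(t_stat)) || any(!is.finite(df)))
    stop("t_stat and df must be finite")
  if (any(df <= 0)) stop("df must be > 0")
  t_stat^2 / (t_stat^2 + df)
}

#' Minimal detectable Cohen's d (sensitivity power analysis)
#'
#' Solves the sensitivity problem for an unpaired two-sample t test: the
#' smallest standardized mean difference d that reaches the requested power
#' at the requested alpha, given the two group sizes. Power is computed
#' exactly from the noncentral t distribution with noncentrality
#' delta = d * sqrt(n1 * n2 / (n1 + n2)) and df = n1 + n2 - 2; for the
#' two-tailed test both rejection tails are summed. The root is found to
#' |power(d) - power| < 1e-8.
#'
#' @param n1,n2 group sizes, integers >= 2.
#' @param alpha significance level in (0, 1).
#' @param power target power in (alpha, 1).
#' @param tails 1 or 2 (default 2, the usual two-tailed test).
#' @return Minimal detectable d (positive scalar).
#' @examples
#' sensitivity_cohen_d(10, 15)  # ~1.54
#' @export
sensitivity_cohen_d <- function(n1, n2, alpha = 0.05, power = 0.95, tails = 2) {
  stopifnot(length(n1) == 1, length(n2) == 1)
  if (!is.finite(n1) || !is.finite(n2) || n1 < 2 || n2 < 2)
    stop("n1 and n2 must be integers >= 2")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.finite(power) || power <= alpha || power >= 1)
    stop("power must be in (alpha, 1)")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  df <- n1 + n2 - 2
  f <- function(d) noncentral_t_power(d, n1, n2, alpha, tails) - power
  # power is strictly increasing in d; bracket then refine
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = .Machine$double.eps^0.75)$root
}

#' Power of the two-sample t test at effect size d
#'
#' Exact power from the noncentral t distribution; both tails are included
#' for the two-tailed test.
#'
#' @inheritParams sensitivity_cohen_d
#' @param d Cohen's d.
#' @return Power in (0, 1).
#' @export
noncentral_t_power <- function(d, n1, n2, alpha = 0.05, tails = 2) {
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == 2) {
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp)
  } else {
    tcrit <- stats::qt(1 - alpha, df)
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Normality gate for two-sample test selection
#'
#' Applies a normality test to each group and recommends a parametric test
#' only when neither group rejects normality at `alpha`. The default test is
#' Shapiro-Wilk; `method = "ks"` uses the Lilliefors-corrected
#' Kolmogorov-Smirnov test.
#'
#' @param sample_a,sample_b numeric vectors, n >= 3 each (>= 4 for "ks").
#' @param alpha rejection level for each normality test.
#' @param method "shapiro" (default) or "ks".
#' @return "parametric" or "nonparametric".
#' @export
normality_gate <- function(sample_a, sample_b, alpha = 0.05,
                           method = c("shapiro", "ks")) {
  method <- match.arg(method)
  if (length(sample_a) < 3 || length(sample_b) < 3)
    stop("normality_gate needs at least 3 values per group")
  pfun <- switch(method,
    shapiro = function(x) stats::shapiro.test(x)$p.value,
    ks = function(x) nortest::lillie.test(x)$p.value)
  p <- vapply(list(sample_a, sample_b), function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: certainly not Gaussian
    pfun(x)
  }, numeric(1))
  if (any(p < alpha)) "nonparametric" else "parametric"
}

#' Two-sample test with the study's test menu
#'
#' Runs a two-tailed unpaired comparison of two samples using Student's t,
#' Welch's t, or the Mann-Whitney (Wilcoxon rank-sum) test. With
#' `variant = "auto"` the choice follows [normality_gate()]: parametric
#' (Welch if the variance ratio exceeds `welch_ratio`) or Mann-Whitney.
#' Mann-Whitney uses exact enumeration up to a combined n of
#' `exact_max_n` (ties permitting) and the tie-corrected normal
#' approximation above it.
#'
#' @param sample_a,sample_b numeric vectors, >= 2 values each.
#' @param variant "student", "welch", "mann_whitney", or "auto".
#' @param conf_level confidence level for the mean-difference CI.
#' @param welch_ratio variance ratio beyond which "auto" switches Student
#'   to Welch.
#' @param exact_max_n combined-n switchover from exact to approximate
#'   Mann-Whitney.
#' @return Object of class `two_sample_test`: a list with `method`,
#'   `statistic`, `df` (NA for Mann-Whitney), `p`, `ci_low`, `ci_high`,
#'   `eta_squared` (t variants only), `estimate` (difference of means a - b),
#'   and `flag` (e.g. "zero_variance").
#' @export
two_sample_test <- function(sample_a, sample_b,
                            variant = c("auto", "student", "welch", "mann_whitney"),
                            conf_level = 0.95, welch_ratio = 4,
                            exact_max_n = 16) {
  variant <- match.arg(variant)
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("two_sample_test needs at least 2 values per group")
  if (variant == "auto") {
    if (normality_gate(sample_a, sample_b) == "nonparametric") {
      variant <- "mann_whitney"
    } else {
      vr <- stats::var(sample_a) / stats::var(sample_b)
      variant <- if (is.finite(vr) && (vr > welch_ratio || vr < 1 / welch_ratio))
        "welch" else "student"
    }
  }
  flag <- NA_character_
  if (variant %in% c("student", "welch")) {
    if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
      # degenerate: no within-group variance. Equal means -> p = 1 by
      # convention; different means -> unbounded statistic, p = 0, flagged.
      delta <- mean(sample_a) - mean(sample_b)
      return(structure(list(method = variant,
                            statistic = if (delta == 0) 0 else Inf * sign(delta),
                            df = NA_real_,
                            p = if (delta == 0) 1 else 0,
                            ci_low = delta, ci_high = delta,
                            eta_squared = if (delta == 0) 0 else 1,
                            estimate = delta,
                            flag = "zero_variance"),
                       class = "two_sample_test"))
    }
    ht <- stats::t.test(sample_a, sample_b, var.equal = (variant == "student"),
                        conf.level = conf_level)
    res <- list(method = variant,
                statistic = unname(ht$statistic),
                df = unname(ht$parameter),
                p = ht$p.value,
                ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
                eta_squared = eta_squared_from_t(unname(ht$statistic),
                                                unname(ht$parameter)),
                estimate = unname(diff(rev(ht$estimate))),
                flag = flag)
  } else {
    exact <- (length(sample_a) + length(sample_b)) <= exact_max_n &&
      !anyDuplicated(c(sample_a, sample_b))
    ht <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                              exact = exact, correct = !exact))
    res <- list(method = "mann_whitney",
                statistic = unname(ht$statistic),
                df = NA_real_, p = ht$p.value,
                ci_low = NA_real_, ci_high = NA_real_,
                eta_squared = NA_real_,
                estimate = mean(sample_a) - mean(sample_b),
                flag = if (exact) NA_character_ else "normal_approximation")
  }
  structure(res, class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat(sprintf("Two-sample test (%s)\n", x$method))
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n", x$statistic,
              ifelse(is.na(x$df), "-", format(x$df, digits = 4)), x$p))
  if (!is.na(x$ci_low))
    cat(sprintf("  mean difference %.4g, 95%% CI [%.4g, %.4g]\n",
                x$estimate, x$ci_low, x$ci_high))
  if (!is.na(x$eta_squared))
    cat(sprintf("  eta-squared = %.4f\n", x$eta_squared))
  invisible(x)
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param p_values numeric p values in [0, 1].
#' @param m family size (defaults to `length(p_values)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  check_pvalues(p_values)
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p_values)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric p values in [0, 1].
#' @return BH-adjusted values (monotone, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  check_pvalues(p_values)
  stats::p.adjust(p_values, method = "BH")
}

check_pvalues <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must be numeric in [0, 1]")
  invisible(p)
}
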