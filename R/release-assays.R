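#' @title Superfusion release assays: fractional release and evoked overflow
#' @description Four 3-minute superfusate fractions are collected from
#'   synaptosomes or gliosomes pre-loaded with a radiolabelled transmitter;
#'   a brief KCl pulse falls within fractions 2-3. Release into each
#'   fraction is expressed as a percentage of the total radioactivity
#'   (four fractions + particles remaining on the filter), and the evoked
#'   overflow is the content of the two stimulated fractions minus the two
#'   flanking basal fractions.
#' @name release_assays
NULL

#' Fractional release percentages
#'
#' @param fraction_counts numeric vector of 4 radioactivity counts (dpm),
#'   all >= 0.
#' @param residual_counts radioactivity remaining in the superfused
#'   particles, >= 0.
#' @return List with `fraction_pct` (length 4) and `residual_pct`; the five
#'   values sum to 100.
#' @export
fraction_percentages <- function(fraction_counts, residual_counts) {
  if (length(fraction_counts) != 4)
    stop("exactly 4 fraction counts are required")
  if (any(!is.finite(fraction_counts)) || any(fraction_counts < 0) ||
      !is.finite(residual_counts) || residual_counts < 0)
    stop("counts must be finite and >= 0")
  total <- sum(fraction_counts) + residual_counts
  if (total <= 0) stop("total radioactivity must be > 0")
  list(fraction_pct = 100 * fraction_counts / total,
       residual_pct = 100 * residual_counts / total)
}

#' KCl-evoked overflow
#'
#' Overflow = (fraction 2 + fraction 3) - (fraction 1 + fraction 4), i.e.
#' stimulated content minus flanking basal content. Negative values are
#' meaningful (reduced exocytosis) and are not clipped.
#'
#' @param fraction_pct numeric vector of 4 fractional release percentages.
#' @return Overflow in percentage-of-total units.
#' @export
evoked_overflow <- function(fraction_pct) {
  if (length(fraction_pct) != 4) stop("exactly 4 fraction percentages required")
  (fraction_pct[2] + fraction_pct[3]) - (fraction_pct[1] + fraction_pct[4])
}

#' Evoked overflow as a percentage over basal release
#'
#' Normalizes the overflow by the basal release. The default denominator is
#' the summed flanking basal fractions (pct1 + pct4); `denominator =
#' "mean_basal"` divides by their mean instead (twice the ratio).
#'
#' @param fraction_pct numeric vector of 4 fractional release percentages.
#' @param denominator "sum_basal" (default) or "mean_basal".
#' @return 100 * overflow / basal.
#' @export
overflow_over_basal <- function(fraction_pct,
                                denominator = c("sum_basal", "mean_basal")) {
  denominator <- match.arg(denominator)
  basal <- fraction_pct[1] + fraction_pct[4]
  if (basal <= 0) stop("basal release (fractions 1 + 4) must be > 0")
  if (denominator == "mean_basal") basal <- basal / 2
  100 * evoked_overflow(fraction_pct) / basal
}

#' Per-run overflow table from raw superfusion counts
#'
#' @param runs data frame with columns `run_id`, `condition`, and fraction
#'   counts `f1`..`f4` plus `residual` (dpm). Extra annotation columns
#'   (`region`, `particle_type`, `tracer`) are carried through.
#' @return Input annotation columns plus `pct1`..`pct4`, `residual_pct`,
#'   `overflow_pct`, `overflow_over_basal_pct`.
#' @export
overflow_table <- function(runs) {
  req <- c("run_id", "condition", paste0("f", 1:4), "residual")
  missing_cols <- setdiff(req, names(runs))
  if (length(missing_cols))
    stop("runs is missing columns: ", paste(missing_cols, collapse = ", "))
  keep <- intersect(c("run_id", "condition", "region", "particle_type", "tracer"),
                    names(runs))
  out <- runs[keep]
  pct <- t(apply(runs[, c(paste0("f", 1:4), "residual")], 1, function(r) {
    fp <- fraction_percentages(as.numeric(r[1:4]), as.numeric(r[5]))
    c(fp$fraction_pct, fp$residual_pct)
  }))
  colnames(pct) <- c(paste0("pct", 1:4), "residual_pct")
  out <- cbind(out, as.data.frame(pct))
  out$overflow_pct <- apply(pct[, 1:4, drop = FALSE], 1, evoked_overflow)
  out$overflow_over_basal_pct <-
    apply(pct[, 1:4, drop = FALSE], 1, overflow_over_basal)
  rownames(out) <- NULL
  out
}

#' Compare release between two conditions
#'
#' Direct comparative two-tailed unpaired Student t test on a per-run
#' release measure.
#'
#' @param runs_a,runs_b data frames as accepted by [overflow_table()], one
#'   per condition, each with >= 2 runs.
#' @param measure "overflow" (percentage-of-total units) or "over_basal".
#' @return A [two_sample_test()] result (Student t). When both groups have
#'   zero variance and different means the result is flagged
#'   "zero_variance" rather than reporting an infinite statistic.
#' @export
compare_release <- function(runs_a, runs_b,
                            measure = c("overflow", "over_basal")) {
  measure <- match.arg(measure)
  col <- switch(measure, overflow = "overflow_pct",
                over_basal = "overflow_over_basal_pct")
  xa <- overflow_table(runs_a)[[col]]
  xb <- overflow_table(runs_b)[[col]]
  if (length(xa) < 2 || length(xb) < 2)
    stop("compare_release needs at least 2 runs per group")
  two_sample_test(xa, xb, variant = "student")
}
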