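#' @title Gadolinium tracer signal-enhancement kinetics
#' @description Quantifies tracer transport after cisterna magna gadolinium
#'   injection: per-ROI percentage signal enhancement relative to
#'   non-injected baselines, SE = (S / Sb) * 100, followed by a
#'   repeated-measures two-way (condition x time) mixed-effects ANOVA with
#'   per-animal random intercepts and Bonferroni per-time post hocs, and a
#'   two-way condition x hemisphere ANOVA of lateral-ventricle volumes.
#' @name tracer_kinetics
NULL

#' Percentage signal enhancement
#'
#' @param S post-injection mean ROI intensity, >= 0.
#' @param Sb baseline (non-injected) mean ROI intensity, > 0.
#' @return 100 * S / Sb. Vectorised.
#' @export
signal_enhancement <- function(S, Sb) {
  if (any(!is.finite(Sb)) || any(Sb <= 0)) stop("Sb must be finite and > 0")
  if (any(!is.finite(S)) || any(S < 0)) stop("S must be finite and >= 0")
  100 * S / Sb
}

#' Baseline reference intensity per ROI
#'
#' Pools all baseline (non-injected) animals into one Sb per ROI by
#' default; `per_condition = TRUE` keeps condition-specific baselines
#' (usable only when every condition has baseline animals).
#'
#' @param baseline_scans data frame with columns `animal_id`, `roi`, `S`
#'   (and `condition` when `per_condition = TRUE`).
#' @param per_condition keep baselines separate per condition.
#' @return Data frame with `roi` (+ `condition` if requested), `Sb`,
#'   `n_baseline`.
#' @export
baseline_reference <- function(baseline_scans, per_condition = FALSE) {
  stopifnot(all(c("roi", "S") %in% names(baseline_scans)))
  if (nrow(baseline_scans) == 0) stop("baseline scan set is empty")
  if (any(!is.finite(baseline_scans$S)) || any(baseline_scans$S <= 0))
    stop("baseline intensities must be finite and > 0")
  by <- if (per_condition) c("roi", "condition") else "roi"
  out <- stats::aggregate(baseline_scans["S"], baseline_scans[by], mean)
  names(out)[names(out) == "S"] <- "Sb"
  out$n_baseline <- stats::aggregate(baseline_scans["S"], baseline_scans[by],
                                     length)$S
  out
}

#' Build the long SE(%) table
#'
#' Joins post-injection time courses with per-ROI baselines and computes
#' SE(%) per animal x ROI x time. Missing input samples simply yield absent
#' rows; nothing is imputed.
#'
#' @param timecourses data frame with `animal_id`, `condition`, `roi`,
#'   `time_min`, `S`.
#' @param baselines output of [baseline_reference()] (pooled mode).
#' @return Data frame with `animal_id`, `condition`, `roi`, `time_min`,
#'   `se_pct`.
#' @export
build_se_table <- function(timecourses, baselines) {
  req <- c("animal_id", "condition", "roi", "time_min", "S")
  stopifnot(all(req %in% names(timecourses)))
  absent <- setdiff(unique(timecourses$roi), baselines$roi)
  if (length(absent))
    stop("no baseline reference for ROI(s): ", paste(absent, collapse = ", "))
  sb <- stats::setNames(baselines$Sb, baselines$roi)
  out <- timecourses[req[-5]]
  out$se_pct <- signal_enhancement(timecourses$S, unname(sb[timecourses$roi]))
  rownames(out) <- NULL
  out
}

#' Repeated-measures condition x time mixed-model ANOVA for one ROI
#'
#' Fits `se_pct ~ condition * time + (1 | animal)` by REML on the available
#' rows (missing time points are simply absent; no imputation), tests the
#' condition, time, and interaction effects with Satterthwaite F tests, and
#' runs per-time condition contrasts with Bonferroni adjustment over the
#' number of time points.
#'
#' @param se_table output of [build_se_table()] (or any long table with
#'   `animal_id`, `condition`, `time_min`, and a response column).
#' @param roi ROI to analyze (ignored when the table has a single ROI and
#'   `roi` is NULL).
#' @param response name of the response column (default "se_pct").
#' @param posthoc compute the per-time Bonferroni contrasts (default TRUE;
#'   skip when only the omnibus tests are needed).
#' @return Object of class `rm_anova`: list with `effects` (data frame of
#'   F, df1, df2, p per effect), `posthoc` (per-time contrast estimates,
#'   raw and Bonferroni-adjusted p), `n_timepoints`, `model`.
#' @export
rm_anova_condition_time <- function(se_table, roi = NULL, response = "se_pct",
                                    posthoc = TRUE) {
  d <- as.data.frame(se_table)
  if (!is.null(roi)) d <- d[d$roi == roi, , drop = FALSE]
  stopifnot(all(c("animal_id", "condition", "time_min", response) %in% names(d)))
  d <- d[is.finite(d[[response]]), , drop = FALSE]
  present <- table(unique(d[c("animal_id", "condition")])$condition)
  if (any(present < 2) || length(present) < 2)
    stop("each of >= 2 conditions needs >= 2 animals")
  if (length(unique(d$time_min)) < 2) stop("need >= 2 time points")
  d$condition <- factor(d$condition)
  d$time_f <- factor(d$time_min)
  d$animal_id <- factor(d$animal_id)
  d$.y <- d[[response]]
  fit <- suppressMessages(lmerTest::lmer(
    .y ~ condition * time_f + (1 | animal_id), data = d,
    contrasts = list(condition = "contr.sum", time_f = "contr.sum")))
  av <- stats::anova(fit, type = 3)
  effects <- data.frame(
    effect = c("condition", "time", "interaction"),
    F = av[["F value"]], df1 = av[["NumDF"]], df2 = av[["DenDF"]],
    p = av[["Pr(>F)"]], row.names = NULL)
  nt <- nlevels(d$time_f)
  ph <- NULL
  if (posthoc) {
    # per-time condition contrasts, Bonferroni family = number of time points
    emm <- emmeans::emmeans(fit, ~ condition | time_f,
                            lmer.df = "satterthwaite")
    ctr <- summary(emmeans::contrast(emm, method = "pairwise"), by = NULL,
                   adjust = "none")
    ph <- data.frame(
      time_min = as.numeric(as.character(ctr$time_f)),
      contrast = as.character(ctr$contrast),
      estimate = ctr$estimate, se = ctr$SE, df = ctr$df,
      p = ctr$p.value,
      adj_p = pmin(1, ctr$p.value * nt))
  }
  structure(list(effects = effects, posthoc = ph,
                 n_timepoints = nt, model = fit),
            class = "rm_anova")
}

#' Two-way condition x hemisphere ANOVA of ventricle volumes
#'
#' Fixed-effects two-way ANOVA of lateral-ventricle volume on condition and
#' hemisphere (with interaction), with Bonferroni-adjusted per-hemisphere
#' condition contrasts. Animals missing one hemisphere are excluded with a
#' warning.
#'
#' @param volumes data frame with `animal_id`, `condition`, `hemisphere`
#'   ("left"/"right"), `volume_mm3` (> 0).
#' @return Object of class `rm_anova` with `effects` (condition,
#'   hemisphere, interaction) and `posthoc` (per-hemisphere contrasts).
#' @export
ventricle_anova <- function(volumes) {
  req <- c("animal_id", "condition", "hemisphere", "volume_mm3")
  stopifnot(all(req %in% names(volumes)))
  if (any(volumes$volume_mm3 <= 0)) stop("volumes must be > 0")
  nh <- tapply(volumes$hemisphere, volumes$animal_id,
               function(h) length(unique(h)))
  incomplete <- names(nh)[nh < 2]
  if (length(incomplete)) {
    warning("excluding animals with one hemisphere: ",
            paste(incomplete, collapse = ", "))
    volumes <- volumes[!volumes$animal_id %in% incomplete, , drop = FALSE]
  }
  d <- data.frame(y = volumes$volume_mm3,
                  condition = factor(volumes$condition),
                  hemisphere = factor(volumes$hemisphere),
                  animal_id = factor(volumes$animal_id))
  fit <- stats::aov(y ~ condition * hemisphere, data = d)
  av <- summary(fit)[[1]]
  effects <- data.frame(
    effect = c("condition", "hemisphere", "interaction"),
    F = av[["F value"]][1:3], df1 = av[["Df"]][1:3],
    df2 = av[["Df"]][4], p = av[["Pr(>F)"]][1:3], row.names = NULL)
  # an effect whose sum of squares is zero (to rounding) is a null
  # effect (F = 0), not an indeterminate 0/0
  total_ss <- sum(av[["Sum Sq"]])
  zero_ss <- av[["Sum Sq"]][1:3] <= 1e-10 * max(total_ss, 1)
  effects$F[zero_ss] <- 0
  effects$p[zero_ss] <- 1
  posthoc <- tryCatch({
    emm <- emmeans::emmeans(fit, ~ condition | hemisphere)
    ctr <- summary(emmeans::contrast(emm, method = "pairwise"), by = NULL,
                   adjust = "none")
    data.frame(
      hemisphere = as.character(ctr$hemisphere),
      contrast = as.character(ctr$contrast),
      estimate = ctr$estimate, se = ctr$SE, df = ctr$df, p = ctr$p.value,
      adj_p = pmin(1, ctr$p.value * nlevels(d$hemisphere)))
  }, error = function(e) {
    # perfect fits (zero residual variance) have no meaningful contrasts
    data.frame(hemisphere = character(0), contrast = character(0),
               estimate = numeric(0), se = numeric(0), df = numeric(0),
               p = numeric(0), adj_p = numeric(0))
  })
  structure(list(effects = effects, posthoc = posthoc,
                 n_timepoints = nlevels(d$hemisphere), model = fit),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way ANOVA\n")
  print(transform(x$effects, F = signif(F, 5), p = signif(p, 4)),
        row.names = FALSE)
  cat("Post hoc (Bonferroni x", x$n_timepoints, "):\n")
  print(utils::head(transform(x$posthoc, p = signif(p, 4),
                              adj_p = signif(adj_p, 4)), 12),
        row.names = FALSE)
  invisible(x)
}
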