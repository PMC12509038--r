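#' @title Disease activity index (DAI) scoring for DSS colitis
#' @description Composite colitis severity scoring from daily records of
#'   body mass, stool consistency, and fecal bleeding. The DAI is the mean
#'   of the three rubric scores:
#'   weight loss 0 (no loss), 1 ((0,5]%), 2 ((5,10]%), 3 ((10,20]%),
#'   4 (> 20%); stool 0 (normal), 2 (loose), 4 (diarrhea); bleeding
#'   0 (none), 1 (hemoccult positive), 2 (hemoccult + visible pellet
#'   blood), 4 (gross bleeding). The printed rubric boundaries overlap
#'   ("1%-5%", "5%-10%"); they are resolved as half-open intervals (a, b]
#'   so every percentage maps to exactly one score, and weight gain maps
#'   to 0.
#' @name colitis_scoring
NULL

STOOL_SCORES <- c(normal = 0, loose = 2, diarrhea = 4)
BLEEDING_SCORES <- c(none = 0, hemoccult_positive = 1,
                     hemoccult_and_visible = 2, gross = 4)

#' Percentage body-weight loss from baseline
#'
#' @param baseline_mass baseline body mass in grams (> 0).
#' @param current_mass current body mass in grams.
#' @return 100 * (baseline - current) / baseline; negative for weight gain.
#' @export
weight_loss_pct <- function(baseline_mass, current_mass) {
  if (any(!is.finite(baseline_mass)) || any(baseline_mass <= 0))
    stop("baseline_mass must be finite and > 0")
  100 * (baseline_mass - current_mass) / baseline_mass
}

#' Rubric score for body-weight loss
#'
#' @param pct weight loss percentage (negative = gain).
#' @return Integer score in {0, 1, 2, 3, 4}. Vectorised.
#' @export
score_weight_loss <- function(pct) {
  if (any(!is.finite(pct))) stop("pct must be finite")
  # half-open (a, b] bins resolve the overlapping printed boundaries
  findInterval(pct, c(0, 5, 10, 20), left.open = TRUE)
}

#' Rubric score for stool consistency
#'
#' @param category one of "normal", "loose", "diarrhea".
#' @return Score in {0, 2, 4}. Vectorised.
#' @export
score_stool <- function(category) {
  map_category(category, STOOL_SCORES, "stool")
}

#' Rubric score for fecal bleeding
#'
#' @param category one of "none", "hemoccult_positive",
#'   "hemoccult_and_visible", "gross".
#' @return Score in {0, 1, 2, 4}. Vectorised.
#' @export
score_bleeding <- function(category) {
  map_category(category, BLEEDING_SCORES, "bleeding")
}

map_category <- function(category, table, what) {
  category <- as.character(category)
  bad <- !(category %in% names(table))
  if (any(bad))
    stop(sprintf("unknown %s category '%s'; valid: %s", what,
                 category[bad][1], paste(names(table), collapse = ", ")))
  unname(table[category])
}

#' Composite disease activity index
#'
#' DAI = (weight loss score + stool score + bleeding score) / 3.
#'
#' @param weight_loss_score,stool_score,bleeding_score rubric scores from
#'   the corresponding scoring functions.
#' @return DAI in [0, 4]. Vectorised.
#' @export
dai <- function(weight_loss_score, stool_score, bleeding_score) {
  stopifnot(weight_loss_score %in% 0:4,
            stool_score %in% c(0, 2, 4),
            bleeding_score %in% c(0, 1, 2, 4))
  (weight_loss_score + stool_score + bleeding_score) / 3
}

#' Per-animal, per-day DAI time course
#'
#' Scores every observation against the animal's baseline mass (the mass on
#' its first recorded day) and returns one DAI record per animal x day.
#'
#' @param observations data frame with columns `animal_id`, `condition`,
#'   `day`, `body_mass_g`, `stool`, `bleeding`.
#' @return Data frame with `animal_id`, `condition`, `day`,
#'   `weight_loss_pct`, `weight_loss_score`, `stool_score`,
#'   `bleeding_score`, `dai`, ordered by animal then day.
#' @export
dai_timecourse <- function(observations) {
  req <- c("animal_id", "condition", "day", "body_mass_g", "stool", "bleeding")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols))
    stop("observations is missing columns: ", paste(missing_cols, collapse = ", "))
  obs <- observations[order(observations$animal_id, observations$day), , drop = FALSE]
  if (anyDuplicated(obs[c("animal_id", "day")]))
    stop("duplicate (animal_id, day) rows in observations")
  if (any(!is.finite(obs$body_mass_g)) || any(obs$body_mass_g <= 0)) {
    bad <- obs$animal_id[!is.finite(obs$body_mass_g) | obs$body_mass_g <= 0][1]
    stop("non-positive or missing body mass for animal ", bad)
  }
  baseline <- tapply(obs$body_mass_g, obs$animal_id, function(x) x[1])
  wl <- weight_loss_pct(unname(baseline[as.character(obs$animal_id)]),
                        obs$body_mass_g)
  ws <- score_weight_loss(wl)
  ss <- score_stool(obs$stool)
  bs <- score_bleeding(obs$bleeding)
  out <- data.frame(animal_id = obs$animal_id, condition = obs$condition,
                    day = obs$day, weight_loss_pct = wl,
                    weight_loss_score = ws, stool_score = ss,
                    bleeding_score = bs, dai = dai(ws, ss, bs),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Group mean and SEM of DAI per condition and day
#'
#' @param dai_records output of [dai_timecourse()].
#' @return Data frame with `condition`, `day`, `n`, `mean_dai`, `sem_dai`.
#' @export
dai_group_summary <- function(dai_records) {
  agg <- function(f) stats::aggregate(dai ~ condition + day, dai_records, f)
  out <- agg(mean)
  names(out)[3] <- "mean_dai"
  out$n <- agg(length)$dai
  out$sem_dai <- agg(stats::sd)$dai / sqrt(out$n)
  out[order(out$condition, out$day), c("condition", "day", "n", "mean_dai", "sem_dai")]
}
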