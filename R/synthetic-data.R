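#' @title Seeded synthetic-data generators
#' @description Generators for every input structure the pipeline consumes:
#'   replicated clock-gene expression series with cosinor periodicity,
#'   per-ROI tracer signal time courses with condition-dependent retention
#'   and dropout, four-fraction superfusion runs with a stimulated-fraction
#'   increment, a spiked proteins x samples intensity matrix with
#'   missingness and per-sample peptide-concentration factors, and daily
#'   colitis observations. Each generator is deterministic given its seed
#'   (sub-streams are derived per generator), restores the caller's RNG
#'   state, and respects the physical sign constraints of its quantity
#'   (expression >= 0, counts >= 0, intensities > 0).
#' @name synthetic_data
NULL

# run `expr` under a deterministic sub-stream without disturbing the
# caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.finite(seed)) stop("seed must be a finite integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

check_finite <- function(...) {
  vals <- c(...)
  if (any(!is.finite(unlist(vals)))) stop("non-finite generator parameter")
}

#' Generate replicated clock-gene expression series
#'
#' Each value is
#' mesor + trend_slope * (t - mean(times)) + amplitude * cos(2 pi (t -
#' phase_h) / period_h) + Normal(0, noise_sd), truncated at 0 (relative
#' expression cannot be negative).
#'
#' @param genes,conditions character labels.
#' @param times zeitgeber hours, strictly increasing in [0, 24) (default
#'   0,4,...,20).
#' @param n_rep animals per time point (default 3).
#' @param params optional data frame with one row per gene x condition and
#'   columns `gene`, `condition`, `mesor`, `amplitude`, `phase_h`,
#'   `period_h`, `trend_slope`, `noise_sd`; defaults below are recycled
#'   otherwise.
#' @param mesor,amplitude,phase_h,period_h,trend_slope,noise_sd scalar
#'   defaults used when `params` is NULL (amplitude must not exceed mesor,
#'   so the mean signal stays non-negative).
#' @param seed integer seed.
#' @return Data frame: `gene`, `condition`, `zt_h`, `rep`, `value`.
#' @export
gen_clock_series <- function(genes = "Bmal1", conditions = c("CTR", "DSS"),
                             times = seq(0, 20, by = 4), n_rep = 3,
                             params = NULL, mesor = 1, amplitude = 0.5,
                             phase_h = 8, period_h = 24, trend_slope = 0,
                             noise_sd = 0.1, seed = 1) {
  if (n_rep < 1) stop("n_rep must be >= 1")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(params)) {
    params <- expand.grid(gene = genes, condition = conditions,
                          stringsAsFactors = FALSE)
    params$mesor <- mesor; params$amplitude <- amplitude
    params$phase_h <- phase_h; params$period_h <- period_h
    params$trend_slope <- trend_slope; params$noise_sd <- noise_sd
  }
  check_finite(params$mesor, params$amplitude, params$phase_h,
               params$period_h, params$trend_slope, params$noise_sd, times)
  if (any(params$noise_sd < 0)) stop("noise_sd must be >= 0")
  if (any(params$amplitude < 0)) stop("amplitude must be >= 0")
  if (any(params$amplitude > params$mesor))
    stop("amplitude must not exceed mesor (non-negative mean signal)")
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      grid <- expand.grid(zt_h = times, rep = seq_len(n_rep))
      mu <- p$mesor + p$trend_slope * (grid$zt_h - mean(times)) +
        p$amplitude * cos(2 * pi * (grid$zt_h - p$phase_h) / p$period_h)
      data.frame(gene = p$gene, condition = p$condition,
                 zt_h = grid$zt_h, rep = grid$rep,
                 value = pmax(0, mu + stats::rnorm(nrow(grid), 0, p$noise_sd)))
    }))
    rownames(out) <- NULL
    out
  })
}

# gamma-variate uptake/washout response normalized to unit peak
gamma_variate <- function(t, t0 = 0, shape = 2, scale = 15) {
  tt <- pmax(0, t - t0)
  peak_t <- shape * scale
  g <- (tt / peak_t)^shape * exp(shape * (1 - tt / peak_t))
  g[tt == 0] <- 0
  g
}

#' Generate tracer signal-enhancement time courses
#'
#' Post-injection signal S(t) = Sb * (1 + E * g(t)) * (1 + delta) where g
#' is a gamma-variate uptake/washout curve normalized to unit peak (so the
#' condition's `enhancement_scale` E is its peak fractional enhancement)
#' and delta ~ Normal(0, noise_cv). Per-animal x time dropout produces
#' missing rows. Baseline animals are drawn around Sb with the same CV.
#'
#' @param rois character ROI labels.
#' @param conditions character condition labels.
#' @param n_animals animals per condition.
#' @param times_min post-injection minutes (default 25, 31, ..., 79: ten
#'   points every 6 minutes).
#' @param baseline_mean named per-ROI baseline intensity Sb (> 0), recycled
#'   from a scalar.
#' @param enhancement_scale named per-condition peak fractional enhancement
#'   E (>= 0), recycled from a scalar.
#' @param shape,scale,t0 gamma-variate parameters (minutes); default peak
#'   at t0 + shape*scale = 30 min.
#' @param dropout_prob per animal x time missingness probability in [0, 1).
#' @param noise_cv multiplicative coefficient of variation (>= 0).
#' @param n_baseline baseline animals per condition (default 2).
#' @param seed integer seed.
#' @return List with `scans` (animal_id, condition, roi, time_min, S) and
#'   `baselines` (animal_id, condition, roi, S).
#' @export
gen_tracer_timecourses <- function(rois = c("hippocampus", "amygdala"),
                                   conditions = c("CTR", "DSS"),
                                   n_animals = 6,
                                   times_min = seq(25, 79, by = 6),
                                   baseline_mean = 100,
                                   enhancement_scale = c(CTR = 0.6, DSS = 1.0),
                                   shape = 2, scale = 15, t0 = 0,
                                   dropout_prob = 0.05, noise_cv = 0.05,
                                   n_baseline = 2, seed = 1) {
  if (any(enhancement_scale < 0)) stop("enhancement_scale must be >= 0")
  if (any(baseline_mean <= 0)) stop("baseline_mean (Sb) must be > 0")
  if (dropout_prob < 0 || dropout_prob >= 1) stop("dropout_prob must be in [0, 1)")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  Sb <- if (is.null(names(baseline_mean)))
    stats::setNames(rep_len(baseline_mean, length(rois)), rois)
    else baseline_mean[rois]
  E <- if (is.null(names(enhancement_scale)))
    stats::setNames(rep_len(enhancement_scale, length(conditions)), conditions)
    else enhancement_scale[conditions]
  check_finite(Sb, E, times_min, shape, scale, t0)
  g <- gamma_variate(times_min, t0, shape, scale)
  with_seed(seed + 1L, {
    scans <- do.call(rbind, lapply(conditions, function(cc) {
      do.call(rbind, lapply(seq_len(n_animals), function(a) {
        id <- sprintf("%s_%02d", cc, a)
        keep <- stats::runif(length(times_min)) >= dropout_prob
        do.call(rbind, lapply(rois, function(r) {
          mu <- Sb[r] * (1 + E[cc] * g)
          S <- mu * (1 + stats::rnorm(length(times_min), 0, noise_cv))
          data.frame(animal_id = id, condition = cc, roi = r,
                     time_min = times_min, S = pmax(S, 1e-6))[keep, ]
        }))
      }))
    }))
    baselines <- do.call(rbind, lapply(conditions, function(cc) {
      do.call(rbind, lapply(seq_len(n_baseline), function(a) {
        data.frame(animal_id = sprintf("%s_base_%02d", cc, a), condition = cc,
                   roi = rois,
                   S = pmax(Sb[rois] *
                              (1 + stats::rnorm(length(rois), 0, noise_cv)),
                            1e-6))
      }))
    }))
    rownames(scans) <- rownames(baselines) <- NULL
    list(scans = scans, baselines = baselines)
  })
}

#' Generate four-fraction superfusion runs
#'
#' Each run has four basal fraction percentages `basal_frac_pct` with the
#' condition's `evoked_increment_pct` added to fractions 2 and 3 and
#' Gaussian noise on every fraction; counts are pct/100 * total_counts and
#' the residual carries the remaining radioactivity.
#'
#' @param n_runs runs per condition.
#' @param conditions character labels.
#' @param basal_frac_pct basal release per fraction, percent of total (> 0).
#' @param evoked_increment_pct named per-condition increment (>= 0) added
#'   to the two stimulated fractions, recycled from a scalar.
#' @param noise_sd_pct Gaussian fraction noise (percent points, >= 0).
#' @param total_counts total radioactivity per run (dpm).
#' @param region,particle_type,tracer annotation labels carried through.
#' @param seed integer seed.
#' @return Data frame: `run_id`, `condition`, `region`, `particle_type`,
#'   `tracer`, `f1`..`f4`, `residual`.
#' @export
gen_superfusion_runs <- function(n_runs = 6, conditions = c("CTR", "DSS"),
                                 basal_frac_pct = 2,
                                 evoked_increment_pct = c(CTR = 3, DSS = 1.5),
                                 noise_sd_pct = 0.3, total_counts = 2e5,
                                 region = "hippocampus",
                                 particle_type = "synaptosome",
                                 tracer = "D-ASP", seed = 1) {
  if (basal_frac_pct <= 0) stop("basal_frac_pct must be > 0")
  if (any(evoked_increment_pct < 0)) stop("evoked_increment_pct must be >= 0")
  if (noise_sd_pct < 0) stop("noise_sd_pct must be >= 0")
  incr <- if (is.null(names(evoked_increment_pct)))
    stats::setNames(rep_len(evoked_increment_pct, length(conditions)), conditions)
    else evoked_increment_pct[conditions]
  check_finite(basal_frac_pct, incr, noise_sd_pct, total_counts)
  with_seed(seed + 2L, {
    out <- do.call(rbind, lapply(conditions, function(cc) {
      do.call(rbind, lapply(seq_len(n_runs), function(i) {
        pct <- rep(basal_frac_pct, 4) + c(0, incr[cc], incr[cc], 0) +
          stats::rnorm(4, 0, noise_sd_pct)
        pct <- pmax(pct, 0)
        if (sum(pct) >= 100) stop("fraction percentages exceed 100; lower basal/increment")
        counts <- pct / 100 * total_counts
        data.frame(run_id = sprintf("%s_run%02d", cc, i), condition = cc,
                   region = region, particle_type = particle_type,
                   tracer = tracer,
                   f1 = counts[1], f2 = counts[2], f3 = counts[3],
                   f4 = counts[4],
                   residual = total_counts - sum(counts))
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a spiked label-free proteome matrix
#'
#' Log2 intensities are Normal(`base_log2_mean`, `base_log2_sd`) per
#' protein with Normal(0, `noise_sd`) sample scatter; the first `n_spiked`
#' proteins get a true log2 fold change (magnitude drawn uniformly in
#' `spike_lfc_range`, random sign) added in the treated group. Raw-scale
#' intensities are multiplied by each sample's peptide-concentration factor
#' and entries are removed at `missing_prob`.
#'
#' @param n_proteins total proteins (default 600).
#' @param n_per_group samples per group (default 8, as in an 8 vs 8
#'   CSF cohort).
#' @param n_spiked number of truly differential proteins.
#' @param spike_lfc_range magnitude range of true |log2FC| (all above 1 by
#'   default so spiked proteins are callable).
#' @param base_log2_mean,base_log2_sd protein-level log2 abundance
#'   distribution.
#' @param noise_sd within-protein sample scatter (log2 units).
#' @param missing_prob per-cell missingness in [0, 1).
#' @param peptide_conc per-sample concentrations (> 0), recycled from a
#'   scalar; mild lognormal variation by default.
#' @param seed integer seed.
#' @return List with `matrix` (raw intensities, NA = missing), `groups`
#'   (factor control/treated), `peptide_conc`, and `truth` (protein,
#'   true_log2fc).
#' @export
gen_proteome <- function(n_proteins = 600, n_per_group = 8, n_spiked = 30,
                         spike_lfc_range = c(1.2, 3), base_log2_mean = 20,
                         base_log2_sd = 2, noise_sd = 0.4,
                         missing_prob = 0.05, peptide_conc = NULL, seed = 1) {
  if (n_spiked > n_proteins) stop("n_spiked must be <= n_proteins")
  if (missing_prob < 0 || missing_prob >= 1) stop("missing_prob must be in [0, 1)")
  n <- 2 * n_per_group
  with_seed(seed + 3L, {
    if (is.null(peptide_conc)) peptide_conc <- exp(stats::rnorm(n, 0, 0.15))
    if (any(peptide_conc <= 0)) stop("peptide_conc must be > 0")
    peptide_conc <- rep_len(peptide_conc, n)
    groups <- factor(rep(c("control", "treated"), each = n_per_group))
    proteins <- sprintf("P%04d", seq_len(n_proteins))
    true_lfc <- numeric(n_proteins)
    if (n_spiked > 0)
      true_lfc[seq_len(n_spiked)] <-
        sample(c(-1, 1), n_spiked, replace = TRUE) *
        stats::runif(n_spiked, spike_lfc_range[1], spike_lfc_range[2])
    base <- stats::rnorm(n_proteins, base_log2_mean, base_log2_sd)
    lmat <- base + matrix(stats::rnorm(n_proteins * n, 0, noise_sd),
                          n_proteins, n)
    lmat[, groups == "treated"] <- lmat[, groups == "treated"] + true_lfc
    mat <- 2^lmat
    mat <- sweep(mat, 2, peptide_conc / mean(peptide_conc), "*")
    if (missing_prob > 0)
      mat[matrix(stats::runif(length(mat)) < missing_prob,
                 n_proteins, n)] <- NA
    dimnames(mat) <- list(proteins,
                          sprintf("%s_%02d", as.character(groups),
                                  c(seq_len(n_per_group), seq_len(n_per_group))))
    names(peptide_conc) <- colnames(mat)
    list(matrix = mat, groups = groups, peptide_conc = peptide_conc,
         truth = data.frame(protein = proteins, true_log2fc = true_lfc))
  })
}

#' Generate daily colitis observations
#'
#' Per animal and day: body mass follows a condition-specific deterministic
#' daily percent drift plus Gaussian noise, and stool/bleeding categories
#' are drawn from condition-specific probability vectors.
#'
#' @param n_animals animals per condition.
#' @param days number of recorded days (day 0 = baseline).
#' @param conditions character labels.
#' @param weight_drift_pct named per-condition daily percent change of body
#'   mass (negative = loss), recycled from a scalar.
#' @param stool_probs,bleeding_probs named list per condition of
#'   probability vectors over the stool categories (normal, loose,
#'   diarrhea) and bleeding categories (none, hemoccult_positive,
#'   hemoccult_and_visible, gross); each must sum to 1.
#' @param baseline_mass_g mean starting mass (grams).
#' @param mass_noise_sd_g daily mass measurement noise (grams).
#' @param seed integer seed.
#' @return Data frame: `animal_id`, `condition`, `day`, `body_mass_g`,
#'   `stool`, `bleeding`.
#' @export
gen_dai_observations <- function(n_animals = 8, days = 8,
                                 conditions = c("CTR", "DSS"),
                                 weight_drift_pct = c(CTR = 0.2, DSS = -2.5),
                                 stool_probs = list(
                                   CTR = c(normal = 1, loose = 0, diarrhea = 0),
                                   DSS = c(normal = 0.3, loose = 0.4, diarrhea = 0.3)),
                                 bleeding_probs = list(
                                   CTR = c(none = 1, hemoccult_positive = 0,
                                           hemoccult_and_visible = 0, gross = 0),
                                   DSS = c(none = 0.3, hemoccult_positive = 0.3,
                                           hemoccult_and_visible = 0.2, gross = 0.2)),
                                 baseline_mass_g = 22, mass_noise_sd_g = 0.1,
                                 seed = 1) {
  drift <- if (is.null(names(weight_drift_pct)))
    stats::setNames(rep_len(weight_drift_pct, length(conditions)), conditions)
    else weight_drift_pct[conditions]
  for (cc in conditions) {
    if (abs(sum(stool_probs[[cc]]) - 1) > 1e-8 ||
        abs(sum(bleeding_probs[[cc]]) - 1) > 1e-8)
      stop("category probabilities must sum to 1 for condition ", cc)
  }
  with_seed(seed + 4L, {
    out <- do.call(rbind, lapply(conditions, function(cc) {
      do.call(rbind, lapply(seq_len(n_animals), function(a) {
        m0 <- baseline_mass_g + stats::rnorm(1, 0, 0.5)
        mass <- m0 * (1 + drift[cc] / 100)^(0:(days - 1)) +
          stats::rnorm(days, 0, mass_noise_sd_g)
        data.frame(
          animal_id = sprintf("%s_%02d", cc, a), condition = cc,
          day = 0:(days - 1), body_mass_g = pmax(mass, 1),
          stool = sample(names(stool_probs[[cc]]), days, replace = TRUE,
                         prob = stool_probs[[cc]]),
          bleeding = sample(names(bleeding_probs[[cc]]), days, replace = TRUE,
                            prob = bleeding_probs[[cc]]))
      }))
    }))
    rownames(out) <- NULL
    out
  })
}
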