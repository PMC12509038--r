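test_that("peptide-concentration normalization rescales samples, preserving missingness", {
  m <- matrix(c(10, 20, 30, 40, 50, 60), nrow = 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  # equal concentrations: unchanged
  expect_equal(normalize_matrix(m, c(s1 = 2, s2 = 2, s3 = 2)), m)
  # one sample at twice the concentration is halved relative to the others
  norm <- normalize_matrix(m, c(s1 = 1, s2 = 2, s3 = 1))
  expect_equal(norm[, "s2"] / norm[, "s1"], (m[, "s2"] / 2) / m[, "s1"])
  m[1, 2] <- NA
  expect_true(is.na(normalize_matrix(m, c(s1 = 1, s2 = 2, s3 = 1))[1, 2]))
  expect_error(normalize_matrix(m, c(1, 0, 1)), "> 0")
})

test_that("normalization equalizes column loadings on generated data", {
  sim <- gen_proteome(n_proteins = 300, n_spiked = 0, missing_prob = 0,
                      noise_sd = 0.2, seed = 31)
  norm <- normalize_matrix(sim$matrix, sim$peptide_conc)
  med_raw <- apply(log2(sim$matrix), 2, median)
  med_norm <- apply(log2(norm), 2, median)
  expect_lt(sd(med_norm), sd(med_raw))
  expect_lt(diff(range(med_norm)), 0.35)
})

test_that("quantification filter keeps proteins observed enough in each group", {
  m <- matrix(rnorm(5 * 6, 20), 5, 6,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:6)))
  g <- rep(c("control", "treated"), each = 3)
  expect_equal(nrow(quantification_filter(m, g)$matrix), 5)  # nothing removed
  m[1, 1:2] <- NA          # p1: only 1 control value -> removed
  m[2, 4] <- NA            # p2: 2 treated values -> kept
  f <- quantification_filter(m, g, min_per_group = 2)
  expect_false("p1" %in% rownames(f$matrix))
  expect_true("p2" %in% rownames(f$matrix))
  expect_equal(f$report$n_identified, 5)
  expect_equal(f$report$n_quantified + f$report$n_removed, 5)
  expect_error(quantification_filter(m, g, min_per_group = 1), ">= 2")
})

test_that("differential test matches the pooled-variance t oracle on a printed fixture", {
  lmat <- rbind(x = c(10, 10.2, 9.8, 12, 12.1, 11.9))
  colnames(lmat) <- paste0("s", 1:6)
  g <- rep(c("control", "treated"), each = 3)
  res <- differential_test(lmat, g, log_transformed = TRUE)
  expect_equal(res$log2fc, 2)
  orc <- oracle_student_t(c(12, 12.1, 11.9), c(10, 10.2, 9.8))
  expect_equal(res$p, orc$p)
})

test_that("differential results obey antisymmetry, BH monotonicity, and the strict filter", {
  sim <- gen_proteome(n_proteins = 120, n_spiked = 15, seed = 41)
  filt <- quantification_filter(normalize_matrix(sim$matrix, sim$peptide_conc),
                                sim$groups)
  res <- differential_test(filt$matrix, sim$groups)
  expect_true(all(res$adj_p >= res$p))
  expect_true(all(res$adj_p <= 1))
  o <- order(res$p)
  expect_true(all(diff(res$adj_p[o]) >= -1e-12))
  # group swap negates log2fc, preserves p
  swapped <- differential_test(filt$matrix, sim$groups,
                               treated_level = "control")
  expect_equal(swapped$log2fc, -res$log2fc)
  expect_equal(swapped$p, res$p)
  # identical groups: all log2fc = 0
  dup <- cbind(filt$matrix[, 1:4], filt$matrix[, 1:4])
  colnames(dup) <- paste0("s", 1:8)
  same <- differential_test(dup, rep(c("control", "treated"), each = 4))
  expect_equal(same$log2fc, rep(0, nrow(dup)))
  # strict boundary: |log2fc| exactly 1 is excluded
  fake <- res
  fake$log2fc <- 1.0
  fake$adj_p <- 0.001
  expect_equal(nrow(significance_filter(fake)), 0)
  fake$log2fc <- -1.5
  expect_equal(nrow(significance_filter(fake)), nrow(fake))
  expect_equal(significance_filter(res),
               res[res$significant, , drop = FALSE])
})

test_that("volcano table is consistent with the filter and preserves rows", {
  sim <- gen_proteome(n_proteins = 80, n_spiked = 10, seed = 51)
  filt <- quantification_filter(normalize_matrix(sim$matrix, sim$peptide_conc),
                                sim$groups)
  res <- differential_test(filt$matrix, sim$groups)
  v <- volcano_table(res)
  expect_equal(nrow(v), nrow(res))
  expect_equal(sort(v$protein[v$significant]),
               sort(significance_filter(res)$protein))
  expect_true(!is.unsorted(-v$neg_log10_adj_p))
  all1 <- res; all1$adj_p <- 1
  expect_equal(volcano_table(all1)$neg_log10_adj_p, rep(0, nrow(res)))
})

test_that("null generated matrix yields approximately uniform raw p values", {
  sim <- gen_proteome(n_proteins = 600, n_spiked = 0, missing_prob = 0,
                      seed = 1)
  res <- differential_test(normalize_matrix(sim$matrix, sim$peptide_conc),
                           sim$groups)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("spiked log2FC is recovered within sampling error", {
  sim <- gen_proteome(n_proteins = 50, n_spiked = 5,
                      spike_lfc_range = c(3, 3), noise_sd = 0.2,
                      missing_prob = 0, seed = 71)
  res <- differential_test(sim$matrix, sim$groups)
  spiked <- merge(res, sim$truth[sim$truth$true_log2fc != 0, ], by = "protein")
  expect_true(all(abs(spiked$log2fc - spiked$true_log2fc) < 0.5))
})

test_that("Fisher enrichment matches exhaustive hypergeometric enumeration", {
  universe <- paste0("g", 1:40)
  query <- paste0("g", 1:8)
  sets <- list(hit = paste0("g", c(1:5, 30:34)),     # overlap 5
               cold = paste0("g", 35:40),            # disjoint from query
               exact = query)
  enr <- fisher_enrichment(query, universe, sets)
  enr <- enr[order(enr$term), ]
  orc <- vapply(sets[sort(names(sets))], function(s) {
    term <- intersect(s, universe)
    oracle_hyper_tail(length(intersect(term, query)), length(term),
                      length(query), length(universe))
  }, numeric(1))
  expect_equal(enr$p, unname(orc), tolerance = 1e-12)
  expect_equal(enr$odds_ratio[enr$term == "cold"], 0)
  expect_equal(enr$p[enr$term == "cold"], 1)
  expect_equal(enr$adj_p, bh_adjust(enr$p)) # BH across terms
  # growing the universe with irrelevant proteins makes a fixed overlap rarer
  enr_big <- fisher_enrichment(query, c(universe, paste0("x", 1:60)), sets)
  expect_lt(enr_big$p[enr_big$term == "hit"], enr$p[enr$term == "hit"])
  expect_error(fisher_enrichment(query, character(0), sets), "empty|subset")
  expect_error(fisher_enrichment(c(query, "zz"), universe, sets), "subset")
})

test_that("GMT round-trip preserves term membership", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("term1\tdesc\tg1\tg2\tg3", "term2\tdesc\tg9"), path)
  sets <- read_gmt(path)
  expect_equal(sets, list(term1 = c("g1", "g2", "g3"), term2 = "g9"))
})
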