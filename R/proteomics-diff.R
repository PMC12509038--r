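#' @title Label-free CSF proteomics differential analysis
#' @description Peptide-concentration normalization of a proteins x samples
#'   intensity matrix, a quantification filter on per-group non-missing
#'   counts, per-protein two-sample t tests on log2 intensities with
#'   Benjamini-Hochberg FDR, the |log2FC| > 1 & adjusted p < 0.05
#'   significance filter, volcano tables, and offline Fisher exact
#'   enrichment against user-supplied gene sets.
#' @name proteomics_diff
NULL

#' Peptide-concentration normalization
#'
#' Divides each sample's intensities by its peptide concentration and
#' rescales by the mean concentration so overall intensity scale is
#' preserved. Missing values stay missing.
#'
#' @param matrix numeric proteins x samples matrix (rownames = proteins,
#'   colnames = samples); NA = not quantified.
#' @param peptide_conc named (or column-ordered) positive concentrations,
#'   one per sample.
#' @return Normalized matrix of the same shape.
#' @export
normalize_matrix <- function(matrix, peptide_conc) {
  if (length(peptide_conc) != ncol(matrix))
    stop("one peptide concentration per sample is required")
  if (any(!is.finite(peptide_conc)) || any(peptide_conc <= 0))
    stop("peptide concentrations must be finite and > 0")
  if (!is.null(names(peptide_conc)) && !is.null(colnames(matrix)))
    peptide_conc <- peptide_conc[colnames(matrix)]
  sweep(matrix, 2, peptide_conc / mean(peptide_conc), "/")
}

#' Quantification filter
#'
#' Keeps proteins quantified (non-missing) in at least `min_per_group`
#' samples of EACH group.
#'
#' @param matrix proteins x samples matrix with NA for missing.
#' @param groups factor/character of length ncol(matrix) with two levels.
#' @param min_per_group minimum non-missing values per group (>= 2).
#' @return List with `matrix` (kept rows), `report` (data frame:
#'   n_identified, n_quantified, n_removed).
#' @export
quantification_filter <- function(matrix, groups, min_per_group = 2) {
  if (min_per_group < 2) stop("min_per_group must be >= 2")
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(matrix), nlevels(groups) == 2)
  ok <- vapply(levels(groups), function(g) {
    rowSums(!is.na(matrix[, groups == g, drop = FALSE])) >= min_per_group
  }, logical(nrow(matrix)))
  keep <- rowSums(ok) == 2
  list(matrix = matrix[keep, , drop = FALSE],
       report = data.frame(n_identified = nrow(matrix),
                           n_quantified = sum(keep),
                           n_removed = sum(!keep)))
}

#' Per-protein differential test
#'
#' For each protein: log2 fold change = mean log2(treated) - mean
#' log2(control) over non-missing values, a two-sided two-sample t test on
#' the log2 intensities (Student pooled-variance by default, Welch
#' optional), and Benjamini-Hochberg adjustment across all tested proteins.
#' Intensities must be positive where present (raw scale); set
#' `log_transformed = TRUE` if the matrix is already on log2 scale.
#'
#' @param matrix proteins x samples intensity matrix (filter first with
#'   [quantification_filter()]).
#' @param groups two-level factor; the "treated" level is `treated_level`.
#' @param treated_level label of the treated group (default "treated", or
#'   the second factor level if absent).
#' @param welch use Welch's t instead of Student's.
#' @param log_transformed matrix already log2.
#' @return Data frame (`diff_result`): `protein`, `log2fc`, `p`, `adj_p`,
#'   `n_control`, `n_treated`, `significant` (|log2fc| > 1 and adj_p <
#'   0.05), `flag`.
#' @export
differential_test <- function(matrix, groups, treated_level = NULL,
                              welch = FALSE, log_transformed = FALSE) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(matrix), nlevels(groups) == 2)
  if (is.null(treated_level))
    treated_level <- if ("treated" %in% levels(groups)) "treated"
      else levels(groups)[2]
  if (!treated_level %in% levels(groups))
    stop("treated_level not among group labels")
  control_level <- setdiff(levels(groups), treated_level)
  lmat <- if (log_transformed) matrix else {
    if (any(matrix <= 0, na.rm = TRUE))
      stop("raw intensities must be > 0 where present")
    log2(matrix)
  }
  tr <- lmat[, groups == treated_level, drop = FALSE]
  ct <- lmat[, groups == control_level, drop = FALSE]
  res <- lapply(seq_len(nrow(lmat)), function(i) {
    x <- tr[i, ][!is.na(tr[i, ])]
    y <- ct[i, ][!is.na(ct[i, ])]
    lfc <- mean(x) - mean(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # no within-group variance: equal means -> p = 1 by convention
      p <- if (lfc == 0) 1 else 0
      flag <- "zero_variance"
    } else {
      p <- stats::t.test(x, y, var.equal = !welch)$p.value
      flag <- NA_character_
    }
    data.frame(log2fc = lfc, p = p, n_control = length(y),
               n_treated = length(x), flag = flag)
  })
  out <- do.call(rbind, res)
  out <- cbind(protein = rownames(lmat), out)
  out$adj_p <- bh_adjust(out$p)
  out$significant <- abs(out$log2fc) > 1 & out$adj_p < 0.05
  rownames(out) <- NULL
  out[c("protein", "log2fc", "p", "adj_p", "n_control", "n_treated",
        "significant", "flag")]
}

#' Significance filter: |log2FC| > 1 and adjusted p < 0.05
#'
#' Both inequalities are strict, as in the published criterion: a protein
#' with log2FC exactly 1.0 is not called.
#'
#' @param results output of [differential_test()].
#' @return The significant subset.
#' @export
significance_filter <- function(results) {
  stopifnot(all(c("log2fc", "adj_p") %in% names(results)))
  results[abs(results$log2fc) > 1 & results$adj_p < 0.05, , drop = FALSE]
}

#' Volcano-plot table
#'
#' @param results output of [differential_test()].
#' @return Data frame (`protein`, `log2fc`, `neg_log10_adj_p`,
#'   `significant`) sorted by adjusted p ascending; row count preserved.
#' @export
volcano_table <- function(results) {
  out <- data.frame(protein = results$protein, log2fc = results$log2fc,
                    neg_log10_adj_p = -log10(results$adj_p),
                    significant = abs(results$log2fc) > 1 & results$adj_p < 0.05)
  out[order(results$adj_p), , drop = FALSE]
}

#' Offline Fisher exact gene-set enrichment
#'
#' One-sided (over-representation) Fisher exact test of each term's overlap
#' with the query set against the universe, BH-adjusted across terms. The
#' odds ratio is the sample odds ratio of the 2x2 table. Gene sets are
#' intersected with the universe before testing.
#'
#' @param query character vector of significant proteins (subset of
#'   `universe`).
#' @param universe character vector of all quantified proteins.
#' @param gene_sets named list of character vectors (term -> members), e.g.
#'   from [read_gmt()].
#' @return Data frame: `term`, `overlap`, `term_size`, `query_size`,
#'   `universe_size`, `odds_ratio`, `p`, `adj_p`.
#' @export
fisher_enrichment <- function(query, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe is empty")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  rows <- lapply(names(gene_sets), function(tm) {
    term <- intersect(unique(gene_sets[[tm]]), universe)
    a <- length(intersect(term, query))                 # in term & in query
    b <- length(setdiff(query, term))                   # in query only
    c_ <- length(setdiff(term, query))                  # in term only
    d <- length(universe) - a - b - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    oddsr <- if (b == 0 || c_ == 0) {
      if (a == 0) 0 else Inf
    } else (a * d) / (b * c_)
    data.frame(term = tm, overlap = a, term_size = length(term),
               query_size = length(query), universe_size = length(universe),
               odds_ratio = oddsr, p = p)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated GMT: term, description, members...
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
  sets
}
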