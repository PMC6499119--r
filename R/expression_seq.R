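## Sex-specific / sex-biased expression calling from sequencing read counts.

#' Default analysis thresholds
#'
#' Sequencing side: minimum pooled count 10, |log2FC| >= 1.5, P <= 0.01,
#' BH-adjusted P <= 0.05, and the high-expression windows 50-4646 (ovary) /
#' 50-8177 (testis) used for probe selection. Array side: replicate CV < 0.3,
#' |log2FC| >= 1, P <= 0.05, co-expression median > 1 on the normalized
#' intensity scale.
#'
#' @return Nested list with `seq` and `array` threshold sets.
#' @export
thresholds_config <- function() {
  list(seq = list(min_count = 10, lfc = 1.5, p = 0.01, padj = 0.05,
                  high_expr_ovary = c(50, 4646), high_expr_testis = c(50, 8177)),
       array = list(cv = 0.3, lfc = 1.0, p = 0.05, coexpr_median = 1.0))
}

#' Sex-specificity category from pooled counts
#'
#' `ovary_specific` means no testis reads at all and at least `min_count`
#' ovary reads (symmetrically for testis); detection in both sexes is
#' `shared`; anything else (including one-sex detection below the floor) is
#' `low_count`.
#'
#' @param ovary,testis Pooled (per-sex summed) read counts, vectorised.
#' @param min_count Count floor for a specific call (default 10).
#' @return Character vector of categories.
#' @export
classify_sex_specificity <- function(ovary, testis, min_count = 10) {
  if (any(ovary < 0) || any(testis < 0))
    stop("classify_sex_specificity(): negative counts")
  ifelse(testis == 0 & ovary >= min_count, "ovary_specific",
  ifelse(ovary == 0 & testis >= min_count, "testis_specific",
  ifelse(ovary > 0 & testis > 0, "shared", "low_count")))
}

#' log2 fold change of pooled, library-size-normalised counts
#'
#' Counts are scaled to the mean per-sex pooled library size and a
#' pseudocount is added to both sexes before taking log2(ovary / testis).
#'
#' @param ovary,testis Pooled counts (vectorised).
#' @param ovary_libsize,testis_libsize Per-sex pooled library sizes (> 0).
#' @param pseudocount Added to both normalised counts (default 0.5).
#' @return Numeric log2 fold changes (positive = ovary-up).
#' @export
seq_logfc <- function(ovary, testis, ovary_libsize, testis_libsize,
                      pseudocount = 0.5) {
  if (ovary_libsize <= 0 || testis_libsize <= 0)
    stop("seq_logfc(): library sizes must be positive")
  scale <- mean(c(ovary_libsize, testis_libsize))
  no <- ovary / ovary_libsize * scale
  nt <- testis / testis_libsize * scale
  log2((no + pseudocount) / (nt + pseudocount))
}

#' Two-sided Fisher's exact test on a 2x2 count table
#'
#' Direct hypergeometric enumeration: the two-sided P is the sum of the
#' probabilities of all tables (at fixed margins) no more likely than the
#' observed one (with the customary 1e-7 relative slack on the comparison).
#'
#' @param a,b,c,d Cells of the table `[[a, c], [b, d]]` — e.g. a = piRNA
#'   reads in ovary, b = remaining ovary reads, c = piRNA reads in testis,
#'   d = remaining testis reads.
#' @return Two-sided P value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("fisher_exact_2x2(): negative cell")
  m <- a + b            # ovary margin
  n_ <- c + d           # testis margin
  k <- a + c            # feature margin
  if (m + n_ == 0) return(1)
  support <- max(0, k - n_):min(k, m)
  dens <- stats::dhyper(support, m, n_, k)
  d_obs <- stats::dhyper(a, m, n_, k)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Differential-expression test for pooled sequencing counts
#'
#' Per piRNA, a two-sided Fisher's exact test on the 2x2 table
#' [piRNA count, library remainder] x [ovary, testis], with
#' Benjamini-Hochberg correction across all tested piRNAs.
#'
#' @param ovary,testis Pooled per-sex counts (vectors).
#' @param ovary_total,testis_total Per-sex pooled library sizes.
#' @return Data frame with `p` and `padj`.
#' @export
seq_de_test <- function(ovary, testis, ovary_total, testis_total) {
  if (ovary_total <= 0 || testis_total <= 0)
    stop("seq_de_test(): zero library totals")
  if (any(ovary > ovary_total) || any(testis > testis_total))
    stop("seq_de_test(): count exceeds library total")
  p <- vapply(seq_along(ovary), function(i)
    fisher_exact_2x2(ovary[i], ovary_total - ovary[i],
                     testis[i], testis_total - testis[i]),
    numeric(1))
  data.frame(p = p, padj = stats::p.adjust(p, method = "BH"))
}

#' Build the sequencing expression table for predicted piRNAs
#'
#' Pools the two libraries of each sex, classifies sex specificity, computes
#' log2FC and the Fisher/BH differential test.
#'
#' @param reads Unique-read table rows for the predicted piRNAs (sequence +
#'   per-library counts).
#' @param libraries Data frame with `library` and `sex` columns matching the
#'   count columns of `reads`.
#' @param thresholds A [thresholds_config()] list.
#' @return Data frame: `sequence`, `ovary_pool`, `testis_pool`, `category`,
#'   `log2fc`, `p`, `padj`.
#' @export
seq_expression_table <- function(reads, libraries,
                                 thresholds = thresholds_config()) {
  ov_cols <- libraries$library[libraries$sex == "ovary"]
  te_cols <- libraries$library[libraries$sex == "testis"]
  ov <- unname(rowSums(as.matrix(reads[, ov_cols, drop = FALSE])))
  te <- unname(rowSums(as.matrix(reads[, te_cols, drop = FALSE])))
  ov_tot <- sum(ov); te_tot <- sum(te)
  de <- if (nrow(reads) && ov_tot > 0 && te_tot > 0)
    seq_de_test(ov, te, ov_tot, te_tot)
  else data.frame(p = rep(NA_real_, nrow(reads)),
                  padj = rep(NA_real_, nrow(reads)))
  data.frame(sequence = reads$sequence, ovary_pool = ov, testis_pool = te,
             category = classify_sex_specificity(ov, te,
                                                 thresholds$seq$min_count),
             log2fc = if (ov_tot > 0 && te_tot > 0)
               seq_logfc(ov, te, ov_tot, te_tot) else NA_real_,
             p = de$p, padj = de$padj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select piRNAs for microarray validation
#'
#' Union of (1) the differential set — |log2FC| >= 1.5, P <= 0.01,
#' Padj <= 0.05 and pooled counts > 10 — and (2) the high-expression set —
#' pooled count within 50-4646 in ovary or 50-8177 in testis (inclusive
#' bounds). Each candidate carries a provenance flag.
#'
#' @param expr Table from [seq_expression_table()].
#' @param thresholds A [thresholds_config()] list.
#' @return Subset of `expr` with logical columns `de_selected`,
#'   `high_selected` and a `provenance` label (`de`, `high` or `both`).
#' @export
select_array_candidates <- function(expr, thresholds = thresholds_config()) {
  th <- thresholds$seq
  de <- !is.na(expr$p) & abs(expr$log2fc) >= th$lfc & expr$p <= th$p &
    expr$padj <= th$padj & (expr$ovary_pool + expr$testis_pool) > th$min_count
  hi <- (expr$ovary_pool >= th$high_expr_ovary[1] &
           expr$ovary_pool <= th$high_expr_ovary[2]) |
        (expr$testis_pool >= th$high_expr_testis[1] &
           expr$testis_pool <= th$high_expr_testis[2])
  out <- expr[de | hi, , drop = FALSE]
  out$de_selected <- de[de | hi]
  out$high_selected <- hi[de | hi]
  out$provenance <- ifelse(out$de_selected & out$high_selected, "both",
                           ifelse(out$de_selected, "de", "high"))
  rownames(out) <- NULL
  out
}
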