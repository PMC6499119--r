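## Microarray expression pipeline: background subtraction, replicate-CV
## filtering, quantile normalization, replicate medians, one-way ANOVA and
## category calls; plus clustering of sex-biased probes and cross-platform
## concordance.

#' Run the microarray expression pipeline
#'
#' Steps, in order: (1) subtract the background matrix, flooring negatives
#' at zero (with a warning giving the floored-spot count); (2) drop probes
#' whose replicate-spot CV (sd/mean) reaches the threshold in any sample —
#' category `filtered`; (3) quantile-normalize the spot columns of the
#' retained probes (rank-wise sorted-value means, ties averaged); (4) take
#' the per-sample replicate median; (5) one-way ANOVA across the ovary and
#' testis groups of sample medians; (6) log2FC of the group medians with a
#' 0.01 pseudo-intensity; (7) categories: `ovary_up` / `testis_up` when
#' |log2FC| >= 1 and P <= 0.05, `co_expressed` when both group medians
#' exceed 1 with P > 0.05, otherwise `nonsignificant`.
#'
#' @param raw,background Congruent numeric matrices, probes x spot columns
#'   named `<sample>_r<replicate>` (e.g. `ovary2_r3`); row names are probe
#'   ids. Sample names must start with `ovary` or `testis`.
#' @param thresholds A [thresholds_config()] list (`$array` is used).
#' @return List with `records` — one row per probe: `probe`, `max_cv`,
#'   `category`, per-sample medians, `ovary_median`, `testis_median`, `F`,
#'   `p`, `log2fc` — and `normalized`, the quantile-normalized spot matrix of
#'   retained probes.
#' @export
array_pipeline <- function(raw, background, thresholds = thresholds_config()) {
  th <- thresholds$array
  if (!all(dim(raw) == dim(background)) ||
      !identical(colnames(raw), colnames(background)) ||
      !identical(rownames(raw), rownames(background)))
    stop("array_pipeline(): raw and background matrices are not congruent")
  spot_cols <- colnames(raw)
  samples <- unique(sub("_r[0-9]+$", "", spot_cols))
  sexes <- ifelse(startsWith(samples, "ovary"), "ovary",
                  ifelse(startsWith(samples, "testis"), "testis", NA))
  if (any(is.na(sexes)))
    stop("array_pipeline(): sample columns must start with 'ovary' or 'testis'")

  bs <- raw - background
  n_floor <- sum(bs < 0)
  if (n_floor > 0) {
    warning(n_floor, " background-subtracted spot(s) below zero floored at 0")
    bs[bs < 0] <- 0
  }

  ## replicate CV per probe per sample; a probe fails if any sample's CV
  ## reaches the threshold (zero-mean samples count as failures)
  cv <- sapply(samples, function(s) {
    cols <- grep(paste0("^", s, "_r[0-9]+$"), spot_cols)
    x <- bs[, cols, drop = FALSE]
    mu <- rowMeans(x)
    sdv <- apply(x, 1L, stats::sd)
    ifelse(mu > 0, sdv / mu, ifelse(sdv == 0, 0, Inf))
  })
  if (is.null(dim(cv))) cv <- matrix(cv, nrow = nrow(bs))
  max_cv <- apply(cv, 1L, max)
  filtered <- !(max_cv < th$cv)

  keep <- which(!filtered)
  qn <- bs[keep, , drop = FALSE]
  if (length(keep) > 1L) qn <- limma::normalizeQuantiles(qn, ties = TRUE)

  records <- data.frame(probe = rownames(raw), max_cv = max_cv,
                        category = "filtered", stringsAsFactors = FALSE)
  for (s in samples) records[[paste0("median_", s)]] <- NA_real_
  records$ovary_median <- NA_real_; records$testis_median <- NA_real_
  records$F <- NA_real_; records$p <- NA_real_; records$log2fc <- NA_real_
  if (length(keep)) {
    sample_medians <- sapply(samples, function(s) {
      cols <- grep(paste0("^", s, "_r[0-9]+$"), spot_cols)
      apply(qn[, cols, drop = FALSE], 1L, stats::median)
    })
    if (length(keep) == 1L)
      sample_medians <- matrix(sample_medians, nrow = 1L,
                               dimnames = list(rownames(qn), samples))
    ov_cols <- which(sexes == "ovary")
    te_cols <- which(sexes == "testis")
    an <- two_group_anova(sample_medians[, ov_cols, drop = FALSE],
                          sample_medians[, te_cols, drop = FALSE])
    ov_med <- apply(sample_medians[, ov_cols, drop = FALSE], 1L, stats::median)
    te_med <- apply(sample_medians[, te_cols, drop = FALSE], 1L, stats::median)
    lfc <- log2((ov_med + 0.01) / (te_med + 0.01))
    cat_kept <- ifelse(abs(lfc) >= th$lfc & an$p <= th$p,
                       ifelse(lfc > 0, "ovary_up", "testis_up"),
                       ifelse(ov_med > th$coexpr_median &
                                te_med > th$coexpr_median & an$p > th$p,
                              "co_expressed", "nonsignificant"))
    cat_kept[is.na(cat_kept)] <- "nonsignificant"
    records$category[keep] <- cat_kept
    for (j in seq_along(samples))
      records[[paste0("median_", samples[j])]][keep] <- sample_medians[, j]
    records$ovary_median[keep] <- ov_med
    records$testis_median[keep] <- te_med
    records$F[keep] <- an$F
    records$p[keep] <- an$p
    records$log2fc[keep] <- lfc
  }
  rownames(records) <- NULL
  list(records = records, normalized = qn)
}

#' Closed-form one-way ANOVA for two groups
#'
#' Between/within decomposition for two groups, vectorised over rows.
#' Identical to the pooled-variance two-sample t test: F = t^2 with the same
#' P value (df 1 and n1 + n2 - 2).
#'
#' @param x1,x2 Matrices (rows = units, columns = replicates per group) or
#'   numeric vectors for a single unit.
#' @return Data frame with `F` and `p`. Zero within-group variance with a
#'   nonzero between-group difference yields `F = Inf`, `p = 0`.
#' @export
two_group_anova <- function(x1, x2) {
  if (is.null(dim(x1))) x1 <- matrix(x1, nrow = 1L)
  if (is.null(dim(x2))) x2 <- matrix(x2, nrow = 1L)
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df2 <- n1 + n2 - 2L
  f <- ifelse(ssw > 0, ssb / (ssw / df2), ifelse(ssb > 0, Inf, NaN))
  p <- ifelse(is.nan(f), NA_real_, stats::pf(f, 1L, df2, lower.tail = FALSE))
  data.frame(F = f, p = p)
}

#' Cluster sex-biased probes into clades
#'
#' Average-linkage hierarchical clustering on correlation distance
#' (1 - Pearson r) of the z-scored per-sample medians, cut at `k` clades.
#' Deterministic given the input order; `k` is reduced with a warning when
#' fewer probes than clades are supplied.
#'
#' @param medians Numeric matrix, probes x samples (per-sample medians of
#'   the biased probes).
#' @param k Number of clades (default 10).
#' @return Integer clade assignment named by probe.
#' @export
cluster_biased <- function(medians, k = 10L) {
  n <- nrow(medians)
  if (n < 1L) stop("cluster_biased(): no probes")
  if (n < k) {
    warning("cluster_biased(): only ", n, " probes; reducing k from ", k)
    k <- n
  }
  z <- t(apply(medians, 1L, function(x) {
    s <- stats::sd(x)
    if (s > 0) (x - mean(x)) / s else x * 0
  }))
  cc <- suppressWarnings(stats::cor(t(z)))
  cc[!is.finite(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

#' Sequencing / microarray fold-change concordance
#'
#' Pearson correlation with a two-sided t-approximation P value.
#'
#' @param seq_logfc,array_logfc Paired log2 fold changes (>= 3 pairs).
#' @return List with `r`, `p` and `n`; a constant vector makes the
#'   correlation undefined and is reported as `r = NA` with a note.
#' @export
platform_concordance <- function(seq_logfc, array_logfc) {
  ok <- is.finite(seq_logfc) & is.finite(array_logfc)
  x <- seq_logfc[ok]; y <- array_logfc[ok]
  if (length(x) < 3L)
    stop("platform_concordance(): need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                note = "undefined: constant vector"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
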