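## piRNA-generating genes and hypergeometric term enrichment.

#' Map predicted piRNAs to their generating genes
#'
#' A transcript is piRNA-generating when at least one predicted piRNA maps
#' to it exactly (either strand). A piRNA hitting several genes is counted
#' once per gene (per-gene uniqueness, not global).
#'
#' @param pirnas Character vector of predicted piRNA sequences.
#' @param index Transcriptome [build_exact_index()].
#' @return List with `table` (data frame: `gene`, `length`, `n_pirna`),
#'   `hits` (the underlying hit table) and `summary` (gene count,
#'   mean/median/range of gene length, mean piRNAs per gene).
#' @export
map_pirnas_to_genes <- function(pirnas, index) {
  hits <- find_exact_hits(index, unique(pirnas))
  if (nrow(hits) == 0L) {
    return(list(table = data.frame(gene = character(0), length = integer(0),
                                   n_pirna = integer(0)),
                hits = hits,
                summary = list(n_genes = 0L, mean_length = NA_real_,
                               median_length = NA_real_,
                               length_range = c(NA_real_, NA_real_),
                               mean_pirnas_per_gene = NA_real_)))
  }
  inc <- unique(hits[, c("sequence", "transcript")])
  tab <- as.data.frame(table(inc$transcript), stringsAsFactors = FALSE)
  names(tab) <- c("gene", "n_pirna")
  tab$length <- index$lengths[match(tab$gene, index$names)]
  tab <- tab[order(tab$gene), c("gene", "length", "n_pirna")]
  rownames(tab) <- NULL
  list(table = tab, hits = hits,
       summary = list(n_genes = nrow(tab),
                      mean_length = mean(tab$length),
                      median_length = stats::median(tab$length),
                      length_range = range(tab$length),
                      mean_pirnas_per_gene = mean(tab$n_pirna)))
}

#' Partition piRNA-generating genes by sex of their piRNAs
#'
#' A gene with only ovary-specific piRNAs is `ovary`, only testis-specific
#' `testis`, at least one of each `both`; genes with no sex-specific piRNA
#' at all are left out of the partition.
#'
#' @param hits Hit table from [map_pirnas_to_genes()].
#' @param categories Data frame with `sequence` and `category` (from
#'   [seq_expression_table()]).
#' @return List with `genes` (data frame `gene` / `partition`) and `counts`
#'   (named ovary / testis / both).
#' @export
sex_partition <- function(hits, categories) {
  inc <- unique(hits[, c("sequence", "transcript")])
  inc$category <- categories$category[match(inc$sequence, categories$sequence)]
  genes <- unique(inc$transcript)
  part <- vapply(genes, function(g) {
    cats <- inc$category[inc$transcript == g]
    has_o <- any(cats == "ovary_specific", na.rm = TRUE)
    has_t <- any(cats == "testis_specific", na.rm = TRUE)
    if (has_o && has_t) "both" else if (has_o) "ovary"
    else if (has_t) "testis" else NA_character_
  }, character(1))
  df <- data.frame(gene = genes, partition = part, stringsAsFactors = FALSE)
  df <- df[!is.na(df$partition), , drop = FALSE]
  rownames(df) <- NULL
  list(genes = df,
       counts = c(ovary = sum(df$partition == "ovary"),
                  testis = sum(df$partition == "testis"),
                  both = sum(df$partition == "both")))
}

#' Hypergeometric term enrichment with BH correction
#'
#' For each term: P(X >= k) where k study genes out of n hit a term of size
#' K in a background of N annotated genes (upper-tail hypergeometric, the
#' one-sided Fisher test). The background universe is the annotated subset
#' of `background` (genes with at least one term). P values are BH-adjusted
#' across terms; `enriched` flags Padj < `alpha`.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param term_map Data frame with columns `term`, `gene` and optionally
#'   `name`.
#' @param alpha Adjusted-P threshold for the enriched flag (default 0.05).
#' @return Data frame sorted by `padj`: `term`, `name`, `k`, `K`, `n`, `N`,
#'   `p`, `padj`, `enriched`.
#' @export
enrich_terms <- function(study, background, term_map, alpha = 0.05) {
  study <- unique(study); background <- unique(background)
  missing <- setdiff(study, background)
  if (length(missing))
    stop("enrich_terms(): study genes absent from background: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  ann_genes <- intersect(background, unique(term_map$gene))
  study_ann <- intersect(study, ann_genes)
  N <- length(ann_genes); n <- length(study_ann)
  tm <- term_map[term_map$gene %in% ann_genes, , drop = FALSE]
  terms <- unique(tm$term)
  if (length(terms) == 0L || n == 0L)
    return(data.frame(term = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), padj = numeric(0),
                      enriched = logical(0)))
  rows <- lapply(terms, function(t) {
    tg <- unique(tm$gene[tm$term == t])
    K <- length(tg)
    k <- length(intersect(tg, study_ann))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t,
               name = if ("name" %in% names(tm))
                 tm$name[match(t, tm$term)] else NA_character_,
               k = k, K = K, n = n, N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$padj < alpha
  out <- out[order(out$padj, out$p, out$term), ]
  rownames(out) <- NULL
  out
}
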