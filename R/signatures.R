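## piRNA signature statistics: positional base usage (ping-pong 5' U /
## position-10 A signature), length distributions, strand composition and
## genic-feature distribution.

#' Position-specific base frequencies
#'
#' Base usage at positions 1..`max_pos` across a read set, either over
#' unique sequences or weighted by read counts. A position only draws on
#' reads long enough to reach it, so each defined row sums to 1. Bases are
#' reported in RNA spelling (U for T).
#'
#' @param seqs Character vector of read sequences (non-empty).
#' @param counts Optional read counts (same length as `seqs`).
#' @param weight_by_counts Weight by `counts` (default) or treat every
#'   unique sequence once.
#' @param max_pos Number of positions (default 32, the piRNA maximum).
#' @return List of class `"position_freq"`: `freq` (max_pos x ACGU matrix),
#'   `n_at_position` (weight reaching each position), `fraction_U_at_1`,
#'   `fraction_A_at_10`.
#' @export
position_base_frequencies <- function(seqs, counts = NULL,
                                      weight_by_counts = TRUE,
                                      max_pos = 32L) {
  if (length(seqs) == 0L) stop("position_base_frequencies(): empty read set")
  w <- if (weight_by_counts && !is.null(counts)) as.numeric(counts)
       else rep(1, length(seqs))
  bases <- c("A", "C", "G", "T")
  freq <- matrix(NA_real_, max_pos, 4L,
                 dimnames = list(NULL, c("A", "C", "G", "U")))
  n_at <- numeric(max_pos)
  len <- nchar(seqs)
  for (p in seq_len(max_pos)) {
    sel <- len >= p
    if (!any(sel)) next
    b <- substr(seqs[sel], p, p)
    wt <- vapply(bases, function(x) sum(w[sel][b == x]), numeric(1))
    tot <- sum(wt)
    n_at[p] <- tot
    if (tot > 0) freq[p, ] <- wt / tot
  }
  structure(list(freq = freq, n_at_position = n_at,
                 fraction_U_at_1 = unname(freq[1L, "U"]),
                 fraction_A_at_10 = if (max_pos >= 10L)
                   unname(freq[10L, "A"]) else NA_real_),
            class = "position_freq")
}

#' Length distribution per group
#'
#' Percentage of reads at each nt length within each group; bins sum to 100
#' per group. Empty groups are skipped with a warning.
#'
#' @param lengths Integer read lengths.
#' @param groups Group labels (same length).
#' @param counts Optional read-count weights.
#' @return Data frame with `group`, `length`, `count`, `pct`.
#' @export
length_distribution <- function(lengths, groups, counts = NULL) {
  w <- if (is.null(counts)) rep(1, length(lengths)) else as.numeric(counts)
  out <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    tot <- sum(w[sel])
    if (tot == 0) {
      warning("length_distribution(): group '", g, "' is empty; skipped")
      next
    }
    tab <- tapply(w[sel], lengths[sel], sum)
    out[[length(out) + 1L]] <- data.frame(
      group = g, length = as.integer(names(tab)),
      count = as.numeric(tab), pct = 100 * as.numeric(tab) / tot,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(group = character(0), length = integer(0),
                  count = numeric(0), pct = numeric(0))
}

## one hit per query: the lexicographically smallest
## (transcript, start, strand) — deterministic multi-mapping tie-break
primary_hits <- function(hits) {
  ord <- order(hits$query, hits$transcript, hits$start, hits$strand)
  h <- hits[ord, ]
  h[!duplicated(h$query), , drop = FALSE]
}

#' Strand composition of predicted piRNAs
#'
#' Counts sense and antisense piRNAs (one primary hit per sequence) and
#' their percentages of the total, half-up to 2 decimal places.
#'
#' @param hits Hit table from [find_exact_hits()] for the predicted piRNAs.
#' @return List with `sense`/`antisense` counts, `total`, and `sense_pct` /
#'   `antisense_pct`.
#' @export
strand_composition <- function(hits) {
  h <- primary_hits(hits)
  n_sense <- sum(h$strand == "+")
  n_anti <- sum(h$strand == "-")
  tot <- n_sense + n_anti
  list(sense = n_sense, antisense = n_anti, total = tot,
       sense_pct = if (tot) pct_value(n_sense, tot) else NA_real_,
       antisense_pct = if (tot) pct_value(n_anti, tot) else NA_real_)
}

## vectorised majority-overlap feature assignment (1-based closed intervals)
assign_features <- function(transcript, start, end, gene_models, tx_len) {
  if (any(!is.na(tx_len) & end > tx_len))
    stop("feature assignment: hit extends beyond transcript end (corrupt input)")
  priority <- c(CDS = 3L, three_prime_UTR = 2L, five_prime_UTR = 1L)
  vapply(seq_along(transcript), function(i) {
    gm <- gene_models[gene_models$transcript == transcript[i], , drop = FALSE]
    if (nrow(gm) == 0L) return("unannotated")
    ov <- pmin(end[i], gm$end) - pmax(start[i], gm$start) + 1L
    ov[ov < 0L] <- 0L
    if (all(ov == 0L)) return("unannotated")
    best <- which(ov == max(ov))
    if (length(best) > 1L) best <- best[which.max(priority[gm$feature[best]])]
    gm$feature[best]
  }, character(1))
}

#' Assign one hit to a genic feature
#'
#' The feature span (5' UTR / CDS / 3' UTR) with the majority overlap of the
#' read interval wins; ties break CDS > 3' UTR > 5' UTR. Reads on
#' transcripts without a gene model are `unannotated`. A hit extending past
#' the transcript end is an error (corrupt input).
#'
#' @param hit One-row hit (list or data frame row with `transcript`,
#'   `start`, `end`).
#' @param gene_models Gene-model table (transcript/feature/start/end).
#' @param tx_len Optional named transcript lengths for bounds checking.
#' @return Feature label (character scalar).
#' @export
feature_assignment <- function(hit, gene_models, tx_len = NULL) {
  tl <- if (is.null(tx_len)) NA_integer_ else tx_len[[hit$transcript]]
  assign_features(hit$transcript, hit$start, hit$end, gene_models, tl)
}

#' Genic-feature distribution of predicted piRNAs
#'
#' Assigns each piRNA (primary hit) a feature by majority overlap and
#' tallies counts and percentages of the total (half-up, 2 dp).
#'
#' @param hits Hit table for the predicted piRNAs.
#' @param gene_models Gene-model table.
#' @param tx_len Named transcript lengths.
#' @return List with `labels` (per primary hit), and `table`: data frame
#'   over five_prime_UTR / CDS / three_prime_UTR / unannotated with `count`
#'   and `pct`.
#' @export
feature_distribution <- function(hits, gene_models, tx_len = NULL) {
  h <- primary_hits(hits)
  labels <- if (nrow(h)) assign_features(h$transcript, h$start, h$end,
                                         gene_models,
                                         if (is.null(tx_len)) rep(NA_integer_, nrow(h))
                                         else tx_len[h$transcript])
            else character(0)
  lv <- c("five_prime_UTR", "CDS", "three_prime_UTR", "unannotated")
  cnt <- vapply(lv, function(x) sum(labels == x), numeric(1))
  tot <- sum(cnt)
  tab <- data.frame(feature = lv, count = as.integer(cnt),
                    pct = if (tot) pct_value(cnt, tot) else rep(NA_real_, 4L),
                    stringsAsFactors = FALSE)
  list(labels = data.frame(h, feature = labels, stringsAsFactors = FALSE),
       table = tab)
}
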