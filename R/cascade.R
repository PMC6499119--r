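## Sequential small-RNA annotation cascade.
##
## Only reads that map perfectly to the transcriptome are annotated; mapped
## reads then receive exactly one label by database priority:
##   conserved_miRNA > rRNA/tRNA/snRNA/snoRNA > repeat > novel_miRNA
##   > piRNA_candidate (remaining 26-32 nt) > other.
## Membership in a database is an exact-match occurrence (either strand) in
## the corresponding reference set.

ANNOTATION_LABELS <- c("conserved_miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                       "repeat", "novel_miRNA", "piRNA_candidate", "other")

#' Annotate a unique-read table through the small-RNA cascade
#'
#' @param reads Unique-read table from [clean_and_collapse()] (`$reads`):
#'   columns `sequence`, `length`, per-library counts, `total`.
#' @param bundle A reference bundle (or any list with `transcriptome`,
#'   `mirna`, `ncrna` (with `subtype` attribute), `repeats` elements).
#' @param index Optional prebuilt transcriptome [build_exact_index()]; built
#'   on the fly when `NULL`.
#' @param hairpin_min_pairs,hairpin_flank Novel-miRNA filter parameters, see
#'   [hairpin_novel_mirna_filter()].
#' @return List with `reads` (input plus `mapped` logical and `label`
#'   columns; unmapped reads carry label `NA`), `hits` (transcriptome hits of
#'   all mapped reads) and `summary` (per-library accounting table from
#'   [summarize_annotation()]).
#' @export
annotate_cascade <- function(reads, bundle, index = NULL,
                             hairpin_min_pairs = 18L, hairpin_flank = 70L) {
  if (is.null(index)) index <- build_exact_index(bundle$transcriptome)
  seqs <- reads$sequence
  hits <- find_exact_hits(index, seqs)
  mapped <- seq_along(seqs) %in% hits$query
  label <- rep(NA_character_, length(seqs))

  ## one membership scan over all small-RNA reference sets at once
  subtype <- attr(bundle$ncrna, "subtype")
  set_seqs <- c(
    if (length(bundle$mirna))
      stats::setNames(bundle$mirna, paste0("M|", names(bundle$mirna))),
    if (length(bundle$ncrna))
      stats::setNames(as.character(bundle$ncrna),
                      paste0("N", unname(subtype), "|", names(bundle$ncrna))),
    if (length(bundle$repeats))
      stats::setNames(bundle$repeats, paste0("R|", names(bundle$repeats))))
  member <- function(tag) rep(FALSE, length(seqs))
  if (length(set_seqs)) {
    set_hits <- find_exact_hits(build_exact_index(set_seqs), seqs)
    src <- sub("\\|.*$", "", set_hits$transcript)
    member <- function(tag) seq_along(seqs) %in% set_hits$query[src == tag]
  }
  remaining <- mapped
  assign_label <- function(sel, value) {
    sel <- sel & remaining
    label[sel] <<- value
    remaining[sel] <<- FALSE
  }
  assign_label(member("M"), "conserved_miRNA")
  for (st in NCRNA_SUBTYPES) assign_label(member(paste0("N", st)), st)
  assign_label(member("R"), "repeat")

  ## novel-miRNA hairpin test on remaining short reads (18-25 nt)
  short <- which(remaining & reads$length >= 18L & reads$length <= 25L)
  if (length(short)) {
    first_hit <- hits[!duplicated(hits$query), ]
    novel <- vapply(short, function(i) {
      h <- first_hit[first_hit$query == i, ]
      hairpin_novel_mirna_filter(seqs[i], h[1, ], bundle$transcriptome,
                                 min_pairs = hairpin_min_pairs,
                                 flank = hairpin_flank)
    }, logical(1))
    sel <- rep(FALSE, length(seqs)); sel[short[novel]] <- TRUE
    assign_label(sel, "novel_miRNA")
  }
  assign_label(reads$length >= 26L & reads$length <= 32L, "piRNA_candidate")
  assign_label(rep(TRUE, length(seqs)), "other")

  out <- reads
  out$mapped <- mapped
  out$label <- label
  lib_cols <- setdiff(colnames(reads), c("sequence", "length", "total"))
  list(reads = out, hits = hits,
       summary = summarize_annotation(out, lib_cols))
}

#' Per-library annotation accounting
#'
#' One row per library: mapped read count, then per label the read count and
#' its percentage of the mapped total (half-up, 2 decimal places), plus the
#' number of distinct piRNA-candidate sequences observed in that library.
#'
#' @param labelled_reads Read table carrying `mapped` and `label` columns
#'   (from [annotate_cascade()]).
#' @param lib_cols Names of the per-library count columns.
#' @return Data frame with columns `library`, `mapped`, `<label>` and
#'   `<label>_pct` for each annotation label, and `unique_piRNA`.
#' @export
summarize_annotation <- function(labelled_reads, lib_cols) {
  rows <- lapply(lib_cols, function(l) {
    cts <- labelled_reads[[l]]
    mapped_total <- sum(cts[labelled_reads$mapped])
    if (mapped_total == 0L)
      warning("library '", l, "': no mapped reads; percentages reported as 0.00")
    row <- list(library = l, mapped = mapped_total)
    for (lab in ANNOTATION_LABELS) {
      n <- sum(cts[labelled_reads$mapped &
                     !is.na(labelled_reads$label) &
                     labelled_reads$label == lab])
      row[[lab]] <- n
      row[[paste0(lab, "_pct")]] <-
        if (mapped_total > 0) pct_value(n, mapped_total) else 0
    }
    row$unique_piRNA <- sum(cts > 0 & labelled_reads$mapped &
                              !is.na(labelled_reads$label) &
                              labelled_reads$label == "piRNA_candidate")
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Novel-miRNA hairpin filter
#'
#' Decides whether a mapped 18-25 nt read could derive from a miRNA-like
#' precursor: the transcript context around the hit (`flank` nt each side)
#' is folded by Nussinov maximum base pairing (Watson-Crick plus G-U wobble,
#' minimum loop 3), and the read is called novel-miRNA when the window
#' reaches `min_pairs` base pairs and the read lies wholly within one arm of
#' the optimal traceback (it does not cross the innermost paired region).
#' An acknowledged simplification of dedicated precursor scanners.
#'
#' @param read Read sequence (only its length is used).
#' @param hit One transcriptome hit (row with `transcript`, `start`, `end`).
#' @param transcriptome Named character vector of transcript sequences.
#' @param min_pairs Minimum base pairs in the window (default 18).
#' @param flank Context taken on each side of the hit (default 70 nt;
#'   truncated at transcript ends).
#' @return Logical scalar.
#' @export
hairpin_novel_mirna_filter <- function(read, hit, transcriptome,
                                       min_pairs = 18L, flank = 70L) {
  tx <- transcriptome[[hit$transcript]]
  L <- nchar(tx)
  ws <- max(1L, hit$start - flank)
  we <- min(L, hit$end + flank)
  window <- substr(tx, ws, we)
  ns <- nussinov_pairs(window)
  if (ns$max_pairs < min_pairs || nrow(ns$pairs) == 0L) return(FALSE)
  rs <- hit$start - ws + 1L            # read interval in window coordinates
  re <- hit$end - ws + 1L
  left_arm_end <- max(ns$pairs$i)
  right_arm_start <- min(ns$pairs$j)
  re <= left_arm_end || rs >= right_arm_start
}

#' Nussinov maximum base pairing
#'
#' Dynamic-programming maximum number of nested base pairs (A-T, G-C, G-T
#' wobble; minimum hairpin loop of 3 unpaired bases) with one optimal
#' traceback.
#'
#' @param seq DNA sequence (character scalar).
#' @return List with `max_pairs` (integer) and `pairs` (data frame of paired
#'   positions `i < j` from the traceback).
#' @export
nussinov_pairs <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  n <- length(b)
  pairable <- c(AT = TRUE, TA = TRUE, CG = TRUE, GC = TRUE, GT = TRUE, TG = TRUE)
  can_pair <- function(i, j) isTRUE(pairable[paste0(b[i], b[j])])
  M <- matrix(0L, n, n)
  if (n >= 5L) {
    for (span in 4:(n - 1L)) {
      for (i in 1:(n - span)) {
        j <- i + span
        best <- M[i + 1L, j]
        v <- M[i, j - 1L]
        if (v > best) best <- v
        if (can_pair(i, j)) {
          v <- M[i + 1L, j - 1L] + 1L
          if (v > best) best <- v
        }
        ks <- i:(j - 1L)
        v <- max(M[i, ks] + M[cbind(ks + 1L, j)])
        if (v > best) best <- v
        M[i, j] <- best
      }
    }
  }
  ## traceback (iterative stack; first optimal rule encountered wins)
  pairs_i <- integer(0); pairs_j <- integer(0)
  if (n >= 5L && M[1L, n] > 0L) {
    stack <- list(c(1L, n))
    while (length(stack)) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (i >= j || M[i, j] == 0L) next
      if (M[i + 1L, j] == M[i, j]) {
        stack[[length(stack) + 1L]] <- c(i + 1L, j)
      } else if (M[i, j - 1L] == M[i, j]) {
        stack[[length(stack) + 1L]] <- c(i, j - 1L)
      } else if (can_pair(i, j) && j - i >= 4L &&
                 M[i + 1L, j - 1L] + 1L == M[i, j]) {
        pairs_i <- c(pairs_i, i); pairs_j <- c(pairs_j, j)
        stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
      } else {
        for (k in i:(j - 1L)) {
          if (M[i, k] + M[k + 1L, j] == M[i, j]) {
            stack[[length(stack) + 1L]] <- c(i, k)
            stack[[length(stack) + 1L]] <- c(k + 1L, j)
            break
          }
        }
      }
    }
  }
  list(max_pairs = if (n >= 5L) M[1L, n] else 0L,
       pairs = data.frame(i = pairs_i, j = pairs_j))
}
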