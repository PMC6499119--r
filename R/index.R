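## Exact-match (zero-mismatch) mapping of small-RNA queries against reference
## sequence sets. Queries are batched into constant-width Aho-Corasick
## dictionaries (Biostrings PDict) per length and scanned on both strands
## over the reference concatenated with N separators (ACGT-only patterns
## cannot cross an N, so concatenated hits map uniquely back to one
## reference sequence). Equivalence with a brute-force substring scan is
## property-tested.

#' Build an exact-match index over a reference set
#'
#' @param ref Named character vector or `DNAStringSet` of reference
#'   sequences. An empty reference yields a valid, empty index.
#' @return An object of class `"exact_index"`.
#' @export
build_exact_index <- function(ref) {
  seqs <- if (inherits(ref, "DNAStringSet")) as.character(ref) else ref
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- sprintf("ref%05d", seq_along(seqs))
  w <- nchar(seqs)
  subject <- if (length(seqs))
    Biostrings::DNAString(paste(seqs, collapse = "N")) else NULL
  rc_subject <- if (length(seqs)) Biostrings::reverseComplement(subject) else NULL
  ## 0-based offset of each reference within the concatenated subject
  offsets <- if (length(seqs)) cumsum(c(0L, utils::head(w, -1L) + 1L)) else integer(0)
  structure(list(subject = subject, rc_subject = rc_subject,
                 names = names(seqs), lengths = unname(w),
                 offsets = unname(offsets)),
            class = "exact_index")
}

#' @export
print.exact_index <- function(x, ...) {
  cat("<exact_index>", length(x$names), "reference sequences,",
      sum(x$lengths), "nt total\n")
  invisible(x)
}

#' Find all exact occurrences of queries in an indexed reference
#'
#' Reports every zero-mismatch occurrence of each query in both orientations:
#' a sense hit means the query equals the reference substring, an antisense
#' hit means it equals the reverse complement of the substring. Queries
#' containing non-ACGT letters cannot match (the mapping contract excludes
#' ambiguous reads).
#'
#' @param index An [build_exact_index()] object.
#' @param queries Character vector of query sequences (the intended use is
#'   small-RNA reads of >= 18 nt; any length >= 1 is accepted).
#' @return Data frame with columns `query` (index into `queries`),
#'   `sequence`, `transcript`, `start`, `end` (1-based closed reference
#'   coordinates) and `strand` (`"+"` sense, `"-"` antisense), ordered by
#'   query, then transcript, start, strand.
#' @export
find_exact_hits <- function(index, queries) {
  stopifnot(inherits(index, "exact_index"))
  empty <- data.frame(query = integer(0), sequence = character(0),
                      transcript = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (length(queries) == 0L || length(index$names) == 0L) return(empty)
  ok <- which(!grepl("[^ACGT]", queries) & nchar(queries) > 0L &
                nchar(queries) <= max(index$lengths))
  if (length(ok) == 0L) return(empty)
  dss <- Biostrings::DNAStringSet(queries[ok])
  w <- Biostrings::width(dss)
  pd <- Biostrings::PDict(dss, tb.start = 1L, tb.end = min(w))
  Lc <- length(index$subject)
  collect <- function(m, strand) {
    cnt <- S4Vectors::elementNROWS(m)
    if (sum(cnt) == 0L) return(NULL)
    st <- unlist(Biostrings::startIndex(m), use.names = FALSE)
    wv <- rep(w, cnt)
    ## a hit on the reverse-complemented subject maps back to original
    ## coordinates as Lc - start - width + 2
    if (strand == "-") st <- Lc - st - wv + 2L
    ti <- findInterval(st, index$offsets + 1L)
    local <- st - index$offsets[ti]
    data.frame(query = ok[rep(seq_along(cnt), cnt)],
               transcript = index$names[ti],
               start = local, end = local + wv - 1L, strand = strand,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(
    collect(Biostrings::matchPDict(pd, index$subject, max.mismatch = 0), "+"),
    collect(Biostrings::matchPDict(pd, index$rc_subject, max.mismatch = 0), "-"))
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits$sequence <- queries[hits$query]
  ord <- order(hits$query, hits$transcript, hits$start, hits$strand)
  hits <- hits[ord, c("query", "sequence", "transcript", "start", "end",
                      "strand")]
  rownames(hits) <- NULL
  hits
}

## convenience: which queries have at least one hit in the index
has_exact_hit <- function(index, queries) {
  if (length(queries) == 0L) return(logical(0))
  if (length(index$names) == 0L) return(rep(FALSE, length(queries)))
  seq_along(queries) %in% find_exact_hits(index, queries)$query
}
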