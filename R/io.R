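#' Read a FASTA file as a named character vector
#'
#' Convenience wrapper (Biostrings underneath) for loading reference sets,
#' known-piRNA collections or file-based classifier training sets.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(dss), names(dss))
}

#' Read a term-to-gene map from TSV
#'
#' Expects at least `term` and `gene` columns (optionally `name`), the input
#' format of [enrich_terms()].
#'
#' @param path Tab-separated file with a header row.
#' @return Data frame with columns `term`, `gene` and, if present, `name`.
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("term", "gene")
  if (!all(need %in% names(df)))
    stop("read_term_map(): '", path, "' must have columns term and gene")
  df[, intersect(c("term", "gene", "name"), names(df)), drop = FALSE]
}
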