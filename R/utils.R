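#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over character sequences (ACGTN alphabet).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")    # "ACGT" (palindrome)
#' revcomp("AAGTC")   # "GACTT"
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half-up
#'
#' Rounds to `digits` decimal places with exact halves going up, the
#' convention used for all percentage reporting in this package (base R
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Format a count ratio as a percentage
#'
#' Reporting convention used throughout: `100 * numerator / denominator`,
#' rounded half-up to two decimal places.
#'
#' @param numerator,denominator Non-negative counts; `denominator` must be > 0.
#' @param digits Decimal places (default 2).
#' @return Character scalar such as `"43.99%"`.
#' @seealso [pct_value()] for the bare numeric value.
#' @export
#' @examples
#' percentage(385222, 875679)  # "43.99%"
percentage <- function(numerator, denominator, digits = 2) {
  if (length(denominator) != 1L || is.na(denominator) || denominator <= 0)
    stop("percentage(): denominator must be a single positive count")
  sprintf(paste0("%.", digits, "f%%"), pct_value(numerator, denominator, digits))
}

#' @rdname percentage
#' @export
pct_value <- function(numerator, denominator, digits = 2) {
  round_half_up(100 * numerator / denominator, digits)
}

## Deterministic sub-seed derived from a run seed and a stage tag, kept below
## 2^31 so it is a valid R integer seed.
sub_seed <- function(seed, tag) {
  h <- 5381
  for (c in utf8ToInt(tag)) h <- (h * 33 + c) %% 2147483629
  as.integer((h + (seed %% 2147483629) * 7919) %% 2147483629)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## FNV-1a-style hash of a string, returned as 8 hex characters. Used for
## config fingerprints in run reports (stable across sessions, no extra deps).
fnv1a <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    lo <- bitwXor(as.integer(h %% 2^16), as.integer(b))
    h <- (h %/% 2^16) * 2^16 + (lo %% 2^16)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

## Draw random DNA sequences with given base composition.
random_dna <- function(n, lengths, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (n == 0L) return(character(0))
  lengths <- rep_len(lengths, n)
  vapply(lengths, function(L)
    paste(sample(names(freqs), L, replace = TRUE, prob = freqs), collapse = ""),
    character(1))
}

## Shuffle the letters of one sequence (used for known-piRNA decoys).
shuffle_seq <- function(x) {
  paste(sample(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
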