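# Independent oracles and fixture builders used across the suite.

# all (overlapping) occurrences of q in ref, 1-based starts
find_all_occurrences <- function(q, ref) {
  out <- integer(0)
  from <- 1L
  n <- nchar(ref)
  w <- nchar(q)
  while (from + w - 1L <= n) {
    p <- regexpr(q, substr(ref, from, n), fixed = TRUE)
    if (p < 0L) break
    pos <- from + as.integer(p) - 1L
    out <- c(out, pos)
    from <- pos + 1L
  }
  out
}

# brute-force substring scan of every reference, both strands
brute_force_hits <- function(refs, queries) {
  rows <- list()
  for (qi in seq_along(queries)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") queries[qi] else gonadpi::revcomp(queries[qi])
      for (ri in seq_along(refs)) {
        for (s in find_all_occurrences(q, refs[[ri]])) {
          rows[[length(rows) + 1L]] <- data.frame(
            query = qi, transcript = names(refs)[ri], start = s,
            end = s + nchar(q) - 1L, strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(query = integer(0), transcript = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$query, out$transcript, out$start, out$strand), ]
}

# exhaustive enumeration of nested base pairings (min loop 3, WC + GU),
# feasible for sequences up to ~12 nt
enum_max_pairs <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  ok <- c("AT", "TA", "CG", "GC", "GT", "TG")
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      if (paste0(b[i], b[k]) %in% ok) {
        v <- 1L + rec(i + 1L, k - 1L) +
          (if (k < j) rec(k + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    best
  }
  if (length(b) < 5L) 0L else rec(1L, length(b))
}

random_seq <- function(n, len) {
  vapply(rep(len, n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

# small, fast simulator configuration for unit tests
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_genes = 40L, n_pirna = 150L, n_mirna = 15L,
               n_ncrna = 8L, n_repeat = 6L, n_decoy = 30L, n_other = 30L,
               n_hairpin = 2L, depth_per_library = 3000L,
               transcript_length_range = c(400L, 1200L))
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(gonadpi::sim_config, args)
}

# 2x2 tables exercised against stats::fisher.test
random_2x2 <- function(n_max = 60L) {
  repeat {
    x <- as.integer(stats::rmultinom(1, sample(4:n_max, 1), rep(1 / 4, 4)))
    if (sum(x) >= 4L) return(x)
  }
}
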