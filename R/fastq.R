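## FASTQ ingestion: validation, cleaning, QC, unique-read collapsing.

read_fastq_records <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(list(seq = character(0), qual = character(0)))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in '", path, "': ", length(lines),
         " lines is not a multiple of 4")
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]; sq <- lines[idx + 1L]
  plus <- lines[idx + 2L]; qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(sq) != nchar(qual) | nchar(sq) == 0L |
                 grepl("[^ACGTNacgtn]", sq))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in '", path, "'")
  list(seq = toupper(sq), qual = qual)
}

## per-base Phred scores (Phred+33) for one quality string
phred_scores <- function(qual) utf8ToInt(qual) - 33L

#' Clean FASTQ libraries and collapse to unique reads
#'
#' Per library: optionally trims a 3' adapter (everything from the first
#' exact adapter occurrence onward is removed), then drops reads containing
#' N, reads with mean Phred quality below `min_quality`, and reads whose
#' (post-trim) length falls outside `length_window`. Survivors are collapsed
#' to distinct sequences with per-library occurrence counts. Library QC
#' (error rate, Q30, GC) is computed on the raw, untrimmed reads.
#'
#' @param fastq_paths Named character vector of FASTQ paths; names are the
#'   library ids (unnamed paths get their base names).
#' @param min_quality Minimum mean Phred quality (default 20).
#' @param length_window Integer pair: retained read-length window, default
#'   `c(18, 35)` (covers the miRNA and piRNA ranges).
#' @param adapter Optional adapter string to trim.
#' @return List with `reads` — the unique-read table (columns `sequence`,
#'   `length`, one count column per library, `total`) — and `qc`, a data
#'   frame of per-library quality metrics: total and retained read counts,
#'   mean per-base error rate (%), Q30 fraction (%), GC content (%).
#' @export
clean_and_collapse <- function(fastq_paths, min_quality = 20,
                               length_window = c(18L, 35L), adapter = NULL) {
  if (is.null(names(fastq_paths)) || any(names(fastq_paths) == ""))
    names(fastq_paths) <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                              basename(fastq_paths))
  libs <- names(fastq_paths)
  per_lib <- lapply(fastq_paths, function(p) {
    rec <- read_fastq_records(p)
    n_total <- length(rec$seq)
    if (n_total == 0L)
      return(list(tab = integer(0),
                  qc = c(total = 0, retained = 0, error_rate_pct = NA,
                         q30_pct = NA, gc_pct = NA)))
    q <- lapply(rec$qual, phred_scores)
    all_q <- unlist(q, use.names = FALSE)
    err_pct <- mean(10^(-all_q / 10)) * 100
    q30_pct <- mean(all_q >= 30) * 100
    nbase <- nchar(rec$seq)
    gc_pct <- 100 * sum(nchar(gsub("[^GC]", "", rec$seq))) / sum(nbase)
    sq <- rec$seq
    if (!is.null(adapter)) {
      pos <- regexpr(adapter, sq, fixed = TRUE)
      hit <- pos > 0L
      sq[hit] <- substr(sq[hit], 1L, pos[hit] - 1L)
      q[hit] <- lapply(which(hit), function(i) q[[i]][seq_len(nchar(sq[i]))])
    }
    mean_q <- vapply(q, function(x) if (length(x)) mean(x) else 0, numeric(1))
    len <- nchar(sq)
    keep <- !grepl("N", sq, fixed = TRUE) & mean_q >= min_quality &
      len >= length_window[1] & len <= length_window[2]
    tab <- table(sq[keep])
    list(tab = tab,
         qc = c(total = n_total, retained = sum(keep),
                error_rate_pct = err_pct, q30_pct = q30_pct, gc_pct = gc_pct))
  })
  qc <- data.frame(library = libs,
                   do.call(rbind, lapply(per_lib, `[[`, "qc")),
                   row.names = NULL, stringsAsFactors = FALSE)
  all_seq <- sort(unique(unlist(lapply(per_lib, function(x) names(x$tab)))))
  counts <- sapply(libs, function(l) {
    tab <- per_lib[[l]]$tab
    v <- as.integer(tab[match(all_seq, names(tab))])
    v[is.na(v)] <- 0L
    v
  }, simplify = FALSE)
  reads <- data.frame(sequence = all_seq,
                      length = nchar(all_seq),
                      stringsAsFactors = FALSE)
  for (l in libs) reads[[l]] <- if (length(all_seq)) counts[[l]] else integer(0)
  reads$total <- if (length(all_seq))
    as.integer(rowSums(as.matrix(reads[, libs, drop = FALSE]))) else integer(0)
  list(reads = reads, qc = qc)
}
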