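## Synthetic reference and ground-truth generation.
##
## All simulated small-RNA elements (piRNAs, mature miRNAs, structural
## ncRNAs, repeats, hairpin precursors, decoy fragments) are planted INTO the
## transcriptome at non-overlapping loci, so every simulated read maps to the
## reference with zero mismatches and re-extracting its origin coordinates
## reproduces the read (after reverse complement on the antisense strand).

SEX_CLASSES <- c("ovary_only", "testis_only", "biased", "shared")
NCRNA_SUBTYPES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

## locus planter over the transcriptome: reserves non-overlapping intervals
new_planter <- function(tx_lengths) {
  env <- new.env(parent = emptyenv())
  env$occ <- vector("list", length(tx_lengths))
  env$tx_lengths <- tx_lengths
  env
}

plant_locus <- function(planter, len, max_tries = 500L) {
  lens <- planter$tx_lengths
  ok <- which(lens >= len)
  if (!length(ok)) return(NULL)
  for (i in seq_len(max_tries)) {
    ti <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = lens[ok])
    s <- sample.int(lens[ti] - len + 1L, 1L)
    e <- s + len - 1L
    ints <- planter$occ[[ti]]
    if (is.null(ints) || !any(s <= ints[, 2] & e >= ints[, 1])) {
      planter$occ[[ti]] <- rbind(ints, c(s, e))
      return(list(tx = ti, start = s, end = e))
    }
  }
  NULL
}

## draw one piRNA-like sequence: A/U-rich composition, 5' U forced with total
## probability p_5prime_U, base 10 A forced with total probability p_pos10_A
draw_pirna_seq <- function(len, base_freqs, p_u1, p_a10) {
  b <- sample(names(base_freqs), len, replace = TRUE, prob = base_freqs)
  nt <- setdiff(names(base_freqs), "T")
  b[1] <- if (stats::runif(1) < p_u1) "T" else
    sample(nt, 1L, prob = base_freqs[nt] / sum(base_freqs[nt]))
  na <- setdiff(names(base_freqs), "A")
  b[10] <- if (stats::runif(1) < p_a10) "A" else
    sample(na, 1L, prob = base_freqs[na] / sum(base_freqs[na]))
  paste(b, collapse = "")
}

## vectorised SimTruth chunk constructor
truth_chunk <- function(id, sequence, class, expected_label, transcript = NA,
                        start = NA, end = NA, strand = "+",
                        feature = "unannotated", sex_category = "shared",
                        true_log2fc = 0) {
  n <- length(sequence)
  if (n == 0L) return(empty_truth())
  data.frame(id = id, sequence = sequence, class = class,
             expected_label = expected_label,
             transcript = rep_len(transcript, n),
             start = as.integer(rep_len(start, n)),
             end = as.integer(rep_len(end, n)),
             strand = rep_len(strand, n),
             feature = rep_len(feature, n),
             sex_category = rep_len(sex_category, n),
             true_log2fc = rep_len(true_log2fc, n),
             stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(id = character(0), sequence = character(0), class = character(0),
             expected_label = character(0), transcript = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             feature = character(0), sex_category = character(0),
             true_log2fc = numeric(0), stringsAsFactors = FALSE)
}

#' Build a synthetic reference bundle with planted ground truth
#'
#' Generates a transcriptome, gene models (5' UTR / CDS / 3' UTR spans that
#' partition each annotated transcript), mature-miRNA, structural-ncRNA and
#' repeat reference sets, a planted piRNA pool with ping-pong sequence biases,
#' degradation decoys, hairpin precursors and a known-piRNA set (planted true
#' sequences plus letter-shuffled decoys). Deterministic under
#' `config$seed`: the same config yields byte-identical files.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional directory; when given, FASTA reference sets, the
#'   GFF3 gene models and the truth table are written there.
#' @return A list of class `"reference_bundle"` with elements
#'   `transcriptome` (named character), `gene_models` (data frame with
#'   columns transcript/feature/start/end, 1-based closed), `mirna`, `ncrna`,
#'   `repeats`, `known` (named character vectors; `ncrna` carries a
#'   `subtype` attribute), `known_truth` (logical: planted true sequence vs
#'   shuffled decoy), and `pool` (the SimTruth table: one row per distinct
#'   simulated read sequence with biological class, expected cascade label,
#'   origin coordinates, strand, feature, sex category and true log2FC).
#' @export
build_reference <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bundle <- with_seed(sub_seed(config$seed, "reference"), {
    build_reference_impl(config)
  })
  if (!is.null(out_dir)) write_reference_files(bundle, out_dir)
  bundle
}

build_reference_impl <- function(cfg) {
  n <- cfg$n_genes
  tx_id <- if (n > 0) sprintf("tx%05d", seq_len(n)) else character(0)
  len_support <- seq(cfg$transcript_length_range[1],
                     cfg$transcript_length_range[2])
  tx_len <- if (n > 0)
    len_support[sample.int(length(len_support), n, replace = TRUE)]
  else integer(0)
  tx_seq <- random_dna(n, tx_len)
  names(tx_seq) <- tx_id

  ## gene models on a random subset of transcripts
  ann <- if (n > 0) sort(sample.int(n, round(cfg$annotated_fraction * n))) else integer(0)
  gm <- if (length(ann)) {
    L <- tx_len[ann]
    l5 <- pmax(1L, as.integer(round(cfg$utr_fractions[1] * L)))
    l3 <- pmax(1L, as.integer(round(cfg$utr_fractions[3] * L)))
    bad <- l5 + l3 >= L
    l5[bad] <- pmax(1L, L[bad] %/% 3L); l3[bad] <- pmax(1L, L[bad] %/% 3L)
    data.frame(
      transcript = rep(tx_id[ann], each = 3L),
      feature = rep(c("five_prime_UTR", "CDS", "three_prime_UTR"),
                    length(ann)),
      start = as.integer(rbind(1L, l5 + 1L, L - l3 + 1L)),
      end = as.integer(rbind(l5, L - l3, L)), stringsAsFactors = FALSE)
  } else {
    data.frame(transcript = character(0), feature = character(0),
               start = integer(0), end = integer(0))
  }

  planter <- new_planter(tx_len)
  truth <- list()

  ## mature miRNA set (5' U biased, planted sense)
  mirna <- character(0)
  if (cfg$n_mirna > 0 && n > 0) {
    ids <- sq <- txs <- character(0); sts <- ens <- integer(0)
    for (i in seq_len(cfg$n_mirna)) {
      len <- sample(20:24, 1L)
      loc <- plant_locus(planter, len)
      if (is.null(loc)) next
      s <- strsplit(substr(tx_seq[loc$tx], loc$start, loc$end), "")[[1]]
      if (stats::runif(1) < 0.8) s[1] <- "T"
      seq1 <- paste(s, collapse = "")
      substr(tx_seq[loc$tx], loc$start, loc$end) <- seq1
      ids <- c(ids, sprintf("mir%04d", i)); sq <- c(sq, seq1)
      txs <- c(txs, tx_id[loc$tx]); sts <- c(sts, loc$start)
      ens <- c(ens, loc$end)
    }
    mirna <- stats::setNames(sq, ids)
    truth[["mirna"]] <- truth_chunk(ids, sq, "miRNA", "conserved_miRNA",
                                    txs, sts, ens)
  }

  ## structural ncRNAs and repeats (planted verbatim, reads are fragments)
  plant_set <- function(n_set, len_range, prefix) {
    out <- list()
    for (i in seq_len(n_set)) {
      len <- sample(len_range, 1L)
      loc <- plant_locus(planter, len)
      if (is.null(loc)) next
      out[[sprintf("%s%04d", prefix, i)]] <-
        list(seq = substr(tx_seq[loc$tx], loc$start, loc$end), loc = loc)
    }
    out
  }
  ncrna_raw <- if (n > 0) plant_set(cfg$n_ncrna, 70:120, "nc") else list()
  rep_raw <- if (n > 0) plant_set(cfg$n_repeat, 80:150, "rep") else list()
  ncrna <- vapply(ncrna_raw, `[[`, "", "seq")
  ncrna_subtype <- stats::setNames(rep_len(NCRNA_SUBTYPES, length(ncrna)),
                                   names(ncrna))
  repeats <- vapply(rep_raw, `[[`, "", "seq")

  ## ncRNA / repeat read fragments
  frag_from <- function(raw, class_by_name, label_by_name, frag_lens,
                        per_entry) {
    if (!length(raw)) return(empty_truth())
    nm <- rep(names(raw), each = per_entry)
    entry_len <- vapply(raw, function(e) nchar(e$seq), integer(1))[nm]
    fl <- sample(frag_lens, length(nm), replace = TRUE)
    keep <- fl <= entry_len
    nm <- nm[keep]; fl <- fl[keep]
    fs <- vapply(seq_along(nm), function(i)
      sample.int(entry_len[nm[i]] - fl[i] + 1L, 1L), integer(1))
    sq <- vapply(seq_along(nm), function(i)
      substr(raw[[nm[i]]]$seq, fs[i], fs[i] + fl[i] - 1L), character(1))
    locs <- lapply(raw, `[[`, "loc")
    tx_i <- vapply(nm, function(x) locs[[x]]$tx, integer(1))
    st0 <- vapply(nm, function(x) locs[[x]]$start, integer(1))
    frag_id <- stats::ave(seq_along(nm), nm, FUN = seq_along)
    truth_chunk(paste0(nm, "_f", frag_id), sq, class_by_name[nm],
                label_by_name[nm], tx_id[tx_i], st0 + fs - 1L,
                st0 + fs + fl - 2L)
  }
  truth[["ncrna"]] <- frag_from(ncrna_raw, ncrna_subtype, ncrna_subtype,
                                18:30, 8L)
  rep_class <- stats::setNames(rep("repeat", length(rep_raw)), names(rep_raw))
  truth[["repeat"]] <- frag_from(rep_raw, rep_class, rep_class, 24:35, 8L)

  ## hairpin precursors: arm + loop + reverse-complement arm, one 20-24 nt
  ## read inside the 5' arm (should be caught by the novel-miRNA filter)
  if (cfg$n_hairpin > 0 && n > 0) {
    ids <- sq <- txs <- character(0); sts <- ens <- integer(0)
    for (i in seq_len(cfg$n_hairpin)) {
      arm <- 30L; loop <- 6L
      loc <- plant_locus(planter, 2L * arm + loop)
      if (is.null(loc)) next
      arm_seq <- random_dna(1L, arm)
      hp <- paste0(arm_seq, random_dna(1L, loop), revcomp(arm_seq))
      substr(tx_seq[loc$tx], loc$start, loc$end) <- hp
      rl <- sample(20:24, 1L)
      rs <- sample.int(arm - rl + 1L, 1L)
      ids <- c(ids, sprintf("hp%03d", i))
      sq <- c(sq, substr(arm_seq, rs, rs + rl - 1L))
      txs <- c(txs, tx_id[loc$tx])
      sts <- c(sts, loc$start + rs - 1L)
      ens <- c(ens, loc$start + rs + rl - 2L)
    }
    truth[["hairpin"]] <- truth_chunk(ids, sq, "novel_miRNA", "novel_miRNA",
                                      txs, sts, ens)
  }

  ## piRNA pool
  pir <- plant_pirnas(cfg, tx_seq, planter)
  tx_seq <- pir$tx_seq
  truth[["pirna"]] <- pir$truth

  ## degradation decoys (unbiased 26-32 nt fragments: piRNA candidates for
  ## the cascade, but not biological piRNAs) and 33-35 nt "other" fragments
  extract_frags <- function(n_frag, len_range, prefix, class, label) {
    ids <- sq <- txs <- character(0); sts <- ens <- integer(0)
    for (i in seq_len(n_frag)) {
      loc <- plant_locus(planter, sample(len_range, 1L))
      if (is.null(loc)) next
      ids <- c(ids, sprintf("%s%05d", prefix, i))
      sq <- c(sq, substr(tx_seq[loc$tx], loc$start, loc$end))
      txs <- c(txs, tx_id[loc$tx]); sts <- c(sts, loc$start)
      ens <- c(ens, loc$end)
    }
    truth_chunk(ids, sq, class, label, txs, sts, ens)
  }
  if (n > 0) {
    truth[["decoy"]] <- extract_frags(cfg$n_decoy, 26:32, "dec", "other",
                                      "piRNA_candidate")
    truth[["other"]] <- extract_frags(cfg$n_other, 33:35, "oth", "other",
                                      "other")
  }

  ## unmapped reads: random sequences absent from the transcriptome
  n_unmapped <- min(200L, max(0L, cfg$n_other %/% 2L))
  if (n_unmapped > 0) {
    sq <- random_dna(n_unmapped, sample(20:35, n_unmapped, replace = TRUE))
    truth[["unmapped"]] <- truth_chunk(sprintf("unm%04d", seq_len(n_unmapped)),
                                       sq, "unmapped", "unmapped")
  }

  pool <- do.call(rbind, truth)
  if (is.null(pool)) pool <- empty_truth()
  dup <- duplicated(pool$sequence)
  if (any(dup)) {
    warning(sum(dup), " duplicate simulated sequences dropped from pool")
    pool <- pool[!dup, , drop = FALSE]
  }
  rownames(pool) <- NULL

  ## annotate piRNA rows with their gene-model feature (majority-overlap rule)
  is_p <- pool$class == "piRNA"
  if (any(is_p)) {
    pool$feature[is_p] <- assign_features(
      pool$transcript[is_p], pool$start[is_p], pool$end[is_p], gm,
      nchar(tx_seq)[match(pool$transcript[is_p], names(tx_seq))])
  }

  ## known-piRNA set: planted true sequences + letter-shuffled decoys
  pir_seqs <- pool$sequence[is_p]
  n_real <- min(cfg$n_known_real, length(pir_seqs))
  known_real <- if (n_real > 0) sample(pir_seqs, n_real) else character(0)
  known_decoy <- character(0)
  if (cfg$n_known_decoy > 0 && length(pir_seqs) > 0) {
    src <- sample(pir_seqs, cfg$n_known_decoy, replace = TRUE)
    known_decoy <- vapply(src, shuffle_seq, character(1), USE.NAMES = FALSE)
    bad <- known_decoy %in% pool$sequence
    for (i in which(bad)) {
      for (t in 1:20) {
        known_decoy[i] <- shuffle_seq(src[i])
        if (!known_decoy[i] %in% pool$sequence) break
      }
    }
    known_decoy <- known_decoy[!known_decoy %in% pool$sequence]
  }
  known <- c(known_real, known_decoy)
  if (length(known))
    names(known) <- sprintf("knp%04d", seq_along(known))
  known_truth <- c(rep(TRUE, length(known_real)), rep(FALSE, length(known_decoy)))
  names(known_truth) <- names(known)

  structure(list(transcriptome = tx_seq, gene_models = gm, mirna = mirna,
                 ncrna = structure(ncrna, subtype = ncrna_subtype),
                 repeats = repeats, known = known, known_truth = known_truth,
                 pool = pool, config = cfg),
            class = "reference_bundle")
}

plant_pirnas <- function(cfg, tx_seq, planter) {
  if (cfg$n_pirna == 0L || length(tx_seq) == 0L)
    return(list(tx_seq = tx_seq, truth = empty_truth()))
  if (any(nchar(tx_seq) < 32L))
    warning(sum(nchar(tx_seq) < 32L),
            " transcripts shorter than 32 nt skipped for piRNA placement")
  lens <- as.integer(names(cfg$pirna_length_weights))
  sex <- sample(SEX_CLASSES, cfg$n_pirna, replace = TRUE,
                prob = cfg$sex_class_proportions)
  np <- cfg$n_pirna
  sq <- txs <- strands <- character(np); sts <- ens <- integer(np)
  lfc <- numeric(np); kept <- logical(np)
  for (i in seq_len(np)) {
    len <- if (length(lens) == 1L) lens else
      sample(lens, 1L, prob = cfg$pirna_length_weights)
    loc <- plant_locus(planter, len)
    if (is.null(loc)) next
    s <- draw_pirna_seq(len, cfg$pirna_base_freqs, cfg$p_5prime_U,
                        cfg$p_pos10_A)
    antisense <- stats::runif(1) < cfg$antisense_fraction
    substr(tx_seq[loc$tx], loc$start, loc$end) <-
      if (antisense) revcomp(s) else s
    kept[i] <- TRUE
    sq[i] <- s; txs[i] <- names(tx_seq)[loc$tx]
    sts[i] <- loc$start; ens[i] <- loc$end
    strands[i] <- if (antisense) "-" else "+"
    lfc[i] <- switch(sex[i],
                     ovary_only = NA_real_, testis_only = NA_real_,
                     biased = sample(c(-1, 1), 1L) * cfg$biased_log2fc,
                     shared = 0)
  }
  truth <- truth_chunk(sprintf("pi%06d", which(kept)), sq[kept], "piRNA",
                       "piRNA_candidate", txs[kept], sts[kept], ens[kept],
                       strands[kept], sex_category = sex[kept],
                       true_log2fc = lfc[kept])
  list(tx_seq = tx_seq, truth = truth)
}

#' Simulate a piRNA pool into an existing reference bundle
#'
#' Plants `config$n_pirna` piRNA-like sequences (A/U-rich composition, forced
#' 5' U and position-10 A biases, sense/antisense mixture, sex-category
#' labels) at free loci of the bundle's transcriptome and returns the updated
#' bundle together with the piRNA truth records. [build_reference()] calls
#' this internally; it is exported for targeted experiments on the pool alone.
#'
#' @param config A [sim_config()].
#' @param ref A `"reference_bundle"`.
#' @return List with elements `ref` (bundle with edited transcriptome and
#'   extended pool) and `pool` (the new piRNA truth rows).
#' @export
simulate_pirna_pool <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"), inherits(ref, "reference_bundle"))
  if (length(ref$transcriptome) == 0L)
    stop("simulate_pirna_pool(): reference is empty")
  res <- with_seed(sub_seed(config$seed, "pirna_pool_extra"), {
    planter <- new_planter(nchar(ref$transcriptome))
    ## reserve loci already used by the bundle's pool
    occ <- ref$pool[!is.na(ref$pool$transcript), c("transcript", "start", "end")]
    for (k in seq_len(nrow(occ))) {
      ti <- match(occ$transcript[k], names(ref$transcriptome))
      planter$occ[[ti]] <- rbind(planter$occ[[ti]], c(occ$start[k], occ$end[k]))
    }
    plant_pirnas(config, ref$transcriptome, planter)
  })
  pool <- res$truth
  pool$id <- paste0("x", pool$id)
  ref$transcriptome <- res$tx_seq
  ref$pool <- rbind(ref$pool, pool)
  list(ref = ref, pool = pool)
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("<reference_bundle>", length(x$transcriptome), "transcripts |",
      sum(x$pool$class == "piRNA"), "planted piRNAs |",
      length(x$known), "known-piRNA entries\n")
  invisible(x)
}

## ---- file emission ---------------------------------------------------------

write_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path, width = 80L)
}

#' Write a gene-model table as GFF3
#'
#' Emits `five_prime_UTR` / `CDS` / `three_prime_UTR` spans with 1-based
#' closed coordinates (GFF3 convention).
#'
#' @param gene_models Data frame with columns transcript/feature/start/end.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gene_models <- function(gene_models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(gene_models)) {
    writeLines(sprintf("%s\tgonadpi_sim\t%s\t%d\t%d\t.\t+\t.\tID=%s",
                       gene_models$transcript, gene_models$feature,
                       gene_models$start, gene_models$end,
                       paste0(gene_models$transcript, ":", gene_models$feature)),
               con)
  }
  invisible(path)
}

#' Read a GFF3 gene-model file
#'
#' @param path A GFF3 file with five_prime_UTR/CDS/three_prime_UTR features.
#' @return Data frame with columns transcript/feature/start/end (1-based
#'   closed), the package's in-memory gene-model representation.
#' @export
read_gene_models <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  data.frame(transcript = as.character(gr$seqnames),
             feature = as.character(gr$type),
             start = gr$start, end = gr$end, stringsAsFactors = FALSE)
}

write_reference_files <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$transcriptome, file.path(dir, "transcriptome.fa"))
  write_fasta(bundle$mirna, file.path(dir, "mirna_mature.fa"))
  write_fasta(bundle$ncrna, file.path(dir, "ncrna.fa"))
  write_fasta(bundle$repeats, file.path(dir, "repeats.fa"))
  write_fasta(bundle$known, file.path(dir, "known_pirna.fa"))
  write_gene_models(bundle$gene_models, file.path(dir, "gene_models.gff3"))
  st <- attr(bundle$ncrna, "subtype")
  write_tsv(data.frame(id = names(bundle$ncrna),
                       subtype = if (length(st)) unname(st) else character(0)),
            file.path(dir, "ncrna_subtypes.tsv"))
  write_tsv(bundle$pool, file.path(dir, "sim_truth.tsv"))
  invisible(dir)
}
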