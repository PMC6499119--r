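## Simulated sequencing libraries and microarray intensities.

#' Simulate gonadal small-RNA FASTQ libraries from a reference bundle
#'
#' Draws per-library read counts for every sequence in the bundle's pool and
#' writes one FASTQ file per library (default two ovary and two testis
#' libraries, Phred+33, constant 'I' qualities). Counts are negative binomial
#' around sex-category-dependent means: `ovary_only` sequences have zero mean
#' in testis libraries (and vice versa), `biased` sequences have an
#' ovary/testis mean ratio of `2^true_log2fc`, `shared` sequences equal means.
#' The dispersion parameter interpolates to a Poisson model as it approaches
#' zero.
#'
#' @param config A [sim_config()].
#' @param bundle A `"reference_bundle"` from [build_reference()].
#' @param out_dir Directory for the FASTQ files (created if needed).
#' @param n_per_sex Libraries per sex (default 2, as in a two-testis
#'   two-ovary design).
#' @param degrade_fraction Fraction of reads given uniformly low (Q2)
#'   qualities, for QC-filter tests.
#' @param n_fraction Fraction of reads with one base replaced by N.
#' @param adapter Optional adapter sequence appended to every read (with 'I'
#'   qualities), for trimming tests.
#' @return List with `fastq` (named paths), `truth` (the pool table extended
#'   with expected and realised per-library counts) and `libraries`
#'   (data frame of library ids and sexes).
#' @export
simulate_libraries <- function(config, bundle, out_dir,
                               n_per_sex = 2L, degrade_fraction = 0,
                               n_fraction = 0, adapter = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(bundle, "reference_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  libs <- data.frame(
    library = c(sprintf("ovary%d", seq_len(n_per_sex)),
                sprintf("testis%d", seq_len(n_per_sex))),
    sex = rep(c("ovary", "testis"), each = n_per_sex),
    stringsAsFactors = FALSE)
  pool <- bundle$pool
  res <- with_seed(sub_seed(config$seed, "libraries"), {
    nseq <- nrow(pool)
    ## relative abundance: lognormal weights shared across libraries
    w <- if (nseq) stats::rlnorm(nseq, meanlog = 0, sdlog = 1) else numeric(0)
    half <- ifelse(is.na(pool$true_log2fc), 0, pool$true_log2fc / 2)
    m_ov <- w * 2^half
    m_te <- w * 2^(-half)
    m_ov[pool$sex_category == "testis_only"] <- 0
    m_te[pool$sex_category == "ovary_only"] <- 0
    lam <- matrix(0, nrow = nseq, ncol = nrow(libs),
                  dimnames = list(NULL, libs$library))
    counts <- lam
    for (j in seq_len(nrow(libs))) {
      m <- if (libs$sex[j] == "ovary") m_ov else m_te
      tot <- sum(m)
      lam[, j] <- if (tot > 0) config$depth_per_library * m / tot else 0
      counts[, j] <- if (config$nb_dispersion < 1e-8)
        stats::rpois(nseq, lam[, j])
      else
        stats::rnbinom(nseq, mu = lam[, j], size = 1 / config$nb_dispersion)
    }
    storage.mode(counts) <- "integer"
    fastq <- character(0)
    for (j in seq_len(nrow(libs))) {
      path <- file.path(out_dir, paste0(libs$library[j], ".fastq"))
      write_sim_fastq(pool$sequence, counts[, j], libs$library[j], path,
                      degrade_fraction, n_fraction, adapter)
      fastq[libs$library[j]] <- path
    }
    list(lam = lam, counts = counts, fastq = fastq)
  })
  truth <- pool
  if (nrow(pool)) {
    colnames(res$lam) <- paste0("expected_", libs$library)
    colnames(res$counts) <- paste0("count_", libs$library)
    truth <- cbind(pool, res$lam, res$counts)
  }
  write_tsv(truth, file.path(out_dir, "library_truth.tsv"))
  list(fastq = res$fastq, truth = truth, libraries = libs)
}

write_sim_fastq <- function(seqs, counts, lib, path, degrade_fraction = 0,
                            n_fraction = 0, adapter = NULL) {
  counts <- as.integer(counts)
  keep <- counts > 0
  reads <- rep(seqs[keep], counts[keep])
  if (length(reads)) reads <- sample(reads)  # shuffle read order
  if (!is.null(adapter) && length(reads))
    reads <- paste0(reads, adapter)
  quals <- strrep("I", nchar(reads))
  if (degrade_fraction > 0 && length(reads)) {
    bad <- stats::runif(length(reads)) < degrade_fraction
    quals[bad] <- strrep("#", nchar(reads[bad]))
  }
  if (n_fraction > 0 && length(reads)) {
    bad <- which(stats::runif(length(reads)) < n_fraction)
    for (i in bad) {
      p <- sample.int(nchar(reads[i]), 1L)
      substr(reads[i], p, p) <- "N"
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    ids <- sprintf("@%s:%07d", lib, seq_along(reads))
    writeLines(rbind(ids, reads, "+", quals), con)
  }
  invisible(path)
}

#' Simulate a replicated single-colour piRNA microarray
#'
#' For three ovary and three testis samples, gives every probe
#' `config$array_replicates` spots with intensity
#' `background + signal * 2^(group effect) * lognormal noise`. The
#' per-sample background (a scanner/gain offset, constant across the spots of
#' one sample) is emitted as a separate congruent matrix. A configurable
#' fraction of probes receives inflated replicate variability so the
#' downstream CV filter has true positives.
#'
#' @param config A [sim_config()].
#' @param probes Data frame with columns `probe` (ids) and `true_log2fc`
#'   (ovary-vs-testis effect; 0 for null probes, NA treated as 0).
#' @param out_dir Optional directory for TSV emission.
#' @param n_per_sex Samples per sex (default 3).
#' @return List with `raw` and `background` (probe x (sample,replicate)
#'   matrices with columns like `ovary1_r2`), `probes` (input plus the
#'   `highcv` flag and baseline signal), and `samples`.
#' @export
simulate_microarray <- function(config, probes, out_dir = NULL, n_per_sex = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$array_replicates < 1L) stop("array_replicates must be >= 1")
  if (nrow(probes) == 0L) stop("simulate_microarray(): empty probe set")
  if (is.null(probes$true_log2fc)) probes$true_log2fc <- 0
  probes$true_log2fc[is.na(probes$true_log2fc)] <- 0
  samples <- data.frame(
    sample = c(sprintf("ovary%d", seq_len(n_per_sex)),
               sprintf("testis%d", seq_len(n_per_sex))),
    sex = rep(c("ovary", "testis"), each = n_per_sex), stringsAsFactors = FALSE)
  r <- config$array_replicates
  cols <- as.vector(t(outer(samples$sample, seq_len(r),
                            function(s, k) paste0(s, "_r", k))))
  out <- with_seed(sub_seed(config$seed, "microarray"), {
    np <- nrow(probes)
    base_signal <- stats::rlnorm(np, meanlog = log(8), sdlog = 1)
    highcv <- stats::runif(np) < config$array_highcv_fraction
    bg_sample <- config$array_background_mean * stats::runif(nrow(samples), 0.8, 1.2)
    sdlog <- sqrt(log(1 + config$array_noise_cv^2))
    raw <- matrix(0, np, length(cols), dimnames = list(probes$probe, cols))
    bg <- raw
    for (si in seq_len(nrow(samples))) {
      eff <- ifelse(samples$sex[si] == "ovary", 1, -1) * probes$true_log2fc / 2
      mu <- base_signal * 2^eff
      for (k in seq_len(r)) {
        j <- (si - 1L) * r + k
        noise <- if (sdlog > 0) stats::rlnorm(np, -sdlog^2 / 2, sdlog) else rep(1, np)
        extra <- ifelse(highcv, stats::rlnorm(np, -0.6^2 / 2, 0.6), 1)
        raw[, j] <- bg_sample[si] + mu * noise * extra
        bg[, j] <- bg_sample[si]
      }
    }
    list(raw = raw, bg = bg, base_signal = base_signal, highcv = highcv)
  })
  probes$highcv <- out$highcv
  probes$base_signal <- out$base_signal
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(cbind(probe = rownames(out$raw), as.data.frame(out$raw)),
              file.path(out_dir, "array_raw.tsv"))
    write_tsv(cbind(probe = rownames(out$bg), as.data.frame(out$bg)),
              file.path(out_dir, "array_background.tsv"))
  }
  list(raw = out$raw, background = out$bg, probes = probes, samples = samples)
}

#' Draw piRNA-like training sequences (no planting)
#'
#' Sequences from the generator's piRNA sequence model (A/U-rich composition
#' plus 5' U and position-10 A biases), used to build classifier training
#' sets without touching a reference.
#'
#' @param config A [sim_config()] (its `pirna_*` fields are used).
#' @param n Number of sequences.
#' @param seed_tag Stage tag mixed into the seed stream.
#' @return Character vector of sequences.
#' @export
sim_pirna_like <- function(config, n, seed_tag = "pirna_like") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, seed_tag), {
    lens <- as.integer(names(config$pirna_length_weights))
    vapply(seq_len(n), function(i) {
      len <- if (length(lens) == 1L) lens else
        sample(lens, 1L, prob = config$pirna_length_weights)
      draw_pirna_seq(len, config$pirna_base_freqs,
                     config$p_5prime_U, config$p_pos10_A)
    }, character(1))
  })
}

#' Simulate a term-to-gene annotation map
#'
#' Assigns each gene one to three terms drawn from a Zipf-weighted term pool;
#' a plain stand-in for GO/KEGG style annotations.
#'
#' @param config A [sim_config()].
#' @param genes Character vector of gene ids.
#' @param n_terms Number of distinct terms.
#' @return Data frame with columns `term`, `gene`, `name`.
#' @export
sim_term_map <- function(config, genes, n_terms = 50L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(genes) == 0L)
    return(data.frame(term = character(0), gene = character(0),
                      name = character(0)))
  with_seed(sub_seed(config$seed, "term_map"), {
    terms <- sprintf("TERM:%04d", seq_len(n_terms))
    wt <- 1 / seq_len(n_terms)
    rows <- lapply(genes, function(g) {
      k <- sample(1:3, 1L)
      data.frame(term = sample(terms, k, prob = wt), gene = g,
                 stringsAsFactors = FALSE)
    })
    df <- unique(do.call(rbind, rows))
    df$name <- paste0("synthetic term ", sub("TERM:", "", df$term))
    rownames(df) <- NULL
    df
  })
}
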