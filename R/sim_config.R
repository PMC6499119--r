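#' Simulation configuration for synthetic gonadal small-RNA studies
#'
#' Builds and validates the parameter set of the synthetic-data generator.
#' Defaults describe a desk-scale gonadal small-RNA study: four libraries
#' (two ovary, two testis), a transcriptome of a few hundred assembled
#' transcripts, piRNA-like reads of 26-32 nt peaking at 26-30 nt with a
#' strong 5' U bias and position-10 A enrichment, miRNA-like 20-24 nt reads,
#' structural-ncRNA and repeat contaminants, and a replicated single-colour
#' microarray with background and per-sample gain.
#'
#' All sequences use the DNA alphabet; "U" in reports maps to T internally.
#'
#' @param seed Integer seed; every downstream stage derives its own stream
#'   from it, so identical configs yield byte-identical outputs.
#' @param n_genes Number of transcripts in the synthetic transcriptome.
#' @param transcript_length_range Integer pair, uniform transcript length
#'   range in nt.
#' @param utr_fractions Length-3 proportions of each transcript given to the
#'   5' UTR, CDS and 3' UTR (must sum to 1).
#' @param annotated_fraction Fraction of transcripts carrying a gene model;
#'   reads from the remainder are "unannotated" in feature summaries.
#' @param n_pirna Number of distinct piRNA-like sequences planted.
#' @param pirna_length_weights Named probabilities over lengths 26..32 nt
#'   (names are the lengths; must sum to 1).
#' @param pirna_base_freqs Base composition of planted piRNA loci (A/U-rich
#'   by default, as piRNA-producing loci are).
#' @param p_5prime_U Probability the first base of a piRNA is forced to U (T).
#' @param p_pos10_A Probability base 10 of a piRNA is forced to A.
#' @param antisense_fraction Probability a piRNA derives from the antisense
#'   strand of its transcript.
#' @param sex_class_proportions Named proportions over
#'   `ovary_only`, `testis_only`, `biased`, `shared` (must sum to 1).
#' @param biased_log2fc Absolute true log2 fold change of the `biased` class.
#' @param depth_per_library Expected read count per library.
#' @param nb_dispersion Negative-binomial dispersion of read counts
#'   (Poisson limit as it approaches 0).
#' @param n_mirna,n_ncrna,n_repeat Sizes of the mature-miRNA, structural
#'   ncRNA (rRNA/tRNA/snRNA/snoRNA) and repeat reference sets.
#' @param n_decoy Number of unbiased 26-32 nt transcript fragments
#'   (degradation-like piRNA-candidate decoys).
#' @param n_other Number of 33-35 nt mapped fragments outside every class.
#' @param n_hairpin Number of planted miRNA-precursor-like hairpins with a
#'   20-24 nt read in one arm (exercises the novel-miRNA filter).
#' @param n_known_real,n_known_decoy Composition of the known-piRNA set:
#'   planted true sequences plus letter-shuffled decoys.
#' @param array_replicates Spot replicates per probe per sample (default 3).
#' @param array_background_mean Mean scanner background intensity.
#' @param array_noise_cv Lognormal coefficient of variation of spot signal.
#' @param array_highcv_fraction Fraction of probes given inflated replicate
#'   variability (exercises the CV filter).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 300L,
                       transcript_length_range = c(500L, 2500L),
                       utr_fractions = c(five_prime_UTR = 0.2, CDS = 0.55,
                                         three_prime_UTR = 0.25),
                       annotated_fraction = 0.8,
                       n_pirna = 3000L,
                       pirna_length_weights = c(`26` = 0.16, `27` = 0.18,
                                                `28` = 0.20, `29` = 0.18,
                                                `30` = 0.12, `31` = 0.09,
                                                `32` = 0.07),
                       pirna_base_freqs = c(A = 0.30, C = 0.17, G = 0.18,
                                            T = 0.35),
                       p_5prime_U = 0.8,
                       p_pos10_A = 0.5,
                       antisense_fraction = 0.57,
                       sex_class_proportions = c(ovary_only = 0.44,
                                                 testis_only = 0.44,
                                                 biased = 0.06,
                                                 shared = 0.06),
                       biased_log2fc = 2,
                       depth_per_library = 40000L,
                       nb_dispersion = 0.2,
                       n_mirna = 150L,
                       n_ncrna = 80L,
                       n_repeat = 60L,
                       n_decoy = 600L,
                       n_other = 400L,
                       n_hairpin = 10L,
                       n_known_real = 93L,
                       n_known_decoy = 200L,
                       array_replicates = 3L,
                       array_background_mean = 30,
                       array_noise_cv = 0.1,
                       array_highcv_fraction = 0.05) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              transcript_length_range = as.integer(transcript_length_range),
              utr_fractions = utr_fractions,
              annotated_fraction = annotated_fraction,
              n_pirna = as.integer(n_pirna),
              pirna_length_weights = pirna_length_weights,
              pirna_base_freqs = pirna_base_freqs,
              p_5prime_U = p_5prime_U, p_pos10_A = p_pos10_A,
              antisense_fraction = antisense_fraction,
              sex_class_proportions = sex_class_proportions,
              biased_log2fc = biased_log2fc,
              depth_per_library = as.integer(depth_per_library),
              nb_dispersion = nb_dispersion,
              n_mirna = as.integer(n_mirna), n_ncrna = as.integer(n_ncrna),
              n_repeat = as.integer(n_repeat), n_decoy = as.integer(n_decoy),
              n_other = as.integer(n_other), n_hairpin = as.integer(n_hairpin),
              n_known_real = as.integer(n_known_real),
              n_known_decoy = as.integer(n_known_decoy),
              array_replicates = as.integer(array_replicates),
              array_background_mean = array_background_mean,
              array_noise_cv = array_noise_cv,
              array_highcv_fraction = array_highcv_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
      stop("sim_config: `", nm, "` must be a probability in [0, 1]")
  }
  chk_prob(cfg$p_5prime_U, "p_5prime_U")
  chk_prob(cfg$p_pos10_A, "p_pos10_A")
  chk_prob(cfg$antisense_fraction, "antisense_fraction")
  chk_prob(cfg$annotated_fraction, "annotated_fraction")
  chk_prob(cfg$array_highcv_fraction, "array_highcv_fraction")
  chk_prob(cfg$utr_fractions, "utr_fractions")
  chk_prob(cfg$sex_class_proportions, "sex_class_proportions")
  chk_prob(cfg$pirna_length_weights, "pirna_length_weights")
  chk_prob(cfg$pirna_base_freqs, "pirna_base_freqs")
  if (length(cfg$utr_fractions) != 3L ||
      abs(sum(cfg$utr_fractions) - 1) > 1e-8)
    stop("sim_config: `utr_fractions` must be 3 proportions that sum to 1")
  if (!setequal(names(cfg$sex_class_proportions),
                c("ovary_only", "testis_only", "biased", "shared")) ||
      abs(sum(cfg$sex_class_proportions) - 1) > 1e-8)
    stop("sim_config: `sex_class_proportions` must be named ",
         "ovary_only/testis_only/biased/shared and sum to 1")
  lw <- cfg$pirna_length_weights
  if (is.null(names(lw)) ||
      !all(as.integer(names(lw)) %in% 26:32) ||
      abs(sum(lw) - 1) > 1e-8)
    stop("sim_config: `pirna_length_weights` must sum to 1 with support in 26..32")
  if (abs(sum(cfg$pirna_base_freqs) - 1) > 1e-8 ||
      !setequal(names(cfg$pirna_base_freqs), c("A", "C", "G", "T")))
    stop("sim_config: `pirna_base_freqs` must be named ACGT and sum to 1")
  if (cfg$depth_per_library < 0L) stop("sim_config: depth must be >= 0")
  if (any(c(cfg$n_genes, cfg$n_pirna, cfg$n_mirna, cfg$n_ncrna, cfg$n_repeat,
            cfg$n_decoy, cfg$n_other, cfg$n_hairpin) < 0L))
    stop("sim_config: element counts must be >= 0")
  if (length(cfg$transcript_length_range) != 2L ||
      cfg$transcript_length_range[1] > cfg$transcript_length_range[2] ||
      cfg$transcript_length_range[1] < 50L)
    stop("sim_config: `transcript_length_range` must be an increasing pair >= 50")
  if (cfg$array_replicates < 1L)
    stop("sim_config: `array_replicates` must be >= 1")
  if (cfg$nb_dispersion < 0) stop("sim_config: `nb_dispersion` must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_genes, "transcripts |",
      x$n_pirna, "piRNAs | depth", x$depth_per_library, "per library\n")
  invisible(x)
}
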