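## End-to-end pipeline orchestration on synthetic data, with a run report.

#' Fingerprint of a simulation configuration
#'
#' Stable 8-hex-digit hash of the serialised config; changes iff any
#' semantic field changes.
#'
#' @param config A [sim_config()].
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  fields <- config[order(names(config))]
  fnv1a(as.character(jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA)))
}

#' Run the full gonadal piRNA pipeline on synthetic data
#'
#' Simulates a study (reference + libraries), then executes every analysis
#' stage in cascade order: cleaning and unique-read collapsing, exact
#' mapping, the annotation cascade, classifier training and candidate
#' classification, known-piRNA homolog matching, signature statistics,
#' sequencing expression calls, microarray simulation and pipeline,
#' clustering and platform concordance, piRNA-generating genes, sex
#' partition and term enrichment. Because the simulator carries ground
#' truth, the report also contains recovery metrics (cascade label
#' agreement, classifier sensitivity/specificity, microarray detection
#' sensitivity and false-positive rate).
#'
#' A fixed config (including its seed) yields an identical report.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; stage outputs (TSV) and the JSON report
#'   are written beneath it.
#' @param thresholds A [thresholds_config()] list.
#' @param n_train Training sequences per class for the k-mer classifier.
#' @return The run report (list), invisibly; also written as
#'   `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("gonadpi_"),
                         thresholds = thresholds_config(), n_train = 1500L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(tool = "gonadpi", version = as.character(utils::packageVersion("gonadpi")),
                 config_hash = config_hash(config), seed = config$seed)

  ref <- stage("simulate_reference",
               build_reference(config, file.path(out_dir, "reference")))
  libs <- stage("simulate_libraries",
                simulate_libraries(config, ref, file.path(out_dir, "fastq")))
  cc <- stage("clean_and_collapse", clean_and_collapse(libs$fastq))
  write_tsv(cc$reads, file.path(out_dir, "unique_reads.tsv"))
  write_tsv(cc$qc, file.path(out_dir, "library_qc.tsv"))
  report$n_unique_reads <- nrow(cc$reads)
  report$library_qc <- cc$qc

  index <- stage("index", build_exact_index(ref$transcriptome))
  casc <- stage("annotate_cascade",
                suppressWarnings(annotate_cascade(cc$reads, ref, index)))
  write_tsv(casc$summary, file.path(out_dir, "annotation_summary.tsv"))
  report$annotation <- casc$summary

  ## cascade recovery against simulator truth
  truth_idx <- match(casc$reads$sequence, ref$pool$sequence)
  expected <- ref$pool$expected_label[truth_idx]
  observed <- ifelse(casc$reads$mapped, casc$reads$label, "unmapped")
  known_truth_rows <- !is.na(expected)
  report$cascade_recovery <- list(
    n = sum(known_truth_rows),
    agreement = sum(observed[known_truth_rows] == expected[known_truth_rows]),
    agreement_pct = if (any(known_truth_rows))
      pct_value(sum(observed[known_truth_rows] == expected[known_truth_rows]),
                sum(known_truth_rows)) else NA_real_)

  ## classifier: train on generator draws, classify cascade candidates
  model <- stage("train_classifier", {
    pos <- sim_pirna_like(config, n_train, "train_pos")
    neg <- with_seed(sub_seed(config$seed, "train_neg"), {
      lens <- sample(as.integer(names(config$pirna_length_weights)), n_train,
                     replace = TRUE, prob = config$pirna_length_weights)
      random_dna(n_train, lens)
    })
    train_fisher(pos, neg)
  })
  write_model(model, file.path(out_dir, "classifier_model.json"))

  cand_rows <- which(!is.na(casc$reads$label) &
                       casc$reads$label == "piRNA_candidate")
  cls <- stage("classify", classify_pirna(casc$reads$sequence[cand_rows], model))
  write_tsv(cls, file.path(out_dir, "classifier_predictions.tsv"))
  predicted <- cls$sequence[cls$predicted]
  report$n_candidates <- nrow(cls)
  report$n_predicted_pirna <- length(predicted)

  if (nrow(cls)) {
    truth_cls <- ref$pool$class[match(cls$sequence, ref$pool$sequence)]
    is_pos <- !is.na(truth_cls) & truth_cls == "piRNA"
    report$classifier_recovery <- list(
      n_true = sum(is_pos), n_null = sum(!is_pos),
      sensitivity = if (any(is_pos)) mean(cls$predicted[is_pos]) else NA_real_,
      specificity = if (any(!is_pos)) mean(!cls$predicted[!is_pos]) else NA_real_)
  }

  ## known-piRNA homologs
  mk <- match_known(predicted, ref$known)
  report$known_homologs <- list(hits = nrow(mk),
                                planted = sum(ref$known_truth))

  ## signature statistics
  if (length(predicted)) {
    pred_rows <- match(predicted, cc$reads$sequence)
    pbf <- position_base_frequencies(predicted, cc$reads$total[pred_rows])
    hits_pred <- find_exact_hits(index, predicted)
    strand <- strand_composition(hits_pred)
    feat <- feature_distribution(hits_pred, ref$gene_models,
                                 nchar(ref$transcriptome))
    write_tsv(feat$table, file.path(out_dir, "feature_distribution.tsv"))
    report$signatures <- list(
      fraction_U_at_1 = unname(pbf$fraction_U_at_1),
      fraction_A_at_10 = unname(pbf$fraction_A_at_10),
      strand = strand,
      features = feat$table)
    ldist <- length_distribution(casc$reads$length,
                                 ifelse(is.na(casc$reads$label), "unmapped",
                                        casc$reads$label),
                                 casc$reads$total)
    write_tsv(ldist, file.path(out_dir, "length_distribution.tsv"))
  }

  ## sequencing expression
  expr <- if (length(predicted))
    seq_expression_table(cc$reads[match(predicted, cc$reads$sequence), ],
                         libs$libraries, thresholds)
  else data.frame()
  if (nrow(expr)) write_tsv(expr, file.path(out_dir, "seq_expression.tsv"))
  tally <- function(cat) sum(expr$category == cat)
  if (nrow(expr)) {
    tot <- nrow(expr)
    report$sex_expression <- list(
      total = tot,
      ovary_specific = list(count = tally("ovary_specific"),
                            pct = pct_value(tally("ovary_specific"), tot)),
      testis_specific = list(count = tally("testis_specific"),
                             pct = pct_value(tally("testis_specific"), tot)),
      shared = list(count = tally("shared"),
                    pct = pct_value(tally("shared"), tot)),
      low_count = list(count = tally("low_count"),
                       pct = pct_value(tally("low_count"), tot)),
      sex_specific_pct = pct_value(tally("ovary_specific") +
                                     tally("testis_specific"), tot))
  }

  ## microarray validation
  if (nrow(expr)) {
    cand <- select_array_candidates(expr, thresholds)
    report$n_array_candidates <- nrow(cand)
    if (nrow(cand) >= 2L) {
      truth_lfc <- ref$pool$true_log2fc[match(cand$sequence, ref$pool$sequence)]
      truth_cat <- ref$pool$sex_category[match(cand$sequence, ref$pool$sequence)]
      ## array-scale truth effect: biased keep their log2FC; one-sex piRNAs
      ## get a strong +/-4 presence effect; everything else is null
      eff <- ifelse(is.na(truth_cat), 0,
             ifelse(truth_cat == "ovary_only", 4,
             ifelse(truth_cat == "testis_only", -4,
                    ifelse(is.na(truth_lfc), 0, truth_lfc))))
      probes <- data.frame(probe = sprintf("ASY-piR-%05d", seq_len(nrow(cand))),
                           sequence = cand$sequence, true_log2fc = eff,
                           stringsAsFactors = FALSE)
      arr <- stage("simulate_microarray",
                   simulate_microarray(config, probes,
                                       file.path(out_dir, "array")))
      ap <- stage("array_pipeline",
                  suppressWarnings(array_pipeline(arr$raw, arr$background,
                                                  thresholds)))
      write_tsv(ap$records, file.path(out_dir, "array_records.tsv"))
      biased <- ap$records$category %in% c("ovary_up", "testis_up")
      report$array <- list(
        n_probes = nrow(ap$records),
        filtered = sum(ap$records$category == "filtered"),
        ovary_up = sum(ap$records$category == "ovary_up"),
        testis_up = sum(ap$records$category == "testis_up"),
        co_expressed = sum(ap$records$category == "co_expressed"),
        nonsignificant = sum(ap$records$category == "nonsignificant"))
      ## detection vs planted truth among unfiltered probes
      unf <- ap$records$category != "filtered"
      true_de <- abs(arr$probes$true_log2fc) >= thresholds$array$lfc
      if (any(unf & true_de) && any(unf & !true_de))
        report$array_recovery <- list(
          sensitivity = mean(biased[unf & true_de]),
          fpr = mean(biased[unf & !true_de]),
          n_true = sum(unf & true_de), n_null = sum(unf & !true_de))
      ## clades of sex-biased probes
      med_cols <- grep("^median_", names(ap$records), value = TRUE)
      if (sum(biased) >= 2L) {
        med <- as.matrix(ap$records[biased, med_cols])
        rownames(med) <- ap$records$probe[biased]
        clades <- suppressWarnings(cluster_biased(med, k = 10L))
        report$clades <- as.list(table(clades))
      }
      ## platform concordance on the sex-biased probes
      if (sum(biased) >= 3L) {
        sl <- expr$log2fc[match(probes$sequence[biased], expr$sequence)]
        conc <- platform_concordance(sl, ap$records$log2fc[biased])
        report$concordance <- conc
      }
    }
  }

  ## piRNA-generating genes and enrichment
  if (length(predicted)) {
    mg <- map_pirnas_to_genes(predicted, index)
    write_tsv(mg$table, file.path(out_dir, "pirna_genes.tsv"))
    report$genes <- mg$summary
    sp <- sex_partition(mg$hits, expr)
    report$gene_sex_partition <- as.list(sp$counts)
    tmap <- sim_term_map(config, index$names)
    study <- sp$genes$gene
    if (length(study)) {
      enr <- enrich_terms(study, index$names, tmap)
      write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
      report$enrichment <- list(n_terms = nrow(enr),
                                n_enriched = sum(enr$enriched))
    }
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null", force = TRUE)
  invisible(report)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may carry a `sim:` block (fields of [sim_config()]) and a
#' `thresholds:` block overriding [thresholds_config()] entries.
#'
#' @param path YAML file.
#' @return List with `config` (a `sim_config`) and `thresholds`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$sim
  if (!is.null(sim)) {
    for (f in c("utr_fractions", "pirna_length_weights", "pirna_base_freqs",
                "sex_class_proportions"))
      if (!is.null(sim[[f]])) sim[[f]] <- unlist(sim[[f]])
  }
  cfg <- do.call(sim_config, if (is.null(sim)) list() else sim)
  th <- thresholds_config()
  for (side in names(y$thresholds))
    for (f in names(y$thresholds[[side]]))
      th[[side]][[f]] <- unlist(y$thresholds[[side]][[f]])
  list(config = cfg, thresholds = th)
}
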