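# Annotation cascade: priority order, label partition, Table-1-style summary.

make_toy_bundle <- function() {
  # one transcript hosting a miRNA-like 22-mer, an rRNA-like 60-mer and free
  # sequence for candidates
  withr::local_seed(99)
  mir <- paste0("T", paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = ""))
  rrna <- random_seq(1, 60)
  spacer1 <- random_seq(1, 50); spacer2 <- random_seq(1, 80)
  tx <- paste0(spacer1, mir, spacer2, rrna, random_seq(1, 60))
  structure(list(transcriptome = c(tx1 = tx),
                 gene_models = data.frame(transcript = character(0),
                                          feature = character(0),
                                          start = integer(0), end = integer(0)),
                 mirna = c(m1 = mir),
                 ncrna = structure(c(n1 = rrna), subtype = c(n1 = "rRNA")),
                 repeats = character(0), known = character(0),
                 pool = data.frame()),
            class = "reference_bundle")
}

reads_table <- function(seqs, counts = NULL) {
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  data.frame(sequence = seqs, length = nchar(seqs), lib1 = counts,
             total = counts, stringsAsFactors = FALSE)
}

test_that("database priority places shared reads in the higher class", {
  b <- make_toy_bundle()
  mir <- b$mirna[["m1"]]
  # plant the miRNA inside the ncRNA set too: conserved_miRNA must win
  b2 <- b
  b2$ncrna <- structure(c(n1 = paste0(b$ncrna[["n1"]], mir)),
                        subtype = c(n1 = "rRNA"))
  res <- annotate_cascade(reads_table(mir), b2)
  expect_identical(res$reads$label, "conserved_miRNA")
})

test_that("remaining mapped reads are labelled by length and sets partition counts", {
  b <- make_toy_bundle()
  tx <- b$transcriptome[[1]]
  cand28 <- substr(tx, 140, 167)             # inside the rRNA? pick free zone
  cand28 <- substr(tx, 2, 29)                # spacer region, 28 nt
  frag_r <- substr(b$ncrna[["n1"]], 5, 30)   # 26-nt rRNA fragment
  other34 <- substr(tx, 10, 43)              # 34 nt -> other
  unmapped <- strrep("ACGTT", 6)             # 30 nt, not in tx (checked below)
  expect_identical(length(find_all_occurrences(unmapped, tx)), 0L)
  rt <- reads_table(c(b$mirna[["m1"]], frag_r, cand28, other34, unmapped),
                    counts = c(4L, 3L, 2L, 1L, 5L))
  res <- annotate_cascade(rt, b)
  labels <- res$reads$label
  expect_identical(labels[1], "conserved_miRNA")
  expect_identical(labels[2], "rRNA")
  expect_identical(labels[3], "piRNA_candidate")
  expect_identical(labels[4], "other")
  expect_true(is.na(labels[5]) && !res$reads$mapped[5])

  s <- res$summary
  expect_identical(s$mapped, 4L + 3L + 2L + 1L)
  # partition invariant: label counts sum to mapped count
  lab_cols <- intersect(colnames(s),
                        c("conserved_miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                          "repeat", "novel_miRNA", "piRNA_candidate", "other"))
  expect_identical(sum(unlist(s[1, lab_cols])), s$mapped)
  # percentages of mapped, half-up 2 dp, summing to ~100
  expect_equal(s$conserved_miRNA_pct, pct_value(4, 10))
  pct_cols <- paste0(lab_cols, "_pct")
  expect_lt(abs(sum(unlist(s[1, pct_cols])) - 100), 0.05)
})

test_that("summary handles empty classes and zero mapped totals", {
  b <- make_toy_bundle()
  res <- annotate_cascade(reads_table(character(0)), b)
  expect_warning(summarize_annotation(res$reads, "lib1"), "no mapped")
  s <- suppressWarnings(summarize_annotation(res$reads, "lib1"))
  expect_identical(s$mapped, 0L)
  expect_identical(s$piRNA_candidate_pct, 0)
})

test_that("cascade labels agree with simulator expected labels on synthetic data", {
  cfg <- small_config(seed = 77L, depth_per_library = 4000L)
  ref <- build_reference(cfg)
  libs <- simulate_libraries(cfg, ref, withr::local_tempdir())
  cc <- clean_and_collapse(libs$fastq)
  res <- annotate_cascade(cc$reads, ref)
  expected <- ref$pool$expected_label[match(res$reads$sequence,
                                            ref$pool$sequence)]
  observed <- ifelse(res$reads$mapped, res$reads$label, "unmapped")
  ok <- !is.na(expected)
  expect_gt(sum(ok), 250)
  expect_gte(mean(observed[ok] == expected[ok]), 0.95)
})
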