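# Synthetic-data generator: reference construction, piRNA pool, libraries,
# microarray. Ground-truth consistency is what the rest of the suite leans on.

test_that("config validation rejects malformed parameter sets", {
  expect_s3_class(small_config(), "sim_config")
  expect_error(small_config(utr_fractions = c(0.5, 0.6, 0.2)), "sum to 1")
  expect_error(small_config(p_5prime_U = 1.4), "probability")
  expect_error(small_config(pirna_length_weights = c(`20` = 1)), "26..32")
  expect_error(small_config(depth_per_library = -5), ">= 0")
  expect_error(small_config(array_replicates = 0), "array_replicates")
  expect_error(small_config(sex_class_proportions =
                              c(ovary_only = 1, testis_only = 0, biased = 0.2,
                                shared = 0)), "sum to 1")
})

test_that("empty reference is valid and deterministic outputs are byte-identical", {
  cfg0 <- small_config(n_genes = 0L, n_pirna = 0L, n_mirna = 0L, n_ncrna = 0L,
                       n_repeat = 0L, n_decoy = 0L, n_other = 0L,
                       n_hairpin = 0L)
  d0 <- withr::local_tempdir()
  ref0 <- build_reference(cfg0, d0)
  expect_length(ref0$transcriptome, 0)
  expect_identical(nrow(ref0$gene_models), 0L)
  expect_true(file.exists(file.path(d0, "transcriptome.fa")))
  expect_identical(readLines(file.path(d0, "gene_models.gff3")),
                   "##gff-version 3")

  cfg <- small_config(seed = 42L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  build_reference(cfg, d1); build_reference(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("gene-model spans partition each transcript at the configured fractions", {
  cfg <- sim_config(seed = 3L, n_genes = 10L,
                    transcript_length_range = c(1000L, 1000L),
                    utr_fractions = c(0.1, 0.7, 0.2), annotated_fraction = 1,
                    n_pirna = 0L, n_mirna = 0L, n_ncrna = 0L, n_repeat = 0L,
                    n_decoy = 0L, n_other = 0L, n_hairpin = 0L)
  ref <- build_reference(cfg)
  gm <- ref$gene_models
  expect_identical(length(unique(gm$transcript)), 10L)
  for (tx in unique(gm$transcript)) {
    spans <- gm[gm$transcript == tx, ]
    spans <- spans[order(spans$start), ]
    # exhaustive, non-overlapping partition of [1, 1000]
    expect_identical(spans$start, c(1L, spans$end[1] + 1L, spans$end[2] + 1L))
    expect_identical(spans$end[3], 1000L)
    lens <- spans$end - spans$start + 1L
    expect_true(all(abs(lens - c(100L, 700L, 200L)) <= 1L))
  }
})

test_that("gene models survive a GFF3 round trip", {
  ref <- build_reference(small_config(seed = 11L))
  d <- withr::local_tempdir()
  p <- file.path(d, "gm.gff3")
  write_gene_models(ref$gene_models, p)
  back <- read_gene_models(p)
  ord <- function(x) {
    x <- x[order(x$transcript, x$start), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(back), ord(ref$gene_models))
})

test_that("piRNA pool carries the forced sequence biases", {
  cfg <- small_config(seed = 5L, n_pirna = 100L, p_5prime_U = 1.0)
  ref <- build_reference(cfg)
  pir <- ref$pool[ref$pool$class == "piRNA", ]
  expect_gte(nrow(pir), 95)
  expect_true(all(substr(pir$sequence, 1, 1) == "T"))
  expect_true(all(nchar(pir$sequence) %in% 26:32))

  cfg2 <- sim_config(seed = 6L, n_genes = 400L, n_pirna = 10000L,
                     p_5prime_U = 0.8, n_mirna = 0L, n_ncrna = 0L,
                     n_repeat = 0L, n_decoy = 0L, n_other = 0L, n_hairpin = 0L,
                     transcript_length_range = c(1500L, 2500L))
  pir2 <- build_reference(cfg2)$pool
  pir2 <- pir2[pir2$class == "piRNA", ]
  frac_u <- mean(substr(pir2$sequence, 1, 1) == "T")
  se <- sqrt(0.8 * 0.2 / nrow(pir2))
  expect_lt(abs(frac_u - 0.8), 3 * se)
})

test_that("every planted sequence is recoverable from its origin coordinates", {
  ref <- build_reference(small_config(seed = 9L))
  pool <- ref$pool[!is.na(ref$pool$transcript), ]
  expect_false(any(duplicated(pool$sequence)))
  extracted <- substr(ref$transcriptome[pool$transcript], pool$start, pool$end)
  anti <- pool$strand == "-"
  extracted[anti] <- revcomp(extracted[anti])
  expect_identical(unname(extracted), pool$sequence)
})

test_that("simulate_pirna_pool extends a bundle without disturbing planted loci", {
  cfg <- small_config(seed = 21L, n_pirna = 50L)
  ref <- build_reference(cfg)
  res <- simulate_pirna_pool(small_config(seed = 22L, n_pirna = 40L), ref)
  expect_gte(nrow(res$pool), 35)
  pool <- res$ref$pool[!is.na(res$ref$pool$transcript), ]
  extracted <- substr(res$ref$transcriptome[pool$transcript],
                      pool$start, pool$end)
  anti <- pool$strand == "-"
  extracted[anti] <- revcomp(extracted[anti])
  expect_identical(unname(extracted), pool$sequence)
})

test_that("known-piRNA set mixes planted sequences with shuffled decoys", {
  ref <- build_reference(small_config(seed = 13L, n_known_real = 20L,
                                      n_known_decoy = 30L))
  kt <- ref$known_truth
  expect_identical(sum(kt), 20L)
  pir <- ref$pool$sequence[ref$pool$class == "piRNA"]
  expect_true(all(ref$known[kt] %in% pir))
  expect_false(any(ref$known[!kt] %in% ref$pool$sequence))
})
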