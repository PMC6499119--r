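# Signature statistics: positional base usage, lengths, strand, features.

test_that("positional frequencies follow the ragged-length rule", {
  pf <- position_base_frequencies("TACGTACGTACGTACGTACGTACGTA")
  expect_equal(pf$fraction_U_at_1, 1)
  # mixed 26/30 nt reads: positions 27-30 only from the 30-mer
  s26 <- paste0("T", strrep("A", 25))
  s30 <- paste0("T", strrep("A", 8), "A", strrep("A", 16), "GGGG")
  pf2 <- position_base_frequencies(c(s26, s30), counts = c(3, 1))
  expect_equal(unname(pf2$freq[27, "G"]), 1)
  expect_equal(pf2$n_at_position[27], 1)
  expect_equal(pf2$n_at_position[26], 4)
  # defined rows sum to 1
  sums <- rowSums(pf2$freq[!is.na(pf2$freq[, 1]), ])
  expect_equal(unname(sums), rep(1, length(sums)))
  # unweighted mode ignores counts
  pf3 <- position_base_frequencies(c(s26, s30), counts = c(3, 1),
                                   weight_by_counts = FALSE)
  expect_equal(pf3$n_at_position[26], 2)
  expect_error(position_base_frequencies(character(0)), "empty")
})

test_that("simulator bias parameters are recovered from the pool", {
  cfg <- sim_config(seed = 71L, n_genes = 500L, n_pirna = 12000L,
                    p_5prime_U = 0.8, p_pos10_A = 0.6,
                    antisense_fraction = 0.5,
                    n_mirna = 0L, n_ncrna = 0L, n_repeat = 0L, n_decoy = 0L,
                    n_other = 0L, n_hairpin = 0L,
                    transcript_length_range = c(1500L, 2500L))
  ref <- build_reference(cfg)
  pir <- ref$pool[ref$pool$class == "piRNA", ]
  n <- nrow(pir)
  pf <- position_base_frequencies(pir$sequence)
  expect_lt(abs(pf$fraction_U_at_1 - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  expect_lt(abs(pf$fraction_A_at_10 - 0.6), 3 * sqrt(0.6 * 0.4 / n))
  expect_lt(abs(mean(pir$strand == "-") - 0.5), 3 * sqrt(0.25 / n))
})

test_that("length distributions normalise per group and modal bin is 26-30", {
  ld <- length_distribution(c(28, 28, 28), rep("g", 3))
  expect_equal(ld$pct, 100)
  cfg <- small_config(seed = 72L)
  pir <- build_reference(cfg)$pool
  pir <- pir[pir$class == "piRNA", ]
  ld2 <- length_distribution(nchar(pir$sequence), rep("pool", nrow(pir)))
  expect_equal(sum(ld2$pct), 100)
  expect_true(ld2$length[which.max(ld2$pct)] %in% 26:30)
  expect_warning(length_distribution(integer(0), character(0)), NA)
  expect_warning(length_distribution(c(1, 2), c("a", "b"), counts = c(1, 0)),
                 "empty")
})

test_that("strand composition reproduces the percentage convention", {
  hits <- data.frame(query = 1:4, sequence = letters[1:4],
                     transcript = "t1", start = 1:4, end = 29:32,
                     strand = c("+", "+", "-", "+"))
  sc <- strand_composition(hits)
  expect_identical(sc$sense, 3L); expect_identical(sc$antisense, 1L)
  expect_equal(sc$sense_pct, 75); expect_equal(sc$antisense_pct, 25)
  # worked example at report precision
  expect_identical(percentage(376487, 875679), "42.99%")
  expect_identical(percentage(499192, 875679), "57.01%")
  # multi-mapping resolves to the lexicographically smallest hit
  multi <- data.frame(query = c(1, 1), sequence = "a",
                      transcript = c("t2", "t1"), start = c(1, 5),
                      end = c(28, 32), strand = c("+", "-"))
  expect_identical(strand_composition(multi)$antisense, 1L)
})

test_that("feature assignment follows the majority-overlap rule with CDS tie priority", {
  gm <- data.frame(transcript = "t1",
                   feature = c("five_prime_UTR", "CDS", "three_prime_UTR"),
                   start = c(1L, 101L, 801L), end = c(100L, 800L, 1000L))
  hit <- list(transcript = "t1", start = 150L, end = 177L)
  expect_identical(feature_assignment(hit, gm), "CDS")
  # 17 nt in CDS vs 11 nt in 3' UTR -> CDS
  hit2 <- list(transcript = "t1", start = 784L, end = 811L)
  expect_identical(feature_assignment(hit2, gm), "CDS")
  # exact tie (14/14) -> CDS beats 3' UTR
  hit3 <- list(transcript = "t1", start = 787L, end = 814L)
  expect_identical(feature_assignment(hit3, gm), "CDS")
  # no model for the transcript -> unannotated
  expect_identical(feature_assignment(list(transcript = "t9", start = 1L,
                                           end = 28L), gm), "unannotated")
  # beyond transcript end -> corrupt input
  expect_error(feature_assignment(list(transcript = "t1", start = 990L,
                                       end = 1017L), gm,
                                  tx_len = c(t1 = 1000L)), "beyond")
})

test_that("feature distribution conserves totals and percentage arithmetic", {
  withr::local_seed(73)
  gm <- data.frame(transcript = "t1",
                   feature = c("five_prime_UTR", "CDS", "three_prime_UTR"),
                   start = c(1L, 201L, 1401L), end = c(200L, 1400L, 2000L))
  tx <- c(t1 = random_seq(1, 2000), t2 = random_seq(1, 500))
  idx <- build_exact_index(tx)
  qs <- c(substr(tx[[1]], 50, 77), substr(tx[[1]], 500, 527),
          substr(tx[[1]], 1500, 1529), substr(tx[[2]], 100, 127))
  fd <- feature_distribution(find_exact_hits(idx, qs), gm, nchar(tx))
  expect_identical(sum(fd$table$count), 4L)
  expect_equal(fd$table$pct[fd$table$feature == "CDS"], 25)
  # the reported worked percentages follow the same convention
  expect_equal(pct_value(265499, 875679), 30.32)
  expect_equal(pct_value(31949, 875679), 3.65)
  expect_equal(pct_value(73802, 875679), 8.43)
})
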