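# Microarray pipeline: normalization identities, ANOVA, categories,
# clustering, concordance.

spot_names <- function(n_per_sex = 3, reps = 3) {
  samples <- c(sprintf("ovary%d", 1:n_per_sex), sprintf("testis%d", 1:n_per_sex))
  as.vector(t(outer(samples, 1:reps, function(s, k) paste0(s, "_r", k))))
}

toy_array <- function(values, probes = paste0("p", seq_len(nrow(values)))) {
  colnames(values) <- spot_names()
  rownames(values) <- probes
  values
}

test_that("quantile normalization: worked example, fixed point, idempotence", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  qn <- limma::normalizeQuantiles(x, ties = TRUE)
  expect_equal(qn[, 1], c(2.5, 3.5, 4.5))
  expect_equal(qn[, 2], c(2.5, 3.5, 4.5))
  # identical columns are a fixed point
  y <- matrix(rep(c(7, 1, 4), 4), 3, 4)
  expect_equal(limma::normalizeQuantiles(y, ties = TRUE), y,
               ignore_attr = TRUE)
  # after normalization all sorted columns coincide; re-applying is identity
  withr::local_seed(91)
  z <- matrix(rexp(60, 1 / 50), 10, 6)
  qz <- limma::normalizeQuantiles(z, ties = TRUE)
  ref_sorted <- sort(qz[, 1])
  for (j in 2:6) expect_equal(sort(qz[, j]), ref_sorted)
  expect_equal(limma::normalizeQuantiles(qz, ties = TRUE), qz,
               ignore_attr = TRUE)
})

test_that("two-group ANOVA equals the pooled-variance t test (F = t^2)", {
  an <- two_group_anova(c(1, 2, 3), c(4, 5, 6))
  expect_equal(an$F, 13.5)
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(an$p, tt$p.value, tolerance = 1e-12)
  withr::local_seed(92)
  for (i in 1:50) {
    x <- rnorm(3); y <- rnorm(3, 1)
    an <- two_group_anova(x, y)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(an$p, tt$p.value, tolerance = 1e-9)
    # and the classical aov decomposition agrees
    av <- summary(stats::aov(v ~ g, data.frame(v = c(x, y),
                                               g = rep(c("a", "b"), each = 3))))
    expect_equal(an$F, av[[1]]$`F value`[1], tolerance = 1e-9)
  }
})

test_that("pipeline steps: subtraction floor, CV filter, category partition", {
  withr::local_seed(93)
  n <- 60
  base <- rlnorm(n, log(20), 0.8)
  raw <- toy_array(matrix(rep(base, 18), n, 18) *
                     matrix(rlnorm(n * 18, 0, 0.05), n, 18) + 30)
  bg <- raw; bg[] <- 30
  # probe 1: make one sample's replicates wildly variable -> filtered
  raw[1, 1:3] <- 30 + c(1, 200, 800)
  # probe 2: raw below background -> floored with warning
  raw[2, ] <- 25
  expect_warning(res <- array_pipeline(raw, bg), "floored")
  rec <- res$records
  expect_identical(rec$category[1], "filtered")
  expect_true(all(res$normalized >= 0))
  # every probe gets exactly one category
  expect_true(all(rec$category %in% c("filtered", "ovary_up", "testis_up",
                                      "co_expressed", "nonsignificant")))
  # congruence violations are rejected
  expect_error(array_pipeline(raw, bg[, 1:6]), "congruent")
  expect_error(array_pipeline(raw, `rownames<-`(bg, rev(rownames(bg)))),
               "congruent")
})

test_that("planted fold changes are called with the expected signs", {
  cfg <- small_config(seed = 94L, array_noise_cv = 0.08,
                      array_highcv_fraction = 0)
  probes <- data.frame(probe = sprintf("p%03d", 1:120),
                       true_log2fc = rep(c(0, 2, -2), 40))
  arr <- simulate_microarray(cfg, probes)
  res <- array_pipeline(arr$raw, arr$background)
  up_o <- res$records$category == "ovary_up"
  up_t <- res$records$category == "testis_up"
  expect_gt(mean(up_o[probes$true_log2fc == 2]), 0.9)
  expect_gt(mean(up_t[probes$true_log2fc == -2]), 0.9)
  expect_lt(mean((up_o | up_t)[probes$true_log2fc == 0]), 0.05 + 0.06)
})

test_that("clustering separates obvious blocks and is permutation-invariant", {
  med <- rbind(matrix(rep(c(5, 5, 5, 1, 1, 1), 6), 6, byrow = TRUE),
               matrix(rep(c(1, 1, 1, 5, 5, 5), 6), 6, byrow = TRUE))
  med <- med + matrix(seq(0, 0.11, 0.01), 12, 6)  # break exact ties, keep blocks
  rownames(med) <- sprintf("p%02d", 1:12)
  colnames(med) <- c(paste0("ovary", 1:3), paste0("testis", 1:3))
  cl <- cluster_biased(med, k = 2)
  expect_identical(length(unique(cl[1:6])), 1L)
  expect_identical(length(unique(cl[7:12])), 1L)
  expect_false(cl[1] == cl[7])
  expect_identical(unique(cluster_biased(med, k = 1)), 1L)
  expect_warning(cluster_biased(med[1:3, ], k = 10), "reducing k")
  # row permutation changes labels only up to relabelling
  perm <- c(4, 9, 1, 12, 6, 2, 8, 3, 10, 5, 11, 7)
  cl2 <- cluster_biased(med[perm, ], k = 2)
  expect_identical(length(unique(paste(cl[perm], cl2))), 2L)
})

test_that("platform concordance handles exact, inverted and degenerate input", {
  x <- c(1.2, -0.5, 3, 0.1, -2)
  expect_equal(platform_concordance(x, x)$r, 1)
  expect_equal(platform_concordance(x, -x)$r, -1)
  const <- platform_concordance(c(1, 1, 1, 1), x[1:4])
  expect_true(is.na(const$r))
  expect_error(platform_concordance(1:2, 1:2), "at least 3")
  # attenuation: r estimates signal variance share under independent noise
  withr::local_seed(95)
  s <- rnorm(400, 0, 1.5); e1 <- rnorm(400); e2 <- rnorm(400)
  rho <- 1.5^2 / (1.5^2 + 1)
  got <- platform_concordance(s + e1, s + e2)
  se <- (1 - rho^2) / sqrt(400 - 3)
  expect_lt(abs(got$r - rho), 3 * se + 0.02)
})
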