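# k-mer features, Fisher training, static comparator, homolog matching.

test_that("k-mer features match hand enumeration and have the right shape", {
  f1 <- extract_kmer_features("AAAA", kmax = 1)
  expect_equal(unname(f1[1, ]), c(1, 0, 0, 0))
  f2 <- extract_kmer_features("ACGT", kmax = 2)
  dimers <- f2[1, 5:20]
  expect_equal(unname(dimers[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  expect_equal(sum(dimers), 1)
  expect_identical(ncol(extract_kmer_features("ACGTACGTACGT", kmax = 5)), 1364L)
  # each k-block of a clean sequence sums to 1
  f5 <- extract_kmer_features(random_seq(1, 30), kmax = 5)
  offs <- cumsum(c(0, 4, 16, 64, 256))
  for (k in 1:5)
    expect_equal(sum(f5[1, (offs[k] + 1):(offs[k] + 4^k)]), 1)
  expect_error(extract_kmer_features("ACG", kmax = 5), "at least kmax")
})

test_that("swapping training sets negates weights and scores exactly", {
  withr::local_seed(61)
  pos <- random_seq(50, 28); neg <- random_seq(50, 28)
  m1 <- train_fisher(pos, neg, kmax = 3)
  m2 <- train_fisher(neg, pos, kmax = 3)
  expect_equal(m2$weights, -m1$weights)
  x <- random_seq(10, 30)
  s1 <- classify_pirna(x, m1)$score
  s2 <- classify_pirna(x, m2)$score
  expect_equal(s2, -s1)
  expect_error(train_fisher("ACGTACGTACGTACGTACGTACGTACG", neg),
               "at least 2")
})

test_that("null training data gives chance-level held-out discrimination", {
  withr::local_seed(62)
  model <- train_fisher(random_seq(500, 28), random_seq(500, 28))
  sp <- classify_pirna(random_seq(300, 28), model)$score
  sn <- classify_pirna(random_seq(300, 28), model)$score
  expect_lt(abs(auroc(sp, sn) - 0.5), 0.05)
})

test_that("held-out AUROC does not decrease as the positional bias gap grows", {
  cfg_at <- function(pu, pa, seed)
    sim_config(seed = seed, p_5prime_U = pu, p_pos10_A = pa,
               pirna_base_freqs = c(A = .25, C = .25, G = .25, T = .25))
  aucs <- vapply(list(c(.25, .25), c(.6, .45), c(.95, .7)), function(s) {
    cfg <- cfg_at(s[1], s[2], 63L)
    pos <- sim_pirna_like(cfg, 1500, "prop_pos")
    neg <- withr::with_seed(1234, random_seq(1500, 29))
    model <- train_fisher(pos[1:1000], neg[1:1000])
    auroc(classify_pirna(pos[1001:1500], model)$score,
          classify_pirna(neg[1001:1500], model)$score)
  }, numeric(1))
  expect_true(all(diff(aucs) >= -0.01))
  expect_lt(abs(aucs[1] - 0.5), 0.06)
})

test_that("rank-based AUROC agrees with the ROC-curve reference implementation", {
  withr::local_seed(60)
  sp <- rnorm(150, 1); sn <- rnorm(120)
  want <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 150), rep(0, 120)), predictor = c(sp, sn),
    quiet = TRUE, direction = "<")))
  expect_equal(auroc(sp, sn), want, tolerance = 1e-12)
})

test_that("candidate length outside 26-32 nt is rejected and empty input allowed", {
  withr::local_seed(64)
  model <- train_fisher(random_seq(20, 28), random_seq(20, 28))
  expect_identical(nrow(classify_pirna(character(0), model)), 0L)
  expect_error(classify_pirna(random_seq(1, 24), model), "26-32")
})

test_that("the trained threshold lies in the training score range", {
  withr::local_seed(65)
  pos <- random_seq(100, 28); neg <- random_seq(100, 28)
  model <- train_fisher(pos, neg)
  sc <- classify_pirna(c(pos, neg), model)$score
  expect_gte(model$theta, min(sc))
  expect_lte(model$theta, max(sc))
  # the top-scoring training positive is always called positive
  expect_true(classify_pirna(pos[which.max(sc[1:100])], model)$predicted)
})

test_that("static position scheme: degenerate and uniform cases", {
  posT <- paste0("T", random_seq(40, 27))
  m <- train_static_scheme(posT, pseudocount = 1e-9)
  expect_equal(unname(m$f[1, "T"]), 1, tolerance = 1e-6)
  # uniform positives score ~0 everywhere (log(0.25 / 0.25))
  withr::local_seed(66)
  mu <- train_static_scheme(random_seq(4000, 28))
  sc <- static_score(random_seq(20, 28), mu)
  expect_lt(max(abs(sc)), 0.5)
  # a T-initial query gains the position-1 log odds under the T-biased model
  expect_gt(static_score("TAAAAAAAAAAAAAAAAAAAAAAAAAAA", m) -
              static_score("GAAAAAAAAAAAAAAAAAAAAAAAAAAA", m), 1)
})

test_that("model serialisation round-trips bit-exactly", {
  withr::local_seed(67)
  model <- train_fisher(random_seq(30, 28), random_seq(30, 28), kmax = 4)
  p <- withr::local_tempfile(fileext = ".json")
  write_model(model, p)
  back <- read_model(p)
  expect_identical(back$weights, model$weights)
  expect_identical(back$theta, model$theta)
  expect_identical(back$kmax, model$kmax)
})

test_that("homolog matching is exact identity only", {
  known <- c(k1 = "ACGTACGTACGTACGTACGTACGTACGT", k2 = strrep("TG", 14))
  expect_identical(match_known(known[["k1"]], known)$known_id, "k1")
  one_off <- paste0("T", substr(known[["k1"]], 2, 28))
  expect_identical(nrow(match_known(one_off, known)), 0L)
  # planted-truth recovery: every planted known sequence is found, no decoy is
  ref <- build_reference(small_config(seed = 68L, n_known_real = 25L))
  planted <- ref$known[ref$known_truth]
  pool_pir <- ref$pool$sequence[ref$pool$class == "piRNA"]
  hits <- match_known(pool_pir, ref$known)
  expect_identical(sort(unique(hits$known_id)), sort(names(planted)))
  expect_identical(nrow(hits), 25L)
})
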