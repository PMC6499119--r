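## k-mer Fisher-discriminant piRNA classifier and the position-specific
## ("static") comparator.

#' Extract normalised k-mer frequency features
#'
#' For k = 1..`kmax`, the frequency of every k-mer (lexicographic order,
#' A < C < G < T): occurrences divided by the number of valid windows.
#' Windows containing non-ACGT letters are excluded from numerator and
#' denominator. At `kmax = 5` the concatenated vector has
#' 4 + 16 + 64 + 256 + 1024 = 1364 dimensions, and each k-block of a clean
#' sequence sums to 1.
#'
#' @param seqs Character vector of sequences (each of length >= `kmax`).
#' @param kmax Largest k (default 5).
#' @return Numeric matrix, one row per sequence, `sum(4^(1:kmax))` columns.
#' @export
extract_kmer_features <- function(seqs, kmax = 5L) {
  if (any(nchar(seqs) < kmax))
    stop("extract_kmer_features(): all sequences must be at least kmax (",
         kmax, ") nt long")
  dss <- Biostrings::DNAStringSet(seqs)
  blocks <- lapply(seq_len(kmax), function(k) {
    cnt <- Biostrings::oligonucleotideFrequency(dss, width = k)
    denom <- rowSums(cnt)           # valid (ACGT-only) windows
    cnt / pmax(denom, 1)
  })
  do.call(cbind, blocks)
}

#' Train the Fisher-weighted k-mer classifier
#'
#' Per feature j with class means m and variances v, the Fisher ratio is
#' `F_j = (m+_j - m-_j)^2 / (v+_j + v-_j + eps)` and the signed weight
#' `w_j = sign(m+_j - m-_j) * F_j`. A sequence scores `sum_j w_j x_j`; the
#' decision threshold is the training score maximising Youden's J
#' (sensitivity + specificity - 1), taking the smallest such score on ties.
#'
#' @param positives,negatives Character vectors of training sequences (each
#'   class needs >= 2 sequences for the variances).
#' @param kmax Largest k-mer length (default 5).
#' @param eps Variance floor (default 1e-9).
#' @return List of class `"pirna_model"`: `kmax`, `weights`, `theta`,
#'   `n_pos`, `n_neg`, `eps`.
#' @export
train_fisher <- function(positives, negatives, kmax = 5L, eps = 1e-9) {
  if (length(positives) < 2L || length(negatives) < 2L)
    stop("train_fisher(): each class needs at least 2 sequences")
  xp <- extract_kmer_features(positives, kmax)
  xn <- extract_kmer_features(negatives, kmax)
  mp <- colMeans(xp); mn <- colMeans(xn)
  vp <- col_vars(xp); vn <- col_vars(xn)
  fr <- (mp - mn)^2 / (vp + vn + eps)
  w <- sign(mp - mn) * fr
  sp <- drop(xp %*% w); sn <- drop(xn %*% w)
  theta <- youden_threshold(sp, sn)
  structure(list(kmax = as.integer(kmax), weights = w, theta = theta,
                 n_pos = length(positives), n_neg = length(negatives),
                 eps = eps),
            class = "pirna_model")
}

col_vars <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  colSums((x - rep(m, each = n))^2) / (n - 1L)
}

## threshold maximising Youden's J for the rule "positive iff score >= theta";
## smallest optimal threshold on ties
youden_threshold <- function(scores_pos, scores_neg) {
  cand <- sort(unique(c(scores_pos, scores_neg)))
  tpr <- vapply(cand, function(t) mean(scores_pos >= t), numeric(1))
  fpr <- vapply(cand, function(t) mean(scores_neg >= t), numeric(1))
  j <- tpr - fpr
  cand[which(j >= max(j) - 1e-12)[1]]
}

#' @export
print.pirna_model <- function(x, ...) {
  cat("<pirna_model> kmax", x$kmax, "|", length(x$weights), "features | theta",
      signif(x$theta, 6), "| trained on", x$n_pos, "+ /", x$n_neg, "-\n")
  invisible(x)
}

#' Score and classify piRNA candidates
#'
#' @param candidates Character vector of candidate sequences; all must lie in
#'   the piRNA length window 26-32 nt.
#' @param model A [train_fisher()] model.
#' @return Data frame with `sequence`, `score` and `predicted` (logical:
#'   score >= theta).
#' @export
classify_pirna <- function(candidates, model) {
  stopifnot(inherits(model, "pirna_model"))
  if (length(candidates) == 0L)
    return(data.frame(sequence = character(0), score = numeric(0),
                      predicted = logical(0)))
  len <- nchar(candidates)
  if (any(len < 26L | len > 32L))
    stop("classify_pirna(): candidate length outside 26-32 nt at position ",
         which(len < 26L | len > 32L)[1])
  x <- extract_kmer_features(candidates, model$kmax)
  score <- drop(x %*% model$weights)
  data.frame(sequence = candidates, score = score,
             predicted = score >= model$theta, stringsAsFactors = FALSE)
}

#' Train the position-specific ("static") comparator
#'
#' Smoothed base frequencies at positions 1..`n_positions`:
#' `f[p, b] = (count + 0.25 * pseudocount) / (n_p + pseudocount)` where `n_p`
#' counts the training sequences reaching position p. Scoring sums the
#' per-position log-odds against a uniform 0.25 background over the first
#' `min(length, n_positions)` bases.
#'
#' @param positives Character vector of training sequences.
#' @param n_positions Number of 5' positions modelled (default 20).
#' @param pseudocount Smoothing mass (default 1).
#' @return List of class `"static_model"` with the frequency matrix `f`
#'   (positions x ACGT), the log-odds matrix `logodds` and the parameters.
#' @export
train_static_scheme <- function(positives, n_positions = 20L, pseudocount = 1) {
  if (length(positives) == 0L) stop("train_static_scheme(): no positives")
  bases <- c("A", "C", "G", "T")
  f <- matrix(NA_real_, n_positions, 4L, dimnames = list(NULL, bases))
  for (p in seq_len(n_positions)) {
    at_p <- substr(positives[nchar(positives) >= p], p, p)
    n_p <- length(at_p)
    cnt <- vapply(bases, function(b) sum(at_p == b), numeric(1))
    f[p, ] <- (cnt + 0.25 * pseudocount) / (n_p + pseudocount)
  }
  structure(list(f = f, logodds = log(f / 0.25),
                 n_positions = as.integer(n_positions),
                 pseudocount = pseudocount),
            class = "static_model")
}

#' @rdname train_static_scheme
#' @param seqs Sequences to score.
#' @param model A `"static_model"`.
#' @export
static_score <- function(seqs, model) {
  stopifnot(inherits(model, "static_model"))
  vapply(seqs, function(s) {
    pmaxn <- min(nchar(s), model$n_positions)
    b <- strsplit(substr(s, 1L, pmaxn), "")[[1]]
    idx <- match(b, colnames(model$logodds))
    ok <- !is.na(idx)
    sum(model$logodds[cbind(which(ok), idx[ok])])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Match predictions against a known-piRNA set
#'
#' Exact full-sequence identity only (both sides are mature sequences; the
#' zero-mismatch rule of the homolog search).
#'
#' @param predictions Character vector of predicted piRNA sequences.
#' @param known Named character vector of known piRNA sequences.
#' @return Data frame with `sequence` and `known_id`, one row per hit.
#' @export
match_known <- function(predictions, known) {
  m <- match(predictions, known)
  hit <- !is.na(m)
  data.frame(sequence = predictions[hit],
             known_id = names(known)[m[hit]], stringsAsFactors = FALSE)
}

#' Serialise / restore a classifier model
#'
#' JSON round-trips bit-exactly (full-precision numbers).
#'
#' @param model A `"pirna_model"`.
#' @param path File path.
#' @return `read_model()` returns the restored model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pirna_model"))
  obj <- list(kmax = model$kmax, feature_names = names(model$weights),
              weights = unname(model$weights), theta = model$theta,
              n_pos = model$n_pos, n_neg = model$n_neg, eps = model$eps)
  ## I(17) significant digits: doubles round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.numeric(obj$weights)
  names(w) <- obj$feature_names
  structure(list(kmax = as.integer(obj$kmax), weights = w, theta = obj$theta,
                 n_pos = obj$n_pos, n_neg = obj$n_neg, eps = obj$eps),
            class = "pirna_model")
}

#' Rank-based AUROC
#'
#' Area under the ROC curve via the rank-sum identity (ties handled by
#' midranks), used for classifier benchmarking.
#'
#' @param scores_pos,scores_neg Scores of the positive and negative class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
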