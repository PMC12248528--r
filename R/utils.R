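#' @useDynLib radsig, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile sd prcomp hclust dist as.dist
#'   chisq.test fisher.test wilcox.test p.adjust predict rnorm runif
#'   uniroot setNames cor aggregate na.omit
#' @importFrom utils read.csv write.csv combn packageVersion
NULL

# Derive a stage sub-seed from a master seed.  Keeps the result a valid
# 32-bit integer so set.seed() never overflows.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729 + 12345) %%
               2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` cross-validation folds such that both
#' classes are spread as evenly as possible across folds.  Within each
#' class, samples are shuffled and dealt round-robin.  A class with fewer
#' than `k` members is simply absent from some folds; consumers skip the
#' resulting degenerate folds (callers that require full stratification,
#' like the repeated-CV harness, enforce their own minimum).
#'
#' @param y binary vector (two observed levels).
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:k`, one per sample.
#' @export
make_stratified_folds <- function(y, k, seed) {
  y <- as.integer(as.factor(y))
  n <- length(y)
  if (k < 2) stop("k must be >= 2")
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Stratified partition into `parts` groups of (near-)equal size per class.
# Errors when the majority class cannot contribute one sample per part.
stratified_partition <- function(y, parts, seed) {
  y <- as.integer(as.factor(y))
  if (max(table(y)) < parts)
    stop("too few samples for a stratified ", parts, "-way partition")
  make_stratified_folds(y, parts, seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
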