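# Shared fixtures, all generated in code.

# small radiomic block layout for fast cohorts (2 modalities x 3 classes)
small_blocks <- function(n_per_block = 8, informative = c(CE_T1w.LoG = 3,
                                                          T2w.Original = 3)) {
  b <- expand.grid(modality = c("CE_T1w", "T2w"),
                   filter_class = c("Original", "LoG", "Wavelet"),
                   stringsAsFactors = FALSE)
  b$n_features <- n_per_block
  key <- paste(b$modality, b$filter_class, sep = ".")
  b$n_informative <- ifelse(key %in% names(informative),
                            informative[key], 0L)
  b
}

small_cohort <- function(seed = 1, effect_size = 1, batch_shift = 0.5,
                         n_patients = 145, n_per_block = 8, ...) {
  generate_cohort(sim_config(n_patients = n_patients,
                             blocks = small_blocks(n_per_block),
                             effect_size = effect_size,
                             batch_shift = batch_shift,
                             n_redundant_pairs = 6, seed = seed, ...))
}

# n x p standardized-scale matrix with the first n_planted columns shifted
# by d for class 1; balanced labels
planted_matrix <- function(n, p, d, n_planted = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", seq_len(p))
    y <- rep(0:1, length.out = n)
    X[y == 1, seq_len(n_planted)] <- X[y == 1, seq_len(n_planted)] + d
    list(X = X, y = y, planted = paste0("f", seq_len(n_planted)))
  })
}

# brute-force chi-squared over explicit cell loops (association oracle)
chisq_bruteforce <- function(tab) {
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  chi2 <- 0
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / n
      chi2 <- chi2 + (tab[i, j] - e)^2 / e
    }
  chi2
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_bruteforce <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  xs <- max(0, k - n2):min(k, m)
  probs <- vapply(xs, function(x)
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k), 0)
  p_obs <- choose(m, a) * choose(n2, c_ - 0) / choose(m + n2, k)
  p_obs <- probs[match(a, xs)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# connected components by transitive closure over an adjacency matrix
components_bruteforce <- function(nodes, edges) {
  adj <- diag(length(nodes)) > 0
  rownames(adj) <- colnames(adj) <- nodes
  for (r in seq_len(nrow(edges)))
    adj[edges$name_i[r], edges$name_j[r]] <-
      adj[edges$name_j[r], edges$name_i[r]] <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0 | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, length(nodes))
  cid <- 0
  for (i in seq_along(nodes)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[adj[i, ]] <- cid
    }
  }
  split(nodes, comp)
}
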