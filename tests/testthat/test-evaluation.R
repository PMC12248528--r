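test_that("MCC matches its definition on examples and by exhaustive
           enumeration", {
  expect_equal(mcc(5, 0, 0, 5), 1)
  expect_equal(mcc(5, 5, 0, 0), 0) # zero-denominator convention
  expect_equal(mcc(3, 1, 2, 4), 10 / sqrt(600), tolerance = 1e-12)

  # every confusion table with total <= 20
  for (total in 1:20) {
    parts <- expand.grid(tp = 0:total, fp = 0:total, fn = 0:total)
    parts$tn <- total - parts$tp - parts$fp - parts$fn
    parts <- parts[parts$tn >= 0, ]
    for (r in seq_len(nrow(parts))) {
      tp <- parts$tp[r]; fp <- parts$fp[r]
      fn <- parts$fn[r]; tn <- parts$tn[r]
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      want <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
      expect_identical(mcc(tp, fp, fn, tn) == want, TRUE)
    }
  }
})

test_that("stratified folds balance classes and respect limits", {
  y <- rep(c(0, 1), c(60, 40))
  f <- make_stratified_folds(y, 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  tab <- table(f, y)
  expect_true(all(tab[, "0"] == 6) && all(tab[, "1"] == 4))
  # the repeated-CV harness refuses layouts it cannot stratify
  expect_error(
    repeated_stratified_cv(pipeline_spec("none"),
                           matrix(rnorm(70), 35), rep(c(0, 1), c(30, 5)),
                           n_folds = 10, n_repeats = 1, seed = 1),
    "fewer folds")
})

test_that("SVM-coefficient selection finds the informative feature", {
  hits <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      X <- matrix(rnorm(100 * 21), 100, 21)
      y <- rep(0:1, each = 50)
      X[y == 1, 1] <- X[y == 1, 1] + 3
    })
    1 %in% svm_select(scale(X), y)
  }, NA)
  expect_gte(mean(hits), 0.95)

  withr::with_seed(2, {
    Xn <- matrix(rnorm(60 * 50), 60, 50)
    yn <- rep(0:1, each = 30)
  })
  expect_gte(length(svm_select(Xn, yn)), 1) # never empty
  expect_equal(length(svm_select(Xn, yn, top_k = 5)), 5)
})

test_that("repeated stratified CV calibrates: separable data scores 1,
           permuted labels score ~0, and reruns are identical", {
  pm <- planted_matrix(100, 5, 3, n_planted = 5, seed = 1)
  res <- repeated_stratified_cv(pipeline_spec("none"), pm$X, pm$y,
                                n_folds = 5, n_repeats = 3, seed = 2)
  expect_equal(summarize_cv(res)$median_mcc, 1)
  expect_equal(length(res$scores), 15)

  withr::with_seed(3, yperm <- sample(pm$y))
  null <- repeated_stratified_cv(pipeline_spec("svm"), pm$X, yperm,
                                 n_folds = 5, n_repeats = 20, seed = 2)
  expect_lt(abs(summarize_cv(null)$median_mcc), 0.1)

  res2 <- repeated_stratified_cv(pipeline_spec("none"), pm$X, pm$y,
                                 n_folds = 5, n_repeats = 3, seed = 2)
  expect_identical(res$scores, res2$scores)

  expect_error(repeated_stratified_cv(pipeline_spec("none"), pm$X, pm$y,
                                      n_folds = 60, n_repeats = 1),
               "fewer folds")
})

test_that("the training fit never sees held-out rows", {
  pm <- planted_matrix(120, 10, 1, seed = 4)
  folds <- make_stratified_folds(pm$y, 4, seed = 1)
  tr <- folds != 1
  X2 <- pm$X
  X2[!tr, ] <- 1e6 # corrupt the held-out rows only
  for (sel in c("svm", "dnetpro_A")) {
    spec <- pipeline_spec(sel, dnetpro = dnetpro_config(inner_folds = 3))
    s1 <- fit_scaler(pm$X[tr, ], "zscore")
    s2 <- fit_scaler(X2[tr, ], "zscore")
    expect_identical(s1, s2)
    Z <- apply_scaler(s1, pm$X[tr, ])
    sel1 <- radsig:::.select_features(spec, Z, pm$y[tr], seed = 7)
    sel2 <- radsig:::.select_features(spec, apply_scaler(s2, X2[tr, ]),
                                      pm$y[tr], seed = 7)
    expect_identical(sel1, sel2)
    f1 <- radsig:::ridge_fit(Z[, sel1, drop = FALSE], pm$y[tr], 1)
    f2 <- radsig:::ridge_fit(Z[, sel2, drop = FALSE], pm$y[tr], 1)
    expect_identical(coef(f1$model), coef(f2$model))
  }
})

test_that("summaries use linear-interpolation quantiles", {
  r <- cv_result(c(0.5, 0.6, 0.7), 1, 3, "x", 1)
  s <- summarize_cv(r)
  expect_equal(s$median_mcc, 0.6)
  expect_equal(s$iqr, 0.1)
  expect_equal(summarize_cv(cv_result(rep(0.4, 5), 1, 5, "x", 1))$iqr, 0)
  s1 <- summarize_cv(cv_result(0.3, 1, 1, "x", 1))
  expect_equal(s1$median_mcc, 0.3)
  expect_equal(s1$iqr, 0)
  # independent sorting-based oracle on random score vectors
  withr::with_seed(5, {
    for (i in 1:20) {
      sc <- runif(sample(3:50, 1), -1, 1)
      s <- summarize_cv(sc)
      srt <- sort(sc); n <- length(srt)
      qt <- function(p) {
        h <- (n - 1) * p + 1
        lo <- floor(h)
        srt[lo] + (h - lo) * (srt[min(lo + 1, n)] - srt[lo])
      }
      expect_equal(s$median_mcc, qt(0.5), tolerance = 1e-12)
      expect_equal(s$iqr, qt(0.75) - qt(0.25), tolerance = 1e-12)
    }
  })
})

test_that("Wilcoxon comparisons behave at the edges and match exact
           enumeration", {
  a <- cv_result(seq(0.1, 0.6, length.out = 50), 5, 10, "a", 3)
  expect_message(p_same <- compare_wilcoxon(a, a), "zero")
  expect_equal(p_same, 1)

  b <- cv_result(a$scores + 0.2, 5, 10, "b", 3)
  expect_lt(compare_wilcoxon(a, b, "less"), 0.001)

  # exact signed-rank enumeration oracle for small paired samples
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- sample(5:12, 1)
      x <- round(runif(n, -1, 1), 3); y <- round(runif(n, -1, 1), 3)
      d <- x - y; d <- d[d != 0]
      if (length(d) < 2 || anyDuplicated(abs(d))) next
      w_obs <- sum(rank(abs(d))[d > 0])
      signs <- expand.grid(rep(list(c(0, 1)), length(d)))
      ws <- as.matrix(signs) %*% rank(abs(d))
      p_oracle <- mean(ws >= w_obs)
      got <- suppressWarnings(
        wilcox.test(x, y, paired = TRUE, alternative = "greater",
                    exact = TRUE)$p.value)
      expect_equal(got, p_oracle, tolerance = 1e-9)
      expect_equal(compare_wilcoxon(x, y, "greater"), got,
                   tolerance = 1e-12)
    }
  })
})

test_that("the benchmark grid summarises cells and recovers the planted
           category", {
  co <- small_cohort(seed = 31, effect_size = 1.2)
  plan <- benchmark_plan(sources = c("clinical", "radiomic"),
                         modalities = "CE_T1w",
                         categories = c("Original", "LoG"),
                         methods = "svm", n_folds = 5, n_repeats = 2)
  bench <- run_benchmark(co, plan, seed = 1)
  expect_equal(nrow(bench$cells), 3) # clinical + 2 radiomic cells
  expect_true(all(is.na(bench$cells$error)))
  expect_true(all(bench$cells$median_mcc >= -1 &
                    bench$cells$median_mcc <= 1))
  # signal was planted in the CE T1-w LoG block
  expect_equal(bench$argmax_category$category[
    bench$argmax_category$modality == "CE_T1w"], "LoG")

  # single-cell plan and failure recording
  plan1 <- benchmark_plan(sources = "radiomic", modalities = "T2w",
                          categories = "Original", methods = "svm",
                          n_folds = 5, n_repeats = 1)
  b1 <- run_benchmark(co, plan1, seed = 1)
  expect_equal(nrow(b1$cells), 1)
  plan_bad <- plan1
  plan_bad$n_folds <- 500
  expect_message(bbad <- run_benchmark(co, plan_bad, seed = 1), "failed")
  expect_true(is.na(bbad$cells$median_mcc))
  expect_match(bbad$cells$error, "folds")
})
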