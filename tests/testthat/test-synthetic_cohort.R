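test_that("cohort matches the configured composition exactly", {
  co <- generate_cohort(sim_config(blocks = small_blocks(), seed = 1))
  expect_equal(sum(co$labels), 76)       # malignant
  expect_equal(sum(1 - co$labels), 69)   # benign
  expect_equal(unname(table(co$centers)["A"]), 119)
  expect_equal(unname(table(co$centers)["B"]), 26)
  expect_true(all(co$truth$informative %in% colnames(co$features$values)))
})

test_that("generation is bit-identical under the same config", {
  a <- small_cohort(seed = 99)
  b <- small_cohort(seed = 99)
  expect_identical(a$features$values, b$features$values)
  expect_identical(a$labels, b$labels)
  expect_identical(a$clinical$data, b$clinical$data)
  c2 <- small_cohort(seed = 100)
  expect_false(identical(a$features$values, c2$features$values))
})

test_that("association calibration hits its population target", {
  # independence and perfect association edge cases
  cc0 <- calibrate_association(c("a", "b"), 0, 0.52)
  expect_equal(cc0$p1, cc0$p0)
  cc1 <- calibrate_association(c("a", "b"), 1, 0.52)
  expect_equal(unname(cc1$p1), c(0, 1))
  expect_equal(unname(cc1$p0), c(1, 0))

  # binary target 0.38 at the study's class balance: the analytic
  # phi-squared of the returned conditionals recomputes the target
  cc <- calibrate_association(c("no", "yes"), 0.38, 0.52,
                              marginal = c(0.85, 0.15))
  joint <- rbind(0.52 * cc$p1, 0.48 * cc$p0)
  phi2 <- chisq_bruteforce(joint * 1e6) / 1e6 # population-level chi2/n
  expect_equal(unname(sqrt(phi2)), 0.38, tolerance = 1e-6)

  # 5-level variable via the tilt family
  sc <- default_clinical_schema()$epicenter
  cc5 <- calibrate_association(sc$levels, 0.25, 0.52, sc$marginal)
  expect_equal(radsig:::population_cramers_v(cc5$p1, cc5$p0, 0.52), 0.25,
               tolerance = 1e-6)
  # marginal is preserved
  expect_equal(unname(0.52 * cc5$p1 + 0.48 * cc5$p0),
               unname(sc$marginal / sum(sc$marginal)), tolerance = 1e-9)

  expect_error(calibrate_association(c("a", "b"), 0.95, 0.52,
                                     marginal = c(0.98, 0.02)),
               "unreachable")
})

test_that("sampled cohorts recover the target corrected V in expectation", {
  sc <- default_clinical_schema()$symptoms
  cc <- calibrate_association(sc$levels, sc$target_v, 0.52, sc$marginal)
  vs <- vapply(1:200, function(r) {
    withr::with_seed(3000 + r, {
      y <- rbinom(500, 1, 0.52)
      x <- vapply(y, function(yi)
        sample(sc$levels, 1, prob = if (yi == 1) cc$p1 else cc$p0), "")
      cramers_v_corrected(table(y, x))
    })
  }, 0)
  expect_lt(abs(mean(vs) - 0.41), 0.05)
})

test_that("block correlation and redundant pairs match the plan", {
  co <- generate_cohort(sim_config(n_patients = 1000,
                                   blocks = small_blocks(10),
                                   effect_size = 0, batch_shift = 0,
                                   n_redundant_pairs = 0, seed = 5))
  keep <- co$features$descriptors$modality == "CE_T1w" &
    co$features$descriptors$filter_class == "Original"
  cm <- cor(co$features$values[, keep])
  expect_lt(abs(mean(cm[upper.tri(cm)]) - 0.4), 0.05)

  co2 <- small_cohort(seed = 6) # n = 145, 6 redundant pairs
  expect_gt(nrow(co2$truth$redundant_pairs), 0)
  for (r in seq_len(nrow(co2$truth$redundant_pairs))) {
    rho <- cor(co2$features$values[, co2$truth$redundant_pairs$source[r]],
               co2$features$values[, co2$truth$redundant_pairs$twin[r]])
    expect_gte(abs(rho), 0.9)
  }
})

test_that("a null configuration produces no discriminative features", {
  co <- generate_cohort(sim_config(n_patients = 500,
                                   blocks = small_blocks(10, c()),
                                   effect_size = 0, batch_shift = 0,
                                   seed = 8))
  auc <- apply(co$features$values, 2, function(x) {
    r <- rank(x)
    n1 <- sum(co$labels == 1); n0 <- sum(co$labels == 0)
    (sum(r[co$labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  expect_true(all(auc > 0.4 & auc < 0.6))
})

test_that("no batch shift means no center-linked feature differences", {
  co <- generate_cohort(sim_config(n_patients = 400,
                                   blocks = small_blocks(12, c()),
                                   effect_size = 0, batch_shift = 0,
                                   center_balance = 0.5, seed = 9))
  pv <- apply(co$features$values, 2, function(x)
    t.test(x[co$centers == "A"], x[co$centers == "B"])$p.value)
  frac <- mean(pv < 0.01)
  # binomial tolerance around the nominal 1% level
  expect_lt(frac, 0.01 + 3 * sqrt(0.01 * 0.99 / length(pv)))
})

test_that("xor pairs are individually null but jointly informative", {
  co <- generate_cohort(sim_config(n_patients = 400,
                                   blocks = small_blocks(10, c()),
                                   effect_size = 0, batch_shift = 0,
                                   n_xor_pairs = 2, seed = 12))
  xp <- co$truth$xor_pairs
  expect_equal(nrow(xp), 2)
  for (r in seq_len(nrow(xp))) {
    a <- co$features$values[, xp$a[r]]; b <- co$features$values[, xp$b[r]]
    # marginally useless
    expect_gt(t.test(a ~ co$labels)$p.value, 0.001)
    # the within-pair correlation flips sign with the class
    expect_gt(cor(a[co$labels == 1], b[co$labels == 1]), 0.5)
    expect_lt(cor(a[co$labels == 0], b[co$labels == 0]), -0.5)
  }
})
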