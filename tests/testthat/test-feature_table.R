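test_that("feature names parse into category metadata", {
  d <- parse_feature_name("original_glcm_JointAverage", "CE_T1w")
  expect_equal(d$filter_class, "Original")
  expect_equal(d$family, "glcm")
  expect_true(is.na(d$filter_param))

  d <- parse_feature_name("log-sigma-1-0-mm-3D_firstorder_Skewness", "CE_T1w")
  expect_equal(d$filter_class, "LoG")
  expect_equal(d$family, "firstorder")
  expect_equal(d$filter_param, "1.0")

  d <- parse_feature_name("wavelet-LLH_glszm_SizeZoneNonUniformityNormalized",
                          "T2w")
  expect_equal(d$filter_class, "Wavelet")
  expect_equal(d$family, "glszm")
  expect_equal(d$filter_param, "LLH")

  d <- parse_feature_name("age", "clinical")
  expect_equal(d$filter_class, "none")
  expect_equal(d$family, "clinical")

  expect_error(parse_feature_name(""), "non-empty")
})

test_that("descriptor -> canonical name -> descriptor is the identity", {
  names <- c("original_shape_Sphericity",
             "original_ngtdm_Coarseness",
             "log-sigma-0-5-mm-3D_glrlm_RunEntropy",
             "log-sigma-2-0-mm-3D_gldm_DependenceEntropy",
             "wavelet-HHH_firstorder_Mean",
             "wavelet-LLL_glcm_Idm")
  for (nm in names) {
    d <- parse_feature_name(nm, "CE_T1w")
    expect_equal(canonical_feature_name(d), nm)
    d2 <- parse_feature_name(canonical_feature_name(d), "CE_T1w")
    expect_equal(d2[c("filter_class", "family", "filter_param", "base")],
                 d[c("filter_class", "family", "filter_param", "base")])
  }
})

test_that("subset_by_category filters and preserves order", {
  co <- small_cohort(seed = 3)
  tab <- co$features
  sub <- subset_by_category(tab, "CE_T1w", "LoG")
  expect_true(all(sub$descriptors$modality == "CE_T1w"))
  expect_true(all(sub$descriptors$filter_class == "LoG"))
  expect_equal(colnames(sub$values),
               colnames(tab$values)[tab$descriptors$modality == "CE_T1w" &
                                      tab$descriptors$filter_class == "LoG"])
  # full selection is the identity
  all_sub <- subset_by_category(tab, c("CE_T1w", "T2w", "clinical"),
                                c("Original", "LoG", "Wavelet", "none"))
  expect_identical(all_sub$values, tab$values)
  expect_error(subset_by_category(sub, "T2w", "Original"), "zero columns")
  expect_error(subset_by_category(tab, character(), "LoG"), "non-empty")
})

test_that("z-score and robust standardization match direct computation", {
  tab <- feature_table(cbind(a = c(1, 2, 3), b = c(5, 5, 5)),
                       parse_feature_names(c("a", "b"), "clinical"),
                       c("p1", "p2", "p3"))
  expect_warning(z <- standardize(tab, "zscore"), "constant")
  expect_equal(z$table$values[, 1], c(p1 = -1.2247449, p2 = 0,
                                      p3 = 1.2247449),
               tolerance = 1e-6)
  expect_equal(unname(z$table$values[, 2]), c(0, 0, 0))

  expect_warning(r <- standardize(tab, "robust"), "constant")
  # median 2, IQR (linear-interpolation quantiles) = 2.5 - 1.5 = 1
  expect_equal(unname(r$table$values[, 1]), c(-1, 0, 1))
  expect_equal(unname(r$table$values[, 2]), c(0, 0, 0))
})

test_that("standardization invariants hold on random tables", {
  co <- small_cohort(seed = 11)
  z <- standardize(co$features, "zscore")$table$values
  expect_true(max(abs(colMeans(z))) < 1e-9)
  psd <- sqrt(colMeans(sweep(z, 2, colMeans(z))^2))
  expect_true(max(abs(psd - 1)) < 1e-9)

  r <- standardize(co$features, "robust")$table$values
  expect_true(max(abs(apply(r, 2, median))) < 1e-9)
  iqr <- apply(r, 2, function(x) diff(quantile(x, c(.25, .75), names = FALSE)))
  expect_true(max(abs(iqr - 1)) < 1e-9)
})

test_that("train-fitted scaling params reproduce the fit and transfer", {
  co <- small_cohort(seed = 4)
  tr <- seq_len(100); te <- 101:145
  sub <- function(idx) feature_table(co$features$values[idx, , drop = FALSE],
                                     co$features$descriptors,
                                     co$features$patient_ids[idx])
  s <- standardize(sub(tr), "zscore")
  again <- apply_scaling(s$params, sub(tr))
  expect_identical(again$values, s$table$values) # bit-for-bit
  held <- apply_scaling(s$params, sub(te))
  expect_equal(dim(held$values), c(45, ncol(co$features$values)))
  expect_error(apply_scaling(s$params, subset_by_category(sub(te), "T2w")),
               "different columns")
})

test_that("load_tables aligns on id intersection and validates labels", {
  co <- small_cohort(seed = 7, n_patients = 30)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  lt <- load_tables(paths[c("CE_T1w", "T2w")], paths[["clinical"]],
                    "outcome", "center")
  expect_equal(lt$features$patient_ids, co$features$patient_ids)
  expect_identical(lt$labels, co$labels)
  expect_equal(lt$features$values[, colnames(co$features$values)],
               co$features$values, tolerance = 1e-12)

  # extra unmatched clinical patient is dropped with a message
  cli <- read.csv(paths[["clinical"]])
  cli <- rbind(cli, cli[1, ]); cli$patient_id[nrow(cli)] <- "P999"
  extra <- file.path(dir, "clin_extra.csv")
  write.csv(cli, extra, row.names = FALSE)
  expect_message(lt2 <- load_tables(paths[c("CE_T1w", "T2w")], extra,
                                    "outcome", "center"), "dropped")
  expect_equal(lt2$dropped, "P999")
  expect_equal(nrow(lt2$features$values), 30)

  # disjoint ids -> alignment error
  r1 <- read.csv(paths[["CE_T1w"]]); r1$patient_id <- paste0("Q", r1$patient_id)
  dis <- file.path(dir, "dis.csv"); write.csv(r1, dis, row.names = FALSE)
  expect_error(load_tables(c(CE_T1w = dis), paths[["clinical"]], "outcome"),
               "empty")

  # non-binary labels -> schema error
  cli3 <- read.csv(paths[["clinical"]]); cli3$outcome[1] <- "other"
  tri <- file.path(dir, "clin3.csv"); write.csv(cli3, tri, row.names = FALSE)
  expect_error(load_tables(paths[c("CE_T1w", "T2w")], tri, "outcome"),
               "binary")
})

test_that("clinical encoding imputes with the training mode and one-hot
           encodes multi-level variables", {
  ct <- clinical_table(
    paste0("p", 1:6),
    data.frame(bin = c("y", "y", "y", "n", NA, "n"),
               multi = c("a", "b", "c", "a", "a", NA)),
    schema = list(bin = c("n", "y"), multi = c("a", "b", "c")))
  enc <- fit_clinical_encoder(ct)
  m <- encode_clinical(enc, ct)
  expect_equal(colnames(m), c("bin", "multi.a", "multi.b", "multi.c"))
  expect_equal(unname(m[5, "bin"]), 1) # mode of bin is "y"
  expect_equal(unname(m[6, c("multi.a", "multi.b", "multi.c")]),
               c(1, 0, 0)) # mode of multi is "a"
  log <- attr(m, "imputation_log")
  expect_equal(nrow(log), 2)
  expect_setequal(log$variable, c("bin", "multi"))
  # codes outside the declared level set are rejected
  expect_error(clinical_table("p1", data.frame(bin = "maybe"),
                              schema = list(bin = c("n", "y"))),
               "outside")
})
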