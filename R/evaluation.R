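#' @name evaluation-module
#' @title MCC-based repeated cross-validation benchmark harness
#'
#' @description
#' All classification performance in the pipeline is quantified with the
#' Matthews Correlation Coefficient, a confusion-matrix correlation in
#' `[-1, 1]` that is robust to class imbalance, summarised as the median
#' and one interquartile range over repeated stratified k-fold
#' cross-validation.  The harness evaluates pipeline variants
#' (clinical-only, radiomic-only, combined; SVM-coefficient selection vs
#' DNetPRO procedures A and B) on a common fold structure so variants can
#' be compared with paired Wilcoxon tests, and never lets any fitted
#' statistic (scaling, imputation mode, selected features, model weights)
#' see a test fold.
NULL

#' Matthews Correlation Coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; when any factor
#' of the denominator is zero the score is 0 by convention.
#'
#' @param tp,fp,fn,tn non-negative confusion counts (positive total).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den <= 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' MCC of predicted vs true binary labels
#'
#' @param truth,pred binary 0/1 vectors of equal length.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_pred <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  mcc(sum(pred == 1 & truth == 1), sum(pred == 1 & truth == 0),
      sum(pred == 0 & truth == 1), sum(pred == 0 & truth == 0))
}

#' Container for a cross-validation score distribution
#'
#' @param scores numeric vector of per-split MCCs.
#' @param n_repeats,n_folds the repeated-CV layout that produced them.
#' @param pipeline_id short string identifying the pipeline variant.
#' @param seed the seed the distribution was generated under.
#' @return a `cv_result` object.
#' @export
cv_result <- function(scores, n_repeats, n_folds, pipeline_id, seed) {
  stopifnot(all(scores >= -1 - 1e-9), all(scores <= 1 + 1e-9))
  structure(list(scores = as.numeric(scores), n_repeats = n_repeats,
                 n_folds = n_folds, pipeline_id = pipeline_id,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- summarize_cv(x)
  cat("<cv_result> ", x$pipeline_id, ": median MCC ",
      format(s$median_mcc, digits = 3), " +/- ",
      format(s$iqr, digits = 3), " IQR (", length(x$scores),
      " splits)\n", sep = "")
  invisible(x)
}

#' Median and interquartile range of a CV score distribution
#'
#' Linear-interpolation (type 7) quantiles, matching the robust scaler.
#'
#' @param result a `cv_result` (or bare numeric vector).
#' @return data.frame with `median_mcc`, `iqr`, `n_scores`.
#' @export
summarize_cv <- function(result) {
  scores <- if (inherits(result, "cv_result")) result$scores
            else as.numeric(result)
  stopifnot(length(scores) >= 1)
  qs <- quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(median_mcc = qs[2], iqr = qs[3] - qs[1],
             n_scores = length(scores))
}

#' SVM-coefficient feature selection
#'
#' Fits the linear SVM on all (standardized) features and keeps the
#' features whose absolute weight exceeds the mean absolute weight
#' (default), or the `top_k` largest-weight features.  At least one
#' feature is always retained.
#'
#' @param X_train standardized training matrix.
#' @param y_train binary labels.
#' @param top_k optional number of features to keep.
#' @param cost SVM cost parameter.
#' @return integer vector of selected column indices.
#' @export
svm_select <- function(X_train, y_train, top_k = NULL, cost = 1) {
  w <- abs(linsvm_fit(X_train, y_train, cost)$weights)
  if (!is.null(top_k)) {
    stopifnot(top_k >= 1)
    sel <- order(-w, seq_along(w))[seq_len(min(top_k, length(w)))]
  } else {
    sel <- which(w > mean(w))
    if (length(sel) == 0) sel <- which.max(w)
  }
  sort(sel)
}

#' Pipeline variant specification
#'
#' @param selector `"none"` (all features), `"svm"`
#'   ([svm_select()]-based), `"dnetpro_A"` or `"dnetpro_B"` (the couple
#'   network's best component, selected inside the training fold; for B,
#'   via a rotated three-way partition of the training fold with the
#'   validation part ranking the components).
#' @param top_k passed to [svm_select()].
#' @param penalty ridge penalty of the final logistic classifier.
#' @param dnetpro a [dnetpro_config()] for the DNetPRO selectors.
#' @param id optional identifier; defaults to the selector name.
#' @return a `pipeline_spec` object.
#' @export
pipeline_spec <- function(selector = c("none", "svm", "dnetpro_A",
                                       "dnetpro_B"),
                          top_k = NULL, penalty = 1,
                          dnetpro = dnetpro_config(), id = NULL) {
  selector <- match.arg(selector)
  structure(list(selector = selector, top_k = top_k, penalty = penalty,
                 dnetpro = dnetpro, id = id %||% selector),
            class = "pipeline_spec")
}

# feature selection on a (standardized) training fold; returns indices
.select_features <- function(spec, Ztr, ytr, seed) {
  p <- ncol(Ztr)
  switch(spec$selector,
    none = seq_len(p),
    svm = svm_select(Ztr, ytr, top_k = spec$top_k,
                     cost = spec$dnetpro$cost),
    dnetpro_A = {
      couples <- score_couples(Ztr, ytr, spec$dnetpro, derive_seed(seed, 7))
      net <- build_network(couples, spec$dnetpro$keep_fraction)
      ranking <- .rank_components(net, Ztr, ytr, spec$dnetpro$eval_folds,
                                  spec$penalty, derive_seed(seed, 8))
      which(colnames(Ztr) %in%
              strsplit(ranking$key[1], "|", fixed = TRUE)[[1]])
    },
    dnetpro_B = {
      parts <- stratified_partition(ytr, 3, derive_seed(seed, 9))
      best_key <- NULL; best_val <- -Inf
      for (t in 1:3) {
        roles <- ((0:2 + t - 1) %% 3) + 1
        tr <- parts == roles[1]; va <- parts == roles[2]
        couples <- score_couples(Ztr[tr, , drop = FALSE], ytr[tr],
                                 spec$dnetpro, derive_seed(seed, 10 + t))
        net <- build_network(couples, spec$dnetpro$keep_fraction)
        ranking <- .rank_components(net, Ztr[tr, , drop = FALSE], ytr[tr],
                                    spec$dnetpro$eval_folds, spec$penalty,
                                    derive_seed(seed, 20 + t),
                                    Xval = Ztr[va, , drop = FALSE],
                                    yval = ytr[va])
        if (ranking$eval_score[1] > best_val) {
          best_val <- ranking$eval_score[1]; best_key <- ranking$key[1]
        }
      }
      which(colnames(Ztr) %in% strsplit(best_key, "|", fixed = TRUE)[[1]])
    })
}

#' Repeated stratified cross-validation of a pipeline variant
#'
#' For each repeat a fresh stratified fold assignment is drawn from a
#' repeat-indexed sub-seed (so different pipeline variants evaluated under
#' the same master seed share fold assignments and can be compared
#' pairwise).  Within each training fold the full pipeline is fitted:
#' z-score scaling, optional training-mode imputation + encoding of
#' clinical covariates, feature selection, and the ridge logistic
#' classifier; the held-out fold only ever passes through the fitted
#' transforms.
#'
#' @param spec a [pipeline_spec()].
#' @param X numeric feature matrix, or `NULL` for clinical-only pipelines.
#' @param y binary labels.
#' @param n_folds stratified folds per repeat (each class must have at
#'   least `n_folds` members).
#' @param n_repeats number of repeats.
#' @param seed master seed.
#' @param clinical optional `clinical_table`; encoded per fold with
#'   training-split mode imputation and appended to `X`.
#' @return a [cv_result()] with `n_repeats * n_folds` scores.
#' @export
repeated_stratified_cv <- function(spec, X, y, n_folds = 10,
                                   n_repeats = 100, seed = 1,
                                   clinical = NULL) {
  y01 <- as.integer(as.factor(y)) - 1L
  if (min(table(y01)) < n_folds)
    stop("each class needs at least n_folds = ", n_folds,
         " members; use fewer folds")
  if (!is.null(X)) X <- as.matrix(X)
  if (is.null(X) && is.null(clinical))
    stop("provide a feature matrix, a clinical table, or both")
  scores <- numeric()
  for (r in seq_len(n_repeats)) {
    folds <- make_stratified_folds(y01, n_folds, derive_seed(seed, 1000 + r))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      blocks_tr <- list(); blocks_te <- list()
      if (!is.null(X)) {
        sc <- fit_scaler(X[tr, , drop = FALSE], "zscore")
        blocks_tr$rad <- apply_scaler(sc, X[tr, , drop = FALSE])
        blocks_te$rad <- apply_scaler(sc, X[!tr, , drop = FALSE])
      }
      if (!is.null(clinical)) {
        ct_tr <- clinical_table(clinical$patient_ids[tr],
                                clinical$data[tr, , drop = FALSE],
                                clinical$schema)
        ct_te <- clinical_table(clinical$patient_ids[!tr],
                                clinical$data[!tr, , drop = FALSE],
                                clinical$schema)
        enc <- fit_clinical_encoder(ct_tr)
        csc <- fit_scaler(encode_clinical(enc, ct_tr), "zscore")
        blocks_tr$cli <- apply_scaler(csc, encode_clinical(enc, ct_tr))
        blocks_te$cli <- apply_scaler(csc, encode_clinical(enc, ct_te))
      }
      Ztr <- do.call(cbind, blocks_tr); Zte <- do.call(cbind, blocks_te)
      sel <- .select_features(spec, Ztr, y01[tr],
                              derive_seed(seed, 2000 + r * 100 + f))
      fit <- ridge_fit(Ztr[, sel, drop = FALSE], y01[tr], spec$penalty)
      pred <- ridge_predict(fit, Zte[, sel, drop = FALSE])
      scores <- c(scores, mcc_pred(y01[!tr], pred))
    }
  }
  cv_result(scores, n_repeats, n_folds, spec$id, seed)
}

#' Wilcoxon comparison of two CV score distributions
#'
#' Paired signed-rank test when the two results share the same fold
#' structure (equal repeats, folds and seed, hence identical splits);
#' unpaired rank-sum otherwise.  Ties are handled by midranks; zero
#' differences are dropped in the paired variant, and an all-zero
#' difference vector returns p = 1 with a message.
#'
#' @param a,b `cv_result` objects (or bare score vectors, compared
#'   unpaired unless equal length).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `a`
#'   relative to `b`).
#' @return the p-value.
#' @export
compare_wilcoxon <- function(a, b,
                             alternative = c("two.sided", "less",
                                             "greater")) {
  alternative <- match.arg(alternative)
  sa <- if (inherits(a, "cv_result")) a$scores else as.numeric(a)
  sb <- if (inherits(b, "cv_result")) b$scores else as.numeric(b)
  paired <- length(sa) == length(sb) &&
    (!inherits(a, "cv_result") || !inherits(b, "cv_result") ||
       (a$n_repeats == b$n_repeats && a$n_folds == b$n_folds &&
          a$seed == b$seed))
  if (paired && all(sa == sb)) {
    message("all paired differences are zero; p = 1")
    return(1)
  }
  suppressWarnings(
    wilcox.test(sa, sb, paired = paired, alternative = alternative)$p.value)
}

#' Benchmark plan
#'
#' A grid of benchmark cells: data source x modality x radiomic category x
#' selection method.  The default is the full crossing used by the study
#' design; pass subsets for cheaper runs.
#'
#' @param sources subset of `c("clinical", "radiomic", "combined")`.
#' @param modalities subset of `c("CE_T1w", "T2w", "both")`.
#' @param categories subset of `c("Original", "LoG", "Wavelet")`.
#' @param methods subset of `c("svm", "dnetpro_A", "dnetpro_B")`.
#' @param n_folds,n_repeats CV layout for every cell.
#' @return data.frame of cells (class `benchmark_plan`); clinical-only
#'   cells have `NA` modality/category.
#' @export
benchmark_plan <- function(sources = c("clinical", "radiomic", "combined"),
                           modalities = c("CE_T1w", "T2w", "both"),
                           categories = c("Original", "LoG", "Wavelet"),
                           methods = c("svm", "dnetpro_A", "dnetpro_B"),
                           n_folds = 10, n_repeats = 100) {
  cells <- NULL
  if ("clinical" %in% sources)
    cells <- rbind(cells, expand.grid(source = "clinical",
                                      modality = NA_character_,
                                      category = NA_character_,
                                      method = methods,
                                      stringsAsFactors = FALSE))
  for (s in intersect(sources, c("radiomic", "combined")))
    cells <- rbind(cells, expand.grid(source = s, modality = modalities,
                                      category = categories,
                                      method = methods,
                                      stringsAsFactors = FALSE))
  cells$n_folds <- n_folds
  cells$n_repeats <- n_repeats
  cells$cell_id <- apply(cells, 1, function(r)
    paste(na.omit(c(r[["source"]], r[["modality"]], r[["category"]],
                    r[["method"]])), collapse = "/"))
  class(cells) <- c("benchmark_plan", "data.frame")
  cells
}

.cell_matrix <- function(cohort, source, modality, category) {
  if (source == "clinical") return(NULL)
  mods <- if (is.na(modality) || modality == "both")
    c("CE_T1w", "T2w") else modality
  subset_by_category(cohort$features, mods, category)$values
}

#' Run a benchmark plan on a cohort
#'
#' Evaluates every cell of the plan with [repeated_stratified_cv()] under
#' a shared master seed (so cells are pairwise comparable), summarises
#' each cell as median MCC and IQR, and reports per modality the radiomic
#' category maximising the median MCC (radiomic-only cells, the study's
#' category pre-selection rule).  Cells that fail are recorded as `NA`
#' with the error message.
#'
#' @param cohort a `synthetic_cohort` (or any list with `features`,
#'   `clinical`, `labels`).
#' @param plan a [benchmark_plan()].
#' @param seed master seed shared by all cells.
#' @return list with `cells` (summary data.frame), `argmax_category`
#'   (per-modality best radiomic category), `results` (named list of
#'   `cv_result`s).
#' @export
run_benchmark <- function(cohort, plan, seed = 1) {
  results <- list()
  rows <- lapply(seq_len(nrow(plan)), function(ci) {
    cell <- plan[ci, ]
    out <- data.frame(cell, median_mcc = NA_real_, iqr = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      Xc <- .cell_matrix(cohort, cell$source, cell$modality, cell$category)
      spec <- switch(cell$method,
                     svm = pipeline_spec("svm", id = cell$cell_id),
                     none = pipeline_spec("none", id = cell$cell_id),
                     dnetpro_A = pipeline_spec("dnetpro_A",
                                               id = cell$cell_id),
                     dnetpro_B = pipeline_spec("dnetpro_B",
                                               id = cell$cell_id))
      cli <- if (cell$source %in% c("clinical", "combined"))
        cohort$clinical else NULL
      repeated_stratified_cv(spec, Xc, cohort$labels,
                             n_folds = cell$n_folds,
                             n_repeats = cell$n_repeats, seed = seed,
                             clinical = cli)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
      message("cell ", cell$cell_id, " failed: ", out$error)
    } else {
      results[[cell$cell_id]] <<- res
      s <- summarize_cv(res)
      out$median_mcc <- s$median_mcc
      out$iqr <- s$iqr
    }
    out
  })
  cells <- do.call(rbind, rows)
  rad <- cells[cells$source == "radiomic" & is.na(cells$error), ,
               drop = FALSE]
  argmax <- NULL
  if (nrow(rad)) {
    agg <- aggregate(median_mcc ~ modality + category, rad, max)
    argmax <- do.call(rbind, lapply(split(agg, agg$modality), function(d)
      d[which.max(d$median_mcc), c("modality", "category", "median_mcc")]))
    rownames(argmax) <- NULL
  }
  list(cells = cells, argmax_category = argmax, results = results)
}
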