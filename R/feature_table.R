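#' @name feature_table-module
#' @title Radiomic feature tables and their category metadata
#'
#' @description
#' Wide radiomic tables arrive as patients-in-rows CSV files whose column
#' names follow the pyRadiomics naming dialect:
#' `original_<family>_<Feature>`, `log-sigma-<s>-<s>-mm-3D_<family>_<Feature>`
#' (Laplacian-of-Gaussian at scale sigma millimetres) and
#' `wavelet-<XYZ>_<family>_<Feature>` (a 3-letter low/high-pass sub-band
#' code).  This module parses those names into per-column category
#' metadata (modality, filter class, feature family), holds aligned
#' feature/clinical/label tables, and implements the two standardization
#' schemes the pipeline uses: z-scoring (mean / population SD) before
#' classification, and robust scaling (median / interquartile range)
#' before unsupervised embedding.
NULL

.modalities <- c("CE_T1w", "T2w", "clinical")
.filter_classes <- c("Original", "LoG", "Wavelet", "none")
.families <- c("shape", "firstorder", "glcm", "glrlm", "glszm", "ngtdm",
               "gldm", "clinical")
.wavelet_bands <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

#' Parse a pyRadiomics-style feature name
#'
#' Resolves the filter class, feature family and filter parameter from a
#' column name in the extractor dialect.  Names that match no known prefix
#' are treated as clinical covariates (`filter_class = "none"`,
#' `family = "clinical"`).
#'
#' @param column_name a single non-empty feature name.
#' @param modality image modality the column was extracted from, one of
#'   `"CE_T1w"`, `"T2w"`, `"clinical"`.
#' @return a `feature_descriptor`: list with `name`, `modality`,
#'   `filter_class`, `family`, `filter_param` (LoG sigma in mm or wavelet
#'   sub-band code, `NA` otherwise) and `base` (the trailing feature name).
#' @examples
#' parse_feature_name("log-sigma-1-0-mm-3D_firstorder_Skewness", "CE_T1w")
#' @export
parse_feature_name <- function(column_name, modality = "clinical") {
  if (!is.character(column_name) || length(column_name) != 1L ||
      is.na(column_name) || !nzchar(column_name))
    stop("column_name must be a single non-empty string")
  modality <- match.arg(modality, .modalities)
  fam_alt <- paste(setdiff(.families, "clinical"), collapse = "|")
  d <- list(name = column_name, modality = modality,
            filter_class = "none", family = "clinical",
            filter_param = NA_character_, base = column_name)
  re_orig <- paste0("^original_(", fam_alt, ")_(.+)$")
  re_log  <- paste0("^log-sigma-([0-9]+)-([0-9]+)-mm-3D_(", fam_alt, ")_(.+)$")
  re_wav  <- paste0("^wavelet-([LH]{3})_(", fam_alt, ")_(.+)$")
  if (grepl(re_orig, column_name)) {
    m <- regmatches(column_name, regexec(re_orig, column_name))[[1]]
    d$filter_class <- "Original"; d$family <- m[2]; d$base <- m[3]
  } else if (grepl(re_log, column_name)) {
    m <- regmatches(column_name, regexec(re_log, column_name))[[1]]
    sigma <- as.numeric(paste0(m[2], ".", m[3]))
    if (!is.finite(sigma) || sigma <= 0)
      stop("LoG sigma must be a positive decimal: ", column_name)
    d$filter_class <- "LoG"; d$family <- m[4]; d$base <- m[5]
    d$filter_param <- format(sigma, nsmall = 1)
  } else if (grepl(re_wav, column_name)) {
    m <- regmatches(column_name, regexec(re_wav, column_name))[[1]]
    d$filter_class <- "Wavelet"; d$filter_param <- m[2]
    d$family <- m[3]; d$base <- m[4]
  }
  class(d) <- "feature_descriptor"
  d
}

#' @rdname parse_feature_name
#' @param column_names character vector of feature names.
#' @return `parse_feature_names()`: a data.frame with one row per name.
#' @export
parse_feature_names <- function(column_names, modality = "clinical") {
  rows <- lapply(column_names, parse_feature_name, modality = modality)
  do.call(rbind, lapply(rows, function(d)
    data.frame(name = d$name, modality = d$modality,
               filter_class = d$filter_class, family = d$family,
               filter_param = d$filter_param, base = d$base,
               stringsAsFactors = FALSE)))
}

#' Canonical extractor-dialect name for a descriptor
#'
#' Inverse of [parse_feature_name()]: rebuilding the name from the parsed
#' descriptor and re-parsing it is the identity for every name the
#' extractor dialect can emit.
#'
#' @param d a `feature_descriptor`.
#' @return the canonical column name string.
#' @export
canonical_feature_name <- function(d) {
  switch(d$filter_class,
    Original = paste0("original_", d$family, "_", d$base),
    LoG = {
      parts <- strsplit(format(as.numeric(d$filter_param), nsmall = 1),
                        ".", fixed = TRUE)[[1]]
      paste0("log-sigma-", parts[1], "-", parts[2], "-mm-3D_",
             d$family, "_", d$base)
    },
    Wavelet = paste0("wavelet-", d$filter_param, "_", d$family, "_", d$base),
    d$name)
}

#' Construct a feature table
#'
#' @param values numeric matrix, patients in rows, features in columns.
#' @param descriptors data.frame of per-column metadata as produced by
#'   [parse_feature_names()] (one row per column).
#' @param patient_ids character vector of unique patient identifiers.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, descriptors, patient_ids) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values))
  if (nrow(descriptors) != ncol(values))
    stop("descriptors must have one row per feature column")
  if (anyDuplicated(patient_ids))
    stop("patient_ids must be unique")
  if (length(patient_ids) != nrow(values))
    stop("patient_ids must have one entry per row")
  dup <- duplicated(descriptors[, c("modality", "name")])
  if (any(dup))
    stop("duplicate feature names within a modality: ",
         paste(utils::head(descriptors$name[dup], 3), collapse = ", "))
  colnames(values) <- paste(descriptors$modality, descriptors$name, sep = ".")
  rownames(values) <- patient_ids
  structure(list(values = values, descriptors = descriptors,
                 patient_ids = as.character(patient_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", length(x$patient_ids), " patients x ",
      ncol(x$values), " features\n", sep = "")
  tab <- table(x$descriptors$modality, x$descriptors$filter_class)
  print(tab)
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table by modality and filter class
#'
#' @param table a `feature_table`.
#' @param modalities character vector of modalities to keep.
#' @param filter_classes character vector of filter classes to keep.
#' @return a `feature_table` with the matching columns, original order
#'   preserved.
#' @export
subset_by_category <- function(table, modalities = .modalities,
                               filter_classes = .filter_classes) {
  if (length(modalities) == 0 || length(filter_classes) == 0)
    stop("selection sets must be non-empty")
  keep <- table$descriptors$modality %in% modalities &
    table$descriptors$filter_class %in% filter_classes
  if (!any(keep))
    stop("selection matches zero columns (modalities: ",
         paste(modalities, collapse = ","), "; filter classes: ",
         paste(filter_classes, collapse = ","), ")")
  feature_table(table$values[, keep, drop = FALSE],
                table$descriptors[keep, , drop = FALSE],
                table$patient_ids)
}

# ---- standardization ------------------------------------------------------

fit_scaler <- function(X, method = c("zscore", "robust")) {
  method <- match.arg(method)
  if (method == "zscore") {
    center <- colMeans(X)
    scale <- sqrt(colMeans(sweep(X, 2, center)^2)) # population SD
  } else {
    center <- apply(X, 2, median)
    qs <- apply(X, 2, quantile, probs = c(0.25, 0.75), names = FALSE,
                type = 7)
    scale <- qs[2, ] - qs[1, ]
  }
  constant <- !is.finite(scale) | scale < 1e-12
  scale[constant] <- 1
  structure(list(method = method, center = center, scale = scale,
                 constant = constant, features = colnames(X)),
            class = "scaling_params")
}

apply_scaler <- function(params, X) {
  Z <- sweep(sweep(X, 2, params$center), 2, params$scale, "/")
  if (any(params$constant)) Z[, params$constant] <- 0
  Z
}

#' Standardize a feature table
#'
#' Two schemes: `"zscore"` (subtract the column mean, divide by the
#' population standard deviation) and `"robust"` (subtract the median,
#' divide by the interquartile range Q3 - Q1 with linear-interpolation
#' quantiles).  Columns with zero spread are mapped to all-zeros and
#' reported with a warning rather than an error, so cross-validation folds
#' never crash on a degenerate column.  The returned `scaling_params`
#' reproduce the fitted transform on held-out data via [apply_scaling()].
#'
#' @param table a `feature_table`.
#' @param method `"zscore"` or `"robust"`.
#' @return list with elements `table` (the standardized `feature_table`,
#'   carrying a `"standardized"` attribute naming the method) and `params`
#'   (a `scaling_params` object).
#' @export
standardize <- function(table, method = c("zscore", "robust")) {
  method <- match.arg(method)
  params <- fit_scaler(table$values, method)
  out <- apply_scaling(params, table)
  if (any(params$constant))
    warning(sum(params$constant), " constant column(s) mapped to zeros")
  list(table = out, params = params)
}

#' Apply fitted scaling parameters to a feature table
#'
#' @param params a `scaling_params` object from [standardize()].
#' @param table a `feature_table` with the same columns (e.g. a held-out
#'   split).
#' @return the transformed `feature_table`.
#' @export
apply_scaling <- function(params, table) {
  if (!identical(params$features, colnames(table$values)))
    stop("scaling parameters were fitted on different columns")
  out <- table
  out$values <- apply_scaler(params, table$values)
  attr(out, "standardized") <- params$method
  out
}

# ---- clinical tables ------------------------------------------------------

#' Clinical table of categorical variables
#'
#' @param patient_ids character vector of unique patient identifiers.
#' @param data data.frame of categorical variables (coerced to factors);
#'   `NA` is the missing marker.
#' @param schema optional named list giving the declared level set of each
#'   variable; defaults to the observed levels.  Codes outside the declared
#'   set are an error.
#' @return an object of class `clinical_table`.
#' @export
clinical_table <- function(patient_ids, data, schema = NULL) {
  if (anyDuplicated(patient_ids)) stop("patient_ids must be unique")
  if (nrow(data) != length(patient_ids))
    stop("data must have one row per patient")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(schema))
    schema <- lapply(data, function(x) sort(unique(as.character(x[!is.na(x)]))))
  for (v in names(data)) {
    x <- as.character(data[[v]])
    bad <- !is.na(x) & !(x %in% schema[[v]])
    if (any(bad))
      stop("variable '", v, "' contains codes outside its declared levels: ",
           paste(unique(x[bad]), collapse = ", "))
    data[[v]] <- factor(x, levels = schema[[v]])
  }
  structure(list(patient_ids = as.character(patient_ids), data = data,
                 schema = schema),
            class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat("<clinical_table> ", length(x$patient_ids), " patients, ",
      ncol(x$data), " variables\n", sep = "")
  for (v in names(x$data))
    cat("  ", v, ": ", paste(x$schema[[v]], collapse = "/"),
        "  (", sum(is.na(x$data[[v]])), " missing)\n", sep = "")
  invisible(x)
}

#' Fit a clinical encoder on a training split
#'
#' Missing codes are imputed with the training-split mode (ties broken by
#' level order); binary variables are integer-coded 0/1 by level order and
#' variables with three or more levels are one-hot encoded.
#'
#' @param clinical a `clinical_table` (training split).
#' @return a `clinical_encoder` storing per-variable modes and the
#'   encoding layout.
#' @export
fit_clinical_encoder <- function(clinical) {
  modes <- lapply(names(clinical$data), function(v) {
    tab <- table(clinical$data[[v]])
    if (sum(tab) == 0) clinical$schema[[v]][1] else names(tab)[which.max(tab)]
  })
  names(modes) <- names(clinical$data)
  structure(list(schema = clinical$schema, modes = modes),
            class = "clinical_encoder")
}

#' Encode a clinical table as a numeric design matrix
#'
#' @param encoder a `clinical_encoder` from [fit_clinical_encoder()].
#' @param clinical a `clinical_table` to encode (training or held-out).
#' @return numeric matrix; attribute `"imputation_log"` is a data.frame of
#'   the (patient, variable) cells that were mode-imputed.
#' @export
encode_clinical <- function(encoder, clinical) {
  cols <- list()
  log_rows <- list()
  for (v in names(clinical$data)) {
    x <- clinical$data[[v]]
    miss <- is.na(x)
    if (any(miss)) {
      x[miss] <- encoder$modes[[v]]
      log_rows[[v]] <- data.frame(
        patient_id = clinical$patient_ids[miss], variable = v,
        imputed = encoder$modes[[v]], stringsAsFactors = FALSE)
    }
    lv <- encoder$schema[[v]]
    if (length(lv) <= 2) {
      cols[[v]] <- as.numeric(x == lv[length(lv)])
    } else {
      for (l in lv)
        cols[[paste(v, l, sep = ".")]] <- as.numeric(x == l)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- clinical$patient_ids
  attr(m, "imputation_log") <-
    if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(patient_id = character(), variable = character(),
                 imputed = character())
  m
}

#' Clinical covariates as a feature table
#'
#' Encodes a clinical table (see [encode_clinical()]) and wraps it as a
#' `feature_table` with modality `"clinical"` so clinical covariates can be
#' concatenated with radiomic features.
#'
#' @inheritParams encode_clinical
#' @return a `feature_table`.
#' @export
clinical_feature_table <- function(encoder, clinical) {
  m <- encode_clinical(encoder, clinical)
  feature_table(m, parse_feature_names(colnames(m), "clinical"),
                clinical$patient_ids)
}

#' Combine feature tables column-wise
#'
#' @param ... `feature_table` objects sharing identical patient ids in the
#'   same order.
#' @return a single `feature_table`.
#' @export
cbind_feature_tables <- function(...) {
  tabs <- list(...)
  ids <- tabs[[1]]$patient_ids
  for (t in tabs)
    if (!identical(t$patient_ids, ids))
      stop("feature tables must share identical patient ids in order")
  feature_table(do.call(cbind, lapply(tabs, `[[`, "values")),
                do.call(rbind, lapply(tabs, `[[`, "descriptors")),
                ids)
}

# ---- I/O ------------------------------------------------------------------

#' Load and align radiomic and clinical CSV tables
#'
#' Reads one CSV per image modality (patients in rows, features in columns,
#' one id column) plus a clinical CSV, aligns everything on the
#' intersection of patient ids (order taken from the first radiomic file),
#' and extracts the binary outcome labels.
#'
#' @param radiomic_paths named character vector of CSV paths; names are the
#'   modalities (`"CE_T1w"`, `"T2w"`).
#' @param clinical_path path to the clinical CSV.
#' @param label_column name of the binary outcome column in the clinical
#'   file.
#' @param center_column optional name of the acquisition-center column.
#' @param id_column name of the patient-id column, default `"patient_id"`.
#' @return list with `features` (`feature_table`), `clinical`
#'   (`clinical_table`), `labels` (0/1 integer vector), `centers` (factor or
#'   `NULL`) and `dropped` (ids present in some file but not all).
#' @export
load_tables <- function(radiomic_paths, clinical_path, label_column,
                        center_column = NULL, id_column = "patient_id") {
  stopifnot(length(radiomic_paths) >= 1, !is.null(names(radiomic_paths)))
  rad <- lapply(radiomic_paths, read.csv, check.names = FALSE,
                stringsAsFactors = FALSE)
  cli <- read.csv(clinical_path, check.names = FALSE,
                  stringsAsFactors = FALSE, na.strings = c("NA", ""))
  for (df in c(rad, list(cli)))
    if (!id_column %in% names(df))
      stop("id column '", id_column, "' missing from an input file")
  ids <- as.character(rad[[1]][[id_column]])
  for (df in rad[-1]) ids <- ids[ids %in% as.character(df[[id_column]])]
  ids <- ids[ids %in% as.character(cli[[id_column]])]
  if (length(ids) == 0)
    stop("patient id intersection across input files is empty")
  all_ids <- unique(c(unlist(lapply(rad, function(d)
    as.character(d[[id_column]]))), as.character(cli[[id_column]])))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped))
    message("dropped ", length(dropped),
            " patient(s) absent from at least one file: ",
            paste(utils::head(dropped, 5), collapse = ", "))

  tabs <- lapply(names(rad), function(mod) {
    df <- rad[[mod]]
    rownames(df) <- as.character(df[[id_column]])
    df <- df[ids, setdiff(names(df), id_column), drop = FALSE]
    feature_table(as.matrix(df), parse_feature_names(names(df), mod), ids)
  })
  features <- do.call(cbind_feature_tables, tabs)

  rownames(cli) <- as.character(cli[[id_column]])
  cli <- cli[ids, , drop = FALSE]
  if (!label_column %in% names(cli))
    stop("label column '", label_column, "' missing from the clinical file")
  lab_raw <- cli[[label_column]]
  lab_lv <- sort(unique(as.character(lab_raw[!is.na(lab_raw)])))
  if (length(lab_lv) != 2)
    stop("labels must be binary; observed levels: ",
         paste(lab_lv, collapse = ", "))
  labels <- as.integer(as.character(lab_raw) == lab_lv[2])
  centers <- NULL
  drop_cols <- c(id_column, label_column)
  if (!is.null(center_column)) {
    centers <- factor(cli[[center_column]])
    drop_cols <- c(drop_cols, center_column)
  }
  clinical <- clinical_table(ids, cli[, setdiff(names(cli), drop_cols),
                                      drop = FALSE])
  list(features = features, clinical = clinical, labels = labels,
       centers = centers, dropped = dropped)
}
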