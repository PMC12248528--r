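#' @name clinical_association-module
#' @title Bias-corrected Cramer's V association screening
#'
#' @description
#' Categorical association between clinical variables and the binary tumor
#' outcome is quantified with Cramer's V, and with its Bergsma-Wicher
#' bias-corrected variant which subtracts the chance-level phi-squared
#' expected under independence before normalizing.  The plain estimator is
#' biased upward in small samples (it is positive in expectation even under
#' independence); the corrected estimator removes most of that bias and is
#' the statistic reported by the screening.
NULL

# drop all-zero rows/columns, warn; returns a validated counts matrix
.clean_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency table must contain non-negative integer counts")
  if (sum(counts) < 1) stop("contingency table must have a positive total")
  zr <- rowSums(counts) == 0; zc <- colSums(counts) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s) from the contingency table")
    counts <- counts[!zr, !zc, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table needs >= 2 non-empty rows and columns")
  counts
}

#' Cramer's V
#'
#' `V = sqrt((chi^2 / n) / min(k - 1, r - 1))` for an `r x k` contingency
#' table, with the uncorrected (no continuity correction) Pearson
#' chi-squared statistic.  All-zero rows or columns are dropped with a
#' warning before the computation.
#'
#' @param counts contingency table (matrix of non-negative integer counts,
#'   at least 2 x 2 after dropping empty margins).
#' @return V in `[0, 1]`.
#' @examples
#' cramers_v(matrix(c(8, 2, 2, 8), 2)) # 0.6
#' @export
cramers_v <- function(counts) {
  counts <- .clean_contingency(counts)
  n <- sum(counts)
  chi2 <- suppressWarnings(
    unname(chisq.test(counts, correct = FALSE)$statistic))
  phi2 <- chi2 / n
  min(1, sqrt(phi2 / min(dim(counts) - 1)))
}

#' Bias-corrected Cramer's V (Bergsma-Wicher)
#'
#' Applies the small-sample bias correction:
#' `phi2~ = max(0, phi2 - (k-1)(r-1)/(n-1))`,
#' `k~ = k - (k-1)^2/(n-1)`, `r~ = r - (r-1)^2/(n-1)`,
#' `V~ = sqrt(phi2~ / min(k~ - 1, r~ - 1))`.
#' Always `V~ <= V`, with equality only when the bias term vanishes.
#'
#' @inheritParams cramers_v
#' @return corrected V in `[0, 1]`.
#' @export
cramers_v_corrected <- function(counts) {
  counts <- .clean_contingency(counts)
  n <- sum(counts)
  if (n < 2) stop("bias correction requires n >= 2")
  r <- nrow(counts); k <- ncol(counts)
  chi2 <- suppressWarnings(
    unname(chisq.test(counts, correct = FALSE)$statistic))
  phi2 <- chi2 / n
  phi2_t <- max(0, phi2 - (k - 1) * (r - 1) / (n - 1))
  k_t <- k - (k - 1)^2 / (n - 1)
  r_t <- r - (r - 1)^2 / (n - 1)
  min(1, sqrt(phi2_t / min(k_t - 1, r_t - 1)))
}

#' Per-variable association screening against the outcome
#'
#' Computes the bias-corrected Cramer's V between each clinical variable
#' and the binary outcome on that variable's complete cases (listwise
#' deletion across all variables would discard too much of an incompletely
#' recorded table).  Variables with fewer than two observed levels, or a
#' constant outcome among their complete cases, are reported as not
#' computable rather than failing the screen.
#'
#' @param clinical a `clinical_table`.
#' @param labels binary outcome vector aligned with the clinical table.
#' @return data.frame with one row per variable (`variable`, `v_corrected`,
#'   `v_plain`, `n_complete`, `computable`, `reason`), sorted by descending
#'   corrected V with non-computable variables last.
#' @export
associate_clinical <- function(clinical, labels) {
  stopifnot(inherits(clinical, "clinical_table"),
            length(labels) == length(clinical$patient_ids))
  rows <- lapply(names(clinical$data), function(v) {
    x <- clinical$data[[v]]
    ok <- !is.na(x)
    out <- data.frame(variable = v, v_corrected = NA_real_,
                      v_plain = NA_real_, n_complete = sum(ok),
                      computable = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    if (sum(ok) < 2) {
      out$reason <- "fewer than 2 complete cases"
      return(out)
    }
    xs <- droplevels(factor(x[ok]))
    ys <- factor(labels[ok])
    if (nlevels(xs) < 2) {
      out$reason <- "single observed level"
      return(out)
    }
    if (nlevels(ys) < 2) {
      out$reason <- "constant outcome"
      return(out)
    }
    tab <- table(ys, xs)
    out$v_corrected <- cramers_v_corrected(tab)
    out$v_plain <- cramers_v(tab)
    out$computable <- TRUE
    out
  })
  res <- do.call(rbind, rows)
  res[order(!res$computable, -ifelse(is.na(res$v_corrected), -Inf,
                                     res$v_corrected)), , drop = FALSE]
}
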