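#' @name synthetic_cohort-module
#' @title Synthetic multi-center radiomic cohort generator
#'
#' @description
#' The pipeline was designed around a two-center cohort of 145 patients
#' (76 malignant, 69 benign) with ~1200 highly redundant radiomic
#' variables per MRI modality organized in Original / LoG / Wavelet
#' blocks, plus categorical clinical variables of which symptoms, tumor
#' size and gross adjacent site involvement carry the strongest outcome
#' association (bias-corrected Cramer's V 0.41 / 0.38 / 0.38).  Patient
#' data of that kind is not publicly depositable, so this module generates
#' cohorts with the same statistical structure: Gaussian equicorrelated
#' feature blocks, a small set of planted discriminative features,
#' near-duplicate redundant feature pairs, clinical variables calibrated
#' to target population Cramer's V values, and an additive per-center
#' batch shift.  Every downstream stage of the package is testable on
#' these cohorts, and the planted truth is returned alongside the data.
NULL

#' Default radiomic block layout
#'
#' Mirrors a standard extractor run per modality: 107 Original features
#' (including shape), 4 LoG scales x 93 features, 8 wavelet sub-bands x 93
#' features.  Planted informative features sit by default in the CE T1-w
#' LoG block, the T2-w Original block and (fewer) in both Wavelet blocks,
#' emulating the per-modality category structure the benchmark is meant to
#' recover.
#'
#' @param scale multiply all block sizes (and informative counts) by this
#'   factor and round up; use a small value for fast experiments.
#' @return data.frame with columns `modality`, `filter_class`,
#'   `n_features`, `n_informative`.
#' @export
default_blocks <- function(scale = 1) {
  b <- expand.grid(modality = c("CE_T1w", "T2w"),
                   filter_class = c("Original", "LoG", "Wavelet"),
                   stringsAsFactors = FALSE)
  b$n_features <- ifelse(b$filter_class == "Original", 107,
                         ifelse(b$filter_class == "LoG", 372, 744))
  b$n_informative <- 0L
  b$n_informative[b$modality == "CE_T1w" & b$filter_class == "LoG"] <- 10L
  b$n_informative[b$modality == "T2w" & b$filter_class == "Original"] <- 10L
  b$n_informative[b$filter_class == "Wavelet"] <- 5L
  if (scale != 1) {
    b$n_features <- pmax(2L, as.integer(ceiling(b$n_features * scale)))
    b$n_informative <- pmin(b$n_features,
                            as.integer(ceiling(b$n_informative * scale)))
  }
  b
}

#' Default clinical schema
#'
#' Level sets and marginal frequencies of the study's clinical and
#' radiological variables, with target bias-corrected Cramer's V against
#' the outcome: 0.41 for symptoms, 0.38 for tumor size and gross adjacent
#' site involvement, and a low 0.10 for all remaining variables (for which
#' no anchor exists).  The five variables recorded incompletely in the
#' source cohort carry a 1% missing rate.
#'
#' @return named list; each element has `levels`, `marginal`, `target_v`,
#'   `missing_rate`.
#' @export
default_clinical_schema <- function() {
  v <- function(levels, counts, target_v = 0.10, missing_rate = 0) {
    list(levels = levels, marginal = counts / sum(counts),
         target_v = target_v, missing_rate = missing_rate)
  }
  list(
    sex = v(c("female", "male"), c(41, 104)),
    symptoms = v(c("nonspecific", "red_flags"), c(66, 79), target_v = 0.41),
    tumor_size = v(c("lt5cm", "ge5cm"), c(61, 83), target_v = 0.38,
                   missing_rate = 0.01),
    side = v(c("left", "right", "bilateral"), c(68, 73, 4)),
    margins = v(c("well_defined", "ill_defined"), c(48, 96)),
    pattern = v(c("homogeneous", "inhomogeneous"), c(30, 114)),
    necrosis = v(c("ge10pct", "lt10pct"), c(85, 59)),
    t2_low_signal = v(c("gt50pct", "le50pct"), c(42, 102)),
    cystic_component = v(c("yes", "no"), c(64, 80)),
    septation = v(c("yes", "no"), c(12, 132)),
    bone_involvement = v(c("yes", "no"), c(82, 62), missing_rate = 0.01),
    perineural_spread = v(c("yes", "no"), c(23, 121), missing_rate = 0.01),
    midline_crossing = v(c("yes", "no"), c(50, 94)),
    epicenter = v(c("ethmoid_sinus", "maxillary_sinus", "nasal_cavity",
                    "frontal_sinus", "sphenoid_sinus"),
                  c(47, 47, 36, 6, 6), missing_rate = 0.01),
    gross_adjacent_involvement = v(c("no", "yes"), c(123, 21),
                                   target_v = 0.38, missing_rate = 0.01)
  )
}

#' Simulation configuration
#'
#' @param n_patients cohort size; default 145.
#' @param class_balance fraction of malignant patients; default 0.52
#'   (76/145).
#' @param blocks radiomic block layout, see [default_blocks()].
#' @param effect_size standardized mean difference (in within-class SD
#'   units) added to planted informative features for the malignant class.
#' @param block_rho exchangeable within-block correlation in `[0, 1)`.
#' @param n_redundant_pairs number of near-duplicate feature pairs planted
#'   across blocks (copy + small noise, correlation ~0.99).
#' @param n_xor_pairs optional number of feature pairs that are
#'   individually uninformative but jointly discriminative (class-dependent
#'   sign of their correlation); exercises couple-based selection.
#' @param clinical_schema see [default_clinical_schema()].
#' @param batch_shift additive per-center offset, in SD units, applied to
#'   every radiomic column of center-B patients.
#' @param center_balance fraction of patients from center A; default 0.82
#'   (119/145).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration including this seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 145, class_balance = 76 / 145,
                       blocks = default_blocks(), effect_size = 0.8,
                       block_rho = 0.4, n_redundant_pairs = 20,
                       n_xor_pairs = 0,
                       clinical_schema = default_clinical_schema(),
                       batch_shift = 0.5, center_balance = 119 / 145,
                       seed = 42) {
  stopifnot(n_patients >= 2,
            class_balance > 0, class_balance < 1,
            center_balance > 0, center_balance < 1,
            effect_size >= 0, block_rho >= 0, block_rho < 1,
            n_redundant_pairs >= 0, n_xor_pairs >= 0)
  if (any(blocks$n_informative > blocks$n_features))
    stop("n_informative cannot exceed block size")
  for (v in names(clinical_schema)) {
    sc <- clinical_schema[[v]]
    if (length(sc$levels) < 2) stop("variable '", v, "' needs >= 2 levels")
    if (sc$target_v < 0 || sc$target_v > 1)
      stop("target V for '", v, "' must be in [0, 1]")
  }
  structure(list(n_patients = n_patients, class_balance = class_balance,
                 blocks = blocks, effect_size = effect_size,
                 block_rho = block_rho,
                 n_redundant_pairs = n_redundant_pairs,
                 n_xor_pairs = n_xor_pairs,
                 clinical_schema = clinical_schema,
                 batch_shift = batch_shift,
                 center_balance = center_balance,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Population Cramer's V of a binary outcome vs a categorical variable with
# class-conditional distributions p1 (cases) and p0 (controls).
population_cramers_v <- function(p1, p0, class_balance) {
  joint <- rbind(class_balance * p1, (1 - class_balance) * p0)
  rs <- rowSums(joint); cs <- colSums(joint)
  keep <- cs > 0
  e <- outer(rs, cs[keep])
  phi2 <- sum((joint[, keep, drop = FALSE] - e)^2 / e)
  sqrt(phi2 / min(1, sum(keep) - 1))
}

#' Calibrate class-conditional distributions to a target Cramer's V
#'
#' Finds class-conditional categorical distributions whose population
#' Cramer's V against the binary outcome equals `target_v`.  When a
#' marginal distribution is supplied (the generator's path) a
#' one-parameter exponential-tilt family preserving that marginal is
#' solved by root finding; otherwise a symmetric tilt around the uniform
#' marginal is used.
#'
#' @param levels character vector of level names (>= 2).
#' @param target_v target population Cramer's V in `[0, 1)`; `1` is
#'   accepted for binary variables without a fixed marginal (deterministic
#'   level per class).
#' @param class_balance population fraction of cases.
#' @param marginal optional marginal level distribution to preserve.
#' @return list with `p1` (distribution given case) and `p0` (given
#'   control), each summing to one; achieved V is within 1e-6 of target.
#' @export
calibrate_association <- function(levels, target_v, class_balance,
                                  marginal = NULL) {
  k <- length(levels)
  stopifnot(k >= 2, target_v >= 0, target_v <= 1,
            class_balance > 0, class_balance < 1)
  pi1 <- class_balance
  if (is.null(marginal)) {
    if (target_v >= 1) {
      if (k != 2) stop("target V = 1 is unreachable for > 2 levels here")
      return(list(p1 = setNames(c(0, 1), levels),
                  p0 = setNames(c(1, 0), levels)))
    }
    m <- rep(1 / k, k)
  } else {
    stopifnot(length(marginal) == k, all(marginal > 0))
    m <- marginal / sum(marginal)
    if (target_v >= 1) stop("target V = 1 unreachable with a fixed marginal")
  }
  if (target_v == 0)
    return(list(p1 = setNames(m, levels), p0 = setNames(m, levels)))
  s <- seq(0, 1, length.out = k)
  cond_at <- function(theta) {
    lw <- log(m) + theta * s
    p1 <- exp(lw - max(lw)); p1 <- p1 / sum(p1)
    p0 <- (m - pi1 * p1) / (1 - pi1)
    list(p1 = p1, p0 = p0)
  }
  feasible <- function(theta) all(cond_at(theta)$p0 > -1e-12)
  v_at <- function(theta) {
    cc <- cond_at(theta)
    population_cramers_v(cc$p1, pmax(cc$p0, 0), pi1)
  }
  # locate the feasibility edge, then check reachability
  lo_edge <- 0; hi_edge <- 1
  while (feasible(hi_edge) && hi_edge < 1024) {
    lo_edge <- hi_edge; hi_edge <- hi_edge * 2
  }
  if (feasible(hi_edge)) {
    lo_edge <- hi_edge
  } else {
    for (i in 1:60) {
      mid <- (lo_edge + hi_edge) / 2
      if (feasible(mid)) lo_edge <- mid else hi_edge <- mid
    }
  }
  theta_max <- lo_edge
  if (v_at(theta_max) < target_v - 1e-9)
    stop("target V = ", target_v, " is unreachable for this level set ",
         "(max attainable ", round(v_at(theta_max), 4), ")")
  root <- uniroot(function(th) v_at(th) - target_v, c(0, theta_max),
                  tol = 1e-12)
  cc <- cond_at(root$root)
  list(p1 = setNames(cc$p1, levels), p0 = setNames(pmax(cc$p0, 0), levels))
}

# deterministic synthetic feature names in the extractor dialect
.block_feature_names <- function(filter_class, n) {
  fams <- setdiff(.families, c("clinical", "shape"))
  prefix <- switch(filter_class,
    Original = "original_",
    LoG = paste0("log-sigma-",
                 c("0-5", "1-0", "1-5", "2-0")[(seq_len(n) - 1) %% 4 + 1],
                 "-mm-3D_"),
    Wavelet = paste0("wavelet-",
                     .wavelet_bands[(seq_len(n) - 1) %% 8 + 1], "_"))
  fam <- fams[(seq_len(n) - 1) %% length(fams) + 1]
  paste0(prefix, fam, "_", sprintf("Synthetic%04d", seq_len(n)))
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [sim_config()]: radiomic blocks from an
#' equicorrelated multivariate normal (common-factor construction),
#' a `+effect_size` shift on planted informative columns for malignant
#' patients, near-duplicate redundant pairs, clinical variables sampled
#' from Cramer's-V-calibrated class conditionals, and an additive batch
#' shift on all radiomic columns of center-B patients.  Deterministic:
#' the same configuration (including its seed) yields a bit-identical
#' cohort.
#'
#' @param config a `sim_config`.
#' @return an object of class `synthetic_cohort`: list with `features`
#'   (`feature_table`), `clinical` (`clinical_table`), `labels` (0/1,
#'   1 = malignant), `centers` (factor A/B), `truth` (planted informative
#'   feature names, redundant pairs, xor pairs) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  with_seed(config$seed, {
    n_mal <- round(n * config$class_balance)
    labels <- integer(n)
    labels[sample.int(n, n_mal)] <- 1L
    n_a <- round(n * config$center_balance)
    centers <- rep("B", n)
    centers[sample.int(n, n_a)] <- "A"
    centers <- factor(centers, levels = c("A", "B"))
    patient_ids <- sprintf("P%03d", seq_len(n))

    blocks <- config$blocks
    rho <- config$block_rho
    values <- NULL; descs <- NULL
    informative <- character(); redundant <- NULL; xor_names <- NULL
    # spread redundant / xor pairs across blocks round-robin
    red_per_block <- diff(round(seq(0, config$n_redundant_pairs,
                                    length.out = nrow(blocks) + 1)))
    xor_per_block <- diff(round(seq(0, config$n_xor_pairs,
                                    length.out = nrow(blocks) + 1)))
    for (bi in seq_len(nrow(blocks))) {
      p <- blocks$n_features[bi]
      nm <- .block_feature_names(blocks$filter_class[bi], p)
      z <- rnorm(n)
      X <- sqrt(rho) * matrix(z, n, p) +
        sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
      ninf <- blocks$n_informative[bi]
      inf_idx <- if (ninf > 0) sample.int(p, ninf) else integer()
      if (ninf > 0)
        X[labels == 1L, inf_idx] <- X[labels == 1L, inf_idx] +
          config$effect_size
      # redundant near-duplicates: overwrite a non-informative column with
      # a noisy copy of another column
      nred <- red_per_block[bi]
      red_rows <- NULL
      if (nred > 0) {
        free <- setdiff(seq_len(p), inf_idx)
        if (length(free) >= 2 * nred) {
          pick <- sample(free, 2 * nred)
          src <- pick[seq_len(nred)]; dst <- pick[nred + seq_len(nred)]
          X[, dst] <- X[, src] + rnorm(n * nred, sd = 0.15)
          red_rows <- data.frame(
            source = paste(blocks$modality[bi], nm[src], sep = "."),
            twin = paste(blocks$modality[bi], nm[dst], sep = "."),
            stringsAsFactors = FALSE)
        }
      }
      # xor pairs: individually null, jointly discriminative via a
      # class-dependent sign of the within-pair correlation
      nxor <- xor_per_block[bi]
      if (nxor > 0) {
        free <- setdiff(seq_len(p), c(inf_idx,
                                      if (!is.null(red_rows)) pick))
        if (length(free) >= 2 * nxor) {
          pk <- sample(free, 2 * nxor)
          a <- pk[seq_len(nxor)]; b <- pk[nxor + seq_len(nxor)]
          sgn <- ifelse(labels == 1L, 1, -1)
          for (q in seq_len(nxor)) {
            u <- rnorm(n)
            X[, a[q]] <- u
            X[, b[q]] <- sgn * 0.9 * u + sqrt(1 - 0.81) * rnorm(n)
          }
          xor_names <- rbind(xor_names, data.frame(
            a = paste(blocks$modality[bi], nm[a], sep = "."),
            b = paste(blocks$modality[bi], nm[b], sep = "."),
            stringsAsFactors = FALSE))
        }
      }
      values <- cbind(values, X)
      descs <- rbind(descs, parse_feature_names(nm, blocks$modality[bi]))
      if (ninf > 0)
        informative <- c(informative,
                         paste(blocks$modality[bi], nm[inf_idx], sep = "."))
      redundant <- rbind(redundant, red_rows)
    }
    if (config$batch_shift != 0)
      values[centers == "B", ] <- values[centers == "B", ] +
        config$batch_shift
    features <- feature_table(values, descs, patient_ids)

    # clinical variables from calibrated class conditionals
    cdata <- list()
    for (v in names(config$clinical_schema)) {
      sc <- config$clinical_schema[[v]]
      cc <- calibrate_association(sc$levels, sc$target_v,
                                  config$class_balance, sc$marginal)
      x <- character(n)
      for (i in seq_len(n)) {
        pr <- if (labels[i] == 1L) cc$p1 else cc$p0
        x[i] <- sample(sc$levels, 1, prob = pr)
      }
      if (sc$missing_rate > 0)
        x[runif(n) < sc$missing_rate] <- NA_character_
      cdata[[v]] <- x
    }
    clinical <- clinical_table(patient_ids,
                               as.data.frame(cdata,
                                             stringsAsFactors = FALSE),
                               schema = lapply(config$clinical_schema,
                                               `[[`, "levels"))
    structure(list(features = features, clinical = clinical,
                   labels = labels, centers = centers,
                   truth = list(informative = informative,
                                redundant_pairs = redundant,
                                xor_pairs = xor_names),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", length(x$labels),
      "(", sum(x$labels), "malignant /", sum(1 - x$labels), "benign ),",
      ncol(x$features$values), "radiomic features,",
      ncol(x$clinical$data), "clinical variables\n")
  cat("  centers:", paste(names(table(x$centers)), table(x$centers),
                          collapse = ", ", sep = "="),
      " batch shift:", x$config$batch_shift, "SD\n")
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the same layout [load_tables()] consumes: one radiomic CSV per
#' modality with dialect feature names, a clinical CSV carrying the
#' outcome and center columns, and a `truth.json` manifest of the planted
#' structure.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (mod in unique(cohort$features$descriptors$modality)) {
    keep <- cohort$features$descriptors$modality == mod
    df <- as.data.frame(cohort$features$values[, keep, drop = FALSE])
    names(df) <- cohort$features$descriptors$name[keep]
    df <- cbind(patient_id = cohort$features$patient_ids, df)
    p <- file.path(dir, paste0(mod, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths[mod] <- p
  }
  cli <- cohort$clinical$data
  cli <- data.frame(patient_id = cohort$clinical$patient_ids,
                    lapply(cli, as.character),
                    outcome = ifelse(cohort$labels == 1L, "malignant",
                                     "benign"),
                    center = as.character(cohort$centers),
                    stringsAsFactors = FALSE, check.names = FALSE)
  write.csv(cli, file.path(dir, "clinical.csv"), row.names = FALSE,
            na = "")
  paths["clinical"] <- file.path(dir, "clinical.csv")
  jsonlite::write_json(cohort$truth[c("informative")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  paths["truth"] <- file.path(dir, "truth.json")
  invisible(paths)
}
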