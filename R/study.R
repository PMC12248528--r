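#' @name cli_reporting-module
#' @title Study orchestration, manifests and reports
#'
#' @description
#' `run_study()` executes the full workflow on a synthetic cohort —
#' simulate, batch-effect audit, clinical association screen, benchmark,
#' signature selection — wiring each stage's output into the next and
#' writing every table as a CSV artifact plus a JSON run manifest
#' (configuration snapshot, seeds, package version, stage timings, file
#' digests).  All randomness flows from the single master seed through
#' named per-stage sub-seeds, so a re-run with the same configuration is
#' bit-identical.  The numbered scripts under `analysis/` are thin
#' narrative drivers over these functions.
NULL

#' Study configuration
#'
#' @param sim a [sim_config()] describing the cohort.
#' @param plan a [benchmark_plan()].
#' @param dnetpro a [dnetpro_config()] used for the final signature
#'   extraction.
#' @param select_modality,select_category the feature subset handed to the
#'   DNetPRO signature stage (defaults to the CE T1-w LoG block, combined
#'   with clinical covariates).
#' @param min_cluster_size audit clustering parameter.
#' @return a `study_config` list.
#' @export
study_config <- function(sim = sim_config(),
                         plan = benchmark_plan(n_repeats = 10),
                         dnetpro = dnetpro_config(),
                         select_modality = "CE_T1w",
                         select_category = "LoG",
                         min_cluster_size = 5) {
  structure(list(sim = sim, plan = plan, dnetpro = dnetpro,
                 select_modality = select_modality,
                 select_category = select_category,
                 min_cluster_size = min_cluster_size),
            class = "study_config")
}

.write_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full study workflow
#'
#' Stages, in order: `simulate` (cohort CSVs + truth manifest), `audit`
#' (embedding coordinates, cluster labels, enrichment p-values),
#' `associate` (per-variable corrected Cramer's V), `benchmark` (per-cell
#' median MCC table and long-format scores), `select` (DNetPRO signature,
#' GraphML + node/edge tables).  A failing stage halts the run with the
#' stage name; artifacts of completed stages are preserved.
#'
#' @param config a [study_config()].
#' @param out_dir output directory.
#' @param seed master seed; stage sub-seeds are derived from it.
#' @return invisibly, the manifest list.
#' @export
run_study <- function(config, out_dir, seed = 1) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(packageVersion("radsig")),
                   master_seed = as.integer(seed), stages = list())
  timings <- list()
  artifacts <- character()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  cohort <- stage("simulate", {
    cfg <- unclass(config$sim)
    cfg$seed <- derive_seed(seed, 1)
    co <- generate_cohort(do.call(sim_config, cfg))
    paths <- write_cohort(co, file.path(out_dir, "cohort"))
    artifacts <<- c(artifacts, paths)
    co
  })

  audit <- stage("audit", {
    au <- audit_report(cohort$features, cohort$centers, cohort$labels,
                       seed = derive_seed(seed, 2),
                       min_cluster_size = config$min_cluster_size)
    artifacts <<- c(artifacts,
      .write_csv(data.frame(patient_id = rownames(au$embedding$coords),
                            au$embedding$coords,
                            cluster = au$clusters$labels),
                 file.path(out_dir, "audit_embedding.csv")),
      .write_csv({
        lab_df <- function(lab, d)
          if (nrow(d)) cbind(label = lab, d)
          else cbind(data.frame(label = character()), d)
        rbind(lab_df("center", au$enrichment$center),
              lab_df("tumor", au$enrichment$tumor))
      }, file.path(out_dir, "audit_enrichment.csv")))
    au
  })

  assoc <- stage("associate", {
    a <- associate_clinical(cohort$clinical, cohort$labels)
    artifacts <<- c(artifacts,
                    .write_csv(a, file.path(out_dir, "association.csv")))
    a
  })

  bench <- stage("benchmark", {
    b <- run_benchmark(cohort, config$plan, seed = derive_seed(seed, 3))
    long <- do.call(rbind, lapply(names(b$results), function(id)
      data.frame(cell_id = id, split = seq_along(b$results[[id]]$scores),
                 mcc = b$results[[id]]$scores)))
    artifacts <<- c(artifacts,
      .write_csv(b$cells, file.path(out_dir, "benchmark_summary.csv")),
      .write_csv(long, file.path(out_dir, "benchmark_scores.csv")))
    if (!is.null(b$argmax_category))
      artifacts <<- c(artifacts,
        .write_csv(b$argmax_category,
                   file.path(out_dir, "benchmark_argmax.csv")))
    b
  })

  sig <- stage("select", {
    rad <- subset_by_category(cohort$features, config$select_modality,
                              config$select_category)
    enc <- fit_clinical_encoder(cohort$clinical)
    cli <- clinical_feature_table(enc, cohort$clinical)
    X <- cbind_feature_tables(rad, cli)$values
    res <- procedure_A(X, cohort$labels, config$dnetpro,
                       seed = derive_seed(seed, 4))
    nodes <- export_signature(res$signature,
                              file.path(out_dir, "signature"))
    artifacts <<- c(artifacts,
                    file.path(out_dir, c("signature.graphml",
                                         "signature_edges.csv",
                                         "signature_nodes.csv")))
    res
  })

  manifest$config <- list(
    sim = unclass(config$sim[setdiff(names(config$sim),
                                     c("blocks", "clinical_schema"))]),
    n_blocks = nrow(config$sim$blocks),
    plan_cells = nrow(config$plan),
    dnetpro = unclass(config$dnetpro),
    select = paste(config$select_modality, config$select_category,
                   sep = "/"),
    min_cluster_size = config$min_cluster_size)
  manifest$stages <- timings
  manifest$artifacts <- as.list(setNames(
    as.character(tools::md5sum(artifacts)), basename(artifacts)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, cohort = cohort, audit = audit,
                 association = assoc, benchmark = bench,
                 signature = sig))
}

#' Render a plain-text report of a completed run
#'
#' Collects the association table, audit p-values, benchmark summary and
#' the best signature's node table from a [run_study()] output directory
#' into one human-readable document.  Missing artifacts are listed as
#' "not run" rather than failing.
#'
#' @param out_dir directory written by [run_study()].
#' @param path output file; default `report.txt` inside `out_dir`.
#' @return invisibly, the report path.
#' @export
render_report <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  section <- function(title, file, fmt) {
    w(""); w("== ", title, " ==")
    fp <- file.path(out_dir, file)
    if (file.exists(fp)) fmt(read.csv(fp)) else w("  [not run]")
  }
  w("radsig study report")
  mf <- file.path(out_dir, "manifest.json")
  if (file.exists(mf)) {
    m <- jsonlite::read_json(mf)
    w("package ", m$package_version, ", master seed ", m$master_seed)
  }
  section("Clinical association (bias-corrected Cramer's V)",
          "association.csv", function(d) {
    for (i in seq_len(nrow(d)))
      w(sprintf("  %-28s V~ = %s  (n = %d%s)", d$variable[i],
                ifelse(is.na(d$v_corrected[i]), "not computable",
                       sprintf("%.3f", d$v_corrected[i])),
                d$n_complete[i],
                ifelse(d$computable[i], "", paste0("; ", d$reason[i]))))
  })
  section("Batch-effect audit (pairwise Fisher, BH-adjusted)",
          "audit_enrichment.csv", function(d) {
    if (nrow(d) == 0) { w("  no testable cluster pairs"); return() }
    for (i in seq_len(nrow(d)))
      w(sprintf("  %s: Cl%d vs Cl%d  p = %.2g (adj %.2g)", d$label[i],
                d$cluster_a[i], d$cluster_b[i], d$p_value[i],
                d$p_adjusted[i]))
  })
  section("Benchmark (median MCC +/- IQR)", "benchmark_summary.csv",
          function(d) {
    for (i in seq_len(nrow(d)))
      w(sprintf("  %-40s %s", d$cell_id[i],
                ifelse(is.na(d$median_mcc[i]),
                       paste0("failed: ", d$error[i]),
                       sprintf("%.2f +/- %.2f", d$median_mcc[i],
                               d$iqr[i]))))
  })
  section("Best-category per modality", "benchmark_argmax.csv",
          function(d) {
    for (i in seq_len(nrow(d)))
      w(sprintf("  %-10s -> %s (median MCC %.2f)", d$modality[i],
                d$category[i], d$median_mcc[i]))
  })
  section("Signature (degree centrality)", "signature_nodes.csv",
          function(d) {
    d <- d[order(-d$degree_centrality), ]
    for (i in seq_len(nrow(d)))
      w(sprintf("  %-60s deg %d  centrality %.2f%s", d$feature[i],
                d$degree[i], d$degree_centrality[i],
                ifelse(d$hub[i], "  [hub]", "")))
  })
  invisible(path)
}
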