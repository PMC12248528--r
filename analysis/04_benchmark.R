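#!/usr/bin/env Rscript
# Benchmark grid: median MCC (+/- IQR) of the standard pipeline
# (z-scoring -> SVM-coefficient selection -> ridge logistic) for every
# source x modality x radiomic-category cell, 10 repeats of stratified
# 10-fold CV under one master seed so cells are pairwise comparable.
# The per-modality argmax category feeds the signature stage.
# Run 01_simulate.R first.

library(radsig)
seed <- 42
dir <- "results/study"

lt <- load_tables(c(CE_T1w = file.path(dir, "cohort/CE_T1w.csv"),
                    T2w = file.path(dir, "cohort/T2w.csv")),
                  file.path(dir, "cohort/clinical.csv"),
                  label_column = "outcome", center_column = "center")
cohort <- list(features = lt$features, clinical = lt$clinical,
               labels = lt$labels)

plan <- benchmark_plan(methods = "svm", n_folds = 10, n_repeats = 10)
bench <- run_benchmark(cohort, plan, seed = seed)

print(bench$cells[, c("cell_id", "median_mcc", "iqr")], row.names = FALSE)
cat("\nbest radiomic category per modality:\n")
print(bench$argmax_category, row.names = FALSE)

write.csv(bench$cells, file.path(dir, "benchmark_summary.csv"),
          row.names = FALSE)
write.csv(bench$argmax_category, file.path(dir, "benchmark_argmax.csv"),
          row.names = FALSE)
long <- do.call(rbind, lapply(names(bench$results), function(id)
  data.frame(cell_id = id, split = seq_along(bench$results[[id]]$scores),
             mcc = bench$results[[id]]$scores)))
write.csv(long, file.path(dir, "benchmark_scores.csv"), row.names = FALSE)

# paired Wilcoxon: does adding radiomics to clinical variables help?
cli <- bench$results[["clinical/svm"]]
for (mod in c("CE_T1w", "T2w", "both")) {
  best_cat <- bench$argmax_category$category[
    bench$argmax_category$modality == mod]
  comb <- bench$results[[paste("combined", mod, best_cat, "svm",
                               sep = "/")]]
  if (is.null(comb) || is.null(cli)) next
  p <- compare_wilcoxon(cli, comb, alternative = "less")
  cat(sprintf("clinical < clinical+%s(%s): one-sided Wilcoxon p = %.2g\n",
              mod, best_cat, p))
}
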