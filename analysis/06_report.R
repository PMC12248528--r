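#!/usr/bin/env Rscript
# One-shot reproduction of the whole workflow through run_study() (a
# reduced benchmark plan keeps it quick) plus the consolidated
# plain-text report.  Independent of scripts 01-05: everything is
# derived from the master seed.

library(radsig)
seed <- 42

cfg <- study_config(
  sim = sim_config(),
  plan = benchmark_plan(modalities = c("CE_T1w", "T2w"),
                        methods = "svm", n_folds = 10, n_repeats = 5),
  dnetpro = dnetpro_config(outer_folds = 5),
  select_modality = "CE_T1w", select_category = "LoG")

run_study(cfg, "results/run", seed = seed)
render_report("results/run")
cat(readLines("results/run/report.txt"), sep = "\n")
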