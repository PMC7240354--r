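#!/usr/bin/env Rscript

# External validation: draw a second cohort from the same data-generating
# process (shared topic and label structure, fresh patients), featurize it
# with the frozen vocabulary and demographic statistics of the fitted run,
# and score the trained models on it. Requires analysis/02_pipeline.R first.

suppressPackageStartupMessages(library(stablerx))
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "config.R"))

run <- readRDS(file.path(results_dir(), "run", "run.rds"))
cfg_b <- analysis_config()
cfg_b$sim$seed <- cfg_b$sim$seed + 1000L
sim_b <- do.call(sim_config, cfg_b$sim)
truth_b <- generate_ground_truth(sim_b, structure_from = run$truth)
gen_b <- generate_cohort(sim_b, truth_b)

mets <- suppressWarnings(
  transfer_evaluate(run, gen_b$cohort, drug_seqs = gen_b$intended$drug_sequence))
jsonlite::write_json(mets, file.path(results_dir(), "transfer_metrics.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("transfer general AUC (demographics+words logistic):",
    mets$dw_logistic$general_auc, "\n")
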