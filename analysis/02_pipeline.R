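#!/usr/bin/env Rscript

# Run the full study pipeline (simulate, include, split, label, featurize,
# train topic model and baselines, evaluate) and write the run directory —
# manifest.json, labels.csv, split.csv, vocabulary.tsv, cohort CSVs — under
# results/run/.

suppressPackageStartupMessages(library(stablerx))
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "config.R"))

cfg <- analysis_config()
run <- suppressWarnings(run_pipeline(cfg, out_dir = file.path(results_dir(), "run")))
saveRDS(run, file.path(results_dir(), "run", "run.rds"))
cat("config hash:", run$manifest$config_hash, "\n")
cat("runtime:", round(run$manifest$runtime_s), "s\n")
str(run$manifest$metrics, max.level = 1)
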