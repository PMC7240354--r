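#!/usr/bin/env Rscript

# Simulate the synthetic EHR cohort used by the downstream analysis scripts
# and write it as plain CSVs under results/cohort/. The same configuration
# (and therefore a bit-identical cohort) is regenerated inside
# analysis/02_pipeline.R; this script exists so the raw tables can be
# inspected on their own.

suppressPackageStartupMessages(library(stablerx))
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "config.R"))

cfg <- analysis_config()
sim <- do.call(sim_config, cfg$sim)
truth <- generate_ground_truth(sim)
gen <- generate_cohort(sim, truth)

out <- file.path(results_dir(), "cohort")
write_cohort(gen$cohort, out)
write.csv(gen$intended$general,
          file.path(results_dir(), "intended_labels.csv"), row.names = FALSE)
cat("cohort of", nrow(gen$cohort$demographics), "patients written to", out, "\n")
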