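# Shared settings for the analysis scripts. Source this file; do not run it.
#
# STABLERX_FULL=1 switches from the desk-scale demonstration study (2000
# patients, 3 topics, minutes on one CPU) to the full-scale configuration
# (K = 10 topics, three constraint weights x three restarts, 5000 bootstrap
# replicates), which takes several hours.

analysis_seed <- function() as.integer(Sys.getenv("STABLERX_SEED", "20260101"))

analysis_config <- function() {
  if (Sys.getenv("STABLERX_FULL", "") == "1") {
    stablerx::default_run_config(n_patients = 20000L, seed = analysis_seed())
  } else {
    stablerx::demo_run_config(n_patients = 2000L, seed = analysis_seed())
  }
}

results_dir <- function() {
  d <- file.path("results")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
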