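#!/usr/bin/env Rscript

# Tidy reporting tables from the fitted run: one row per model with the
# headline metrics, plus the top words of each recovered topic. Requires
# analysis/02_pipeline.R first.

suppressPackageStartupMessages(library(stablerx))
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "config.R"))

`%||%` <- function(a, b) if (is.null(a)) b else a

run <- readRDS(file.path(results_dir(), "run", "run.rds"))
m <- run$manifest$metrics

model_rows <- Filter(function(x) !is.null(x$general_auc), m)
tab <- do.call(rbind, lapply(names(model_rows), function(nm) {
  x <- model_rows[[nm]]
  data.frame(model = nm,
             general_auc = x$general_auc,
             general_auc_lo = x$general_auc_lo,
             general_auc_hi = x$general_auc_hi,
             mean_drug_auc = x$general_mean_drug_auc,
             top3_accuracy = x$top3_accuracy %||% NA_real_,
             top3_assessable = x$top3_assessable %||% NA_real_)
}))
write.csv(tab, file.path(results_dir(), "model_metrics.csv"), row.names = FALSE)

tw <- top_words_per_topic(run$topic_model, run$vocabulary$words, n = 10L)
write.table(tw, file.path(results_dir(), "topic_top_words.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

comp <- m[c("most_common_stable", "observed_practice", "practice_filled")]
comp <- Filter(Negate(is.null), comp)
if (length(comp)) {
  ctab <- do.call(rbind, lapply(names(comp), function(nm)
    data.frame(comparator = nm,
               top3_accuracy = comp[[nm]]$top3_accuracy,
               top3_assessable = comp[[nm]]$top3_assessable)))
  write.csv(ctab, file.path(results_dir(), "comparator_metrics.csv"),
            row.names = FALSE)
}
print(tab, row.names = FALSE)
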