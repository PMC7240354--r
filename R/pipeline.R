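#' End-to-end pipeline: simulate, label, featurize, train, evaluate
#'
#' Orchestrates the full study workflow over a single configuration object:
#' generate (or load) a cohort, apply inclusion criteria, partition 50/25/25,
#' compute stability labels, build leakage-safe features, train the topic
#' model and baseline classifiers, and run the evaluation battery on the test
#' set. A JSON manifest records the config hash, per-stage seeds, row counts
#' and every reported metric, so reruns with the same config reproduce the
#' metrics bit for bit.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' Every threshold of the outcome, covariate and evaluation definitions is a
#' named key with its study default: stability rules (30-day spacing, 90-day
#' duration, 80% possession, 390-day gap), 50-patient vocabulary threshold,
#' 1000-patient target-drug threshold, K = 10 topics, 512-tree ensembles,
#' 5000 bootstrap replicates.
#'
#' @param n_patients simulated cohort size.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_run_config <- function(n_patients = 5000L, seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    sim = list(n_patients = as.integer(n_patients), n_topics_true = 10L,
               vocab_size = 500L, topic_sparsity = 0.1, doc_length_mean = 40,
               doc_alpha = 0.3, n_drugs = 11L,
               stability_mix = c(index_stable = 0.47, later_stable = 0.22,
                                 never_stable = 0.31),
               demo_effects = FALSE, seed = seed),
    outcome = list(min_spacing = 30L, min_duration = 90L, min_mpr = 0.80,
                   max_gap = 390L, days_supply_default = 90L,
                   terminate_on_add = FALSE),
    split = list(fractions = c(0.5, 0.25, 0.25), seed = seed + 11L),
    vocabulary = list(min_patients = 50L),
    target_drugs = list(min_patients = 1000L),
    topic = list(K = 10L, lambda_grid = c(1, 10, 100), n_restarts = 3L,
                 alpha = 1, n_map_iters = 100L, map_step = 2,
                 tau = 0.01, l2_eta = 0.1, max_epochs = 150L, patience = 10L,
                 eval_every = 5L, learn_rate = 0.05, seed = seed + 21L),
    classifiers = list(families = c("logistic", "extra_trees"),
                       seed = seed + 31L),
    evaluation = list(bootstrap_B = 5000L, top_k = 3L, seed = seed + 41L)
  )
}

#' Desk-scale demonstration configuration
#'
#' The default configuration scaled to a small simulated cohort so the whole
#' pipeline runs in minutes on one CPU: 3 true topics over 200 code words,
#' K = 3 fitted topics with a single constraint weight and restart, lighter
#' vocabulary/target thresholds, and a reduced bootstrap.
#'
#' @param n_patients simulated cohort size.
#' @param seed master seed.
#' @export
demo_run_config <- function(n_patients = 2000L, seed = 1L) {
  cfg <- default_run_config(n_patients, seed)
  cfg$sim$n_topics_true <- 3L
  cfg$sim$vocab_size <- 200L
  cfg$sim$doc_length_mean <- 30
  cfg$vocabulary$min_patients <- 20L
  cfg$target_drugs$min_patients <- 100L
  cfg$topic$K <- 3L
  cfg$topic$lambda_grid <- 10
  cfg$topic$n_restarts <- 1L
  cfg$topic$max_epochs <- 60L
  cfg$topic$eval_every <- 10L
  cfg$evaluation$bootstrap_B <- 500L
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file; keys override [default_run_config()].
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(user$sim$n_patients %||% 5000L, user$seed %||% 1L)
  modifyList(cfg, user)
}

stage_counts <- function(...) list(...)

#' Run the full pipeline
#'
#' @param config configuration list from [default_run_config()] /
#'   [demo_run_config()] / [read_run_config()].
#' @param out_dir optional run directory; when given, the cohort CSVs, label
#'   table, vocabulary and `manifest.json` are written there.
#' @param cohort optional pre-built `rx_cohort` with intended labels skipped;
#'   default simulates one from `config$sim`.
#' @return a `stablerx_run`: list with `config`, `manifest` (hash, seeds,
#'   counts, metrics), `models` (registry), `topic_model`, `vocabulary`,
#'   `transform`, `split`, `labels`, `features`, `truth`.
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL) {
  t_start <- Sys.time()
  # -- simulate ---------------------------------------------------------------
  truth <- NULL; intended <- NULL
  if (is.null(cohort)) {
    sim_cfg <- do.call(sim_config, config$sim)
    truth <- generate_ground_truth(sim_cfg)
    gen <- generate_cohort(sim_cfg, truth)
    cohort <- gen$cohort; intended <- gen$intended
  }
  # -- inclusion and split ----------------------------------------------------
  inc <- apply_inclusion_criteria(cohort)
  included <- inc$included
  split <- split_cohort(included, config$split$fractions, config$split$seed)
  # -- outcomes ---------------------------------------------------------------
  rules <- stability_rules(config$outcome$min_spacing, config$outcome$min_duration,
                           config$outcome$min_mpr, config$outcome$max_gap)
  labels <- label_cohort(included, rules = rules,
                         days_supply_default = config$outcome$days_supply_default,
                         terminate_on_add = config$outcome$terminate_on_add)
  gen_lab <- stats::setNames(labels$general$general_stable, labels$general$patient_id)
  trials <- stats::setNames(labels$general$additional_trials, labels$general$patient_id)
  index_dates <- stats::setNames(labels$general$index_date, labels$general$patient_id)
  target_drugs <- select_target_drugs(
    labels$per_drug[labels$per_drug$patient_id %in% split$train, , drop = FALSE],
    config$target_drugs$min_patients)
  # -- features ---------------------------------------------------------------
  vocab <- build_vocabulary(included, split$train, index_dates,
                            config$vocabulary$min_patients)
  transform <- fit_demographics(included, split$train, index_dates)
  feats <- lapply(split[c("train", "validation", "test")], function(ids)
    featurize(included, ids, vocab, transform, index_dates))
  Xdw <- lapply(feats, feature_matrix)
  # -- topic model ------------------------------------------------------------
  tc <- config$topic
  topic_model <- train_pc_slda(feats$train$counts, gen_lab[split$train],
                               feats$validation$counts, gen_lab[split$validation],
                               K = tc$K, lambda_grid = tc$lambda_grid,
                               seed = tc$seed, n_restarts = tc$n_restarts,
                               alpha = tc$alpha, n_map_iters = tc$n_map_iters,
                               map_step = tc$map_step, tau = tc$tau,
                               l2_eta = tc$l2_eta, max_epochs = tc$max_epochs,
                               patience = tc$patience, eval_every = tc$eval_every,
                               learn_rate = tc$learn_rate)
  Xtp <- lapply(feats, function(f) {
    m <- estimate_doc_topics(f$counts, topic_model)$proportions
    rownames(m) <- f$ids
    colnames(m) <- sprintf("topic_%d", seq_len(ncol(m)))
    m
  })
  # -- classifiers ------------------------------------------------------------
  feature_sets <- list(
    demographics_words = list(train = Xdw$train, validation = Xdw$validation),
    topics = list(train = Xtp$train, validation = Xtp$validation))
  registry <- train_all_models(
    feature_sets, gen_lab, labels$per_drug, target_drugs,
    families = list(demographics_words = config$classifiers$families,
                    topics = "logistic"),
    seed = config$classifiers$seed)
  # -- evaluation -------------------------------------------------------------
  test_X <- list(demographics_words = Xdw$test, topics = Xtp$test)
  drug_seqs <- if (!is.null(intended)) intended$drug_sequence else NULL
  metrics <- evaluate_battery(
    registry, test_X, split$test, labels, trials, target_drugs, drug_seqs,
    config$evaluation,
    per_drug_rank = labels$per_drug[labels$per_drug$patient_id %in% split$train, ,
                                    drop = FALSE])
  # -- manifest ---------------------------------------------------------------
  cfg_hashable <- config
  manifest <- list(
    config_hash = rlang::hash(cfg_hashable),
    seeds = list(sim = config$sim$seed, split = config$split$seed,
                 topic = config$topic$seed, classifiers = config$classifiers$seed,
                 evaluation = config$evaluation$seed),
    counts = stage_counts(
      n_simulated = n_patients(cohort), n_included = n_patients(included),
      n_excluded = nrow(inc$excluded),
      n_train = length(split$train), n_validation = length(split$validation),
      n_test = length(split$test), n_vocab = length(vocab$words),
      n_target_drugs = length(target_drugs)),
    topic_lambda = topic_model$lambda_pc,
    metrics = metrics,
    runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    lab_out <- labels$general
    lab_out$index_date <- day_to_iso(lab_out$index_date)
    write.csv(lab_out, file.path(out_dir, "labels.csv"), row.names = FALSE)
    write.csv(inc$excluded, file.path(out_dir, "excluded.csv"), row.names = FALSE)
    write.csv(data.frame(patient_id = unlist(split[c("train", "validation", "test")],
                                             use.names = FALSE),
                         subset = rep(c("train", "validation", "test"),
                                      lengths(split[c("train", "validation", "test")]))),
              file.path(out_dir, "split.csv"), row.names = FALSE)
    utils::write.table(data.frame(word = vocab$words, patient_freq = vocab$patient_freq),
                       file.path(out_dir, "vocabulary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest_out <- manifest
    manifest_out$runtime_s <- NULL  # wall time is not part of reproducible state
    jsonlite::write_json(manifest_out, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(config = config, manifest = manifest, models = registry,
                 topic_model = topic_model, vocabulary = vocab,
                 transform = transform, split = split, labels = labels,
                 features = feats, target_drugs = target_drugs,
                 truth = truth, intended = intended, cohort = included),
            class = "stablerx_run")
}

# The shared metric battery: general AUC + CI per model, per-drug mean AUC,
# top-3 ranking accuracies (model, fixed-list, observed practice), quartile
# trial means, PPV/NPV.
evaluate_battery <- function(registry, test_X, test_ids, labels, trials,
                             target_drugs, drug_seqs, eval_cfg,
                             per_drug_rank = NULL) {
  B <- eval_cfg$bootstrap_B; seed <- eval_cfg$seed; k <- eval_cfg$top_k
  gen_lab <- stats::setNames(labels$general$general_stable, labels$general$patient_id)
  per_drug_test <- labels$per_drug[labels$per_drug$patient_id %in% test_ids, , drop = FALSE]
  if (is.null(per_drug_rank)) {
    per_drug_rank <- labels$per_drug[!labels$per_drug$patient_id %in% test_ids, , drop = FALSE]
  }
  # rank only the drugs under evaluation so fallback rankings line up with
  # the per-drug prediction columns
  per_drug_rank <- per_drug_rank[per_drug_rank$drug_name %in% target_drugs, , drop = FALSE]
  y_test <- gen_lab[test_ids]
  model_specs <- list(
    dw_logistic = c("logistic", "demographics_words"),
    dw_extra_trees = c("extra_trees", "demographics_words"),
    topics_logistic = c("logistic", "topics"))
  out <- list()
  for (nm in names(model_specs)) {
    family <- model_specs[[nm]][1L]; fs <- model_specs[[nm]][2L]
    fit <- get_model(registry, family, fs, "general")
    if (is.null(fit)) next
    scores <- predict_classifier(fit, test_X[[fs]])
    ci <- bootstrap_ci(scores, y_test, B = max(B, 1L), seed = seed)
    m <- list(general_auc = ci$point, general_auc_lo = ci$lo,
              general_auc_hi = ci$hi)
    pda <- suppressWarnings(
      per_drug_auc(scores, per_drug_test, target_drugs, B = B, seed = seed + 1L))
    m$general_mean_drug_auc <- pda$mean_auc
    m$general_mean_drug_auc_lo <- pda$ci$lo
    m$general_mean_drug_auc_hi <- pda$ci$hi
    if (length(target_drugs) >= k) {
      pm <- predict_per_drug(registry, family, fs, test_X[[fs]])
      fb <- most_common_stable_baseline(per_drug_rank, k = length(target_drugs))
      fb <- c(fb, setdiff(target_drugs, fb))
      t3 <- top3_stability_accuracy(pm, per_drug_test, test_ids, fb, k = k)
      m$top3_accuracy <- t3$accuracy
      m$top3_assessable <- t3$assessable_fraction
      dpda <- suppressWarnings(per_drug_auc(
        lapply(target_drugs, function(dr) pm[, dr]) |> stats::setNames(target_drugs),
        per_drug_test, target_drugs, B = B, seed = seed + 2L))
      m$drug_specific_mean_auc <- dpda$mean_auc
      m$drug_specific_mean_auc_lo <- dpda$ci$lo
      m$drug_specific_mean_auc_hi <- dpda$ci$hi
    }
    qt <- suppressWarnings(
      quartile_medication_trials(scores, trials, B = B, seed = seed + 3L))
    m$quartile_mean_trials <- qt$mean_trials
    m$quartile_lo <- qt$lo
    m$quartile_hi <- qt$hi
    pn <- ppv_npv(scores, y_test, quantile(scores, seq(0.1, 0.9, by = 0.2),
                                           names = FALSE))
    m$ppv <- pn$ppv; m$npv <- pn$npv
    out[[nm]] <- m
  }
  if (length(target_drugs) >= k) {
    fb3 <- most_common_stable_baseline(per_drug_rank, k = k)
    t3fix <- top3_stability_accuracy(NULL, per_drug_test, test_ids,
                                     c(fb3, setdiff(target_drugs, fb3)), k = k)
    out$most_common_stable <- list(top3_accuracy = t3fix$accuracy,
                                   top3_assessable = t3fix$assessable_fraction)
    if (!is.null(drug_seqs)) {
      pr <- practice_stability_accuracy(drug_seqs, per_drug_test, test_ids, k = k)
      prf <- practice_stability_accuracy(drug_seqs, per_drug_test, test_ids,
                                         fill_from = fb3, k = k)
      out$observed_practice <- list(top3_accuracy = pr$accuracy,
                                    top3_assessable = pr$assessable_fraction)
      out$practice_filled <- list(top3_accuracy = prf$accuracy,
                                  top3_assessable = prf$assessable_fraction)
    }
  }
  out$prevalence <- as.list(table(labels$general$category[
    labels$general$patient_id %in% test_ids]) / length(test_ids))
  out
}

#' Apply a fitted run to a second cohort without refitting
#'
#' The external-transfer mechanism: cohort B is labeled and featurized with
#' cohort A's frozen vocabulary and standardization statistics, A's models
#' score B's test patients, and the same metric battery is reported. A
#' vocabulary whose content hash differs from the fit-time vocabulary raises
#' an error (guarding against silent feature misalignment).
#'
#' @param run a `stablerx_run` from [run_pipeline()].
#' @param cohort_b an `rx_cohort` (all of it is treated as evaluation data).
#' @param vocabulary the vocabulary to featurize with; must be the run's own
#'   (checked by hash).
#' @param drug_seqs optional named list of observed drug sequences for the
#'   practice comparator.
#' @param bootstrap_B,seed evaluation settings (default: the run's).
#' @return metric list as in the run manifest.
#' @export
transfer_evaluate <- function(run, cohort_b, vocabulary = run$vocabulary,
                              drug_seqs = NULL,
                              bootstrap_B = run$config$evaluation$bootstrap_B,
                              seed = run$config$evaluation$seed) {
  if (!identical(vocabulary$hash, run$vocabulary$hash)) {
    stop("vocabulary hash mismatch: cohort B must be featurized with the ",
         "fitted run's vocabulary")
  }
  config <- run$config
  inc <- apply_inclusion_criteria(cohort_b)
  included <- inc$included
  rules <- stability_rules(config$outcome$min_spacing, config$outcome$min_duration,
                           config$outcome$min_mpr, config$outcome$max_gap)
  labels <- label_cohort(included, rules = rules,
                         days_supply_default = config$outcome$days_supply_default,
                         terminate_on_add = config$outcome$terminate_on_add)
  ids <- labels$general$patient_id
  index_dates <- stats::setNames(labels$general$index_date, ids)
  trials <- stats::setNames(labels$general$additional_trials, ids)
  feats <- featurize(included, ids, vocabulary, run$transform, index_dates)
  Xdw <- feature_matrix(feats)
  Xtp <- estimate_doc_topics(feats$counts, run$topic_model)$proportions
  rownames(Xtp) <- ids
  colnames(Xtp) <- sprintf("topic_%d", seq_len(ncol(Xtp)))
  train_pd <- run$labels$per_drug[
    run$labels$per_drug$patient_id %in% run$split$train, , drop = FALSE]
  evaluate_battery(run$models, list(demographics_words = Xdw, topics = Xtp),
                   ids, labels, trials, run$target_drugs, drug_seqs,
                   list(bootstrap_B = bootstrap_B, seed = seed,
                        top_k = config$evaluation$top_k),
                   per_drug_rank = train_pd)
}
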