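#' Synthetic EHR cohorts with known topic structure and known outcomes
#'
#' The generator emulates the structure of a large health-system cohort of
#' adults starting antidepressant treatment: each patient has a pre-index
#' history of coded events drawn from a mixture of latent clinical topics, a
#' demographic record, and an antidepressant prescription timeline engineered
#' to realize a known stability category. Because both the topic structure and
#' the outcomes are known, every downstream stage (outcome engine,
#' featurization, topic-model recovery, evaluation) is testable without any
#' protected patient data.
#'
#' @name synthetic_ehr
NULL

#' Simulation configuration
#'
#' Defaults describe the emulated study population: stability-category mix of
#' roughly 47% stable on the index prescription, 22% stable later and 31%
#' never stable, 11 candidate antidepressants, and topic-structured code
#' histories.
#'
#' @param n_patients number of patients.
#' @param n_topics_true number of latent topics in the generative model.
#' @param vocab_size number of distinct code words; must be >=
#'   `n_topics_true`.
#' @param topic_sparsity symmetric Dirichlet concentration for topic-word
#'   distributions; small values give sparse, well-separated topics.
#' @param doc_length_mean expected number of pre-index coded events per
#'   patient (Poisson, truncated at 1).
#' @param doc_alpha symmetric Dirichlet concentration for per-patient topic
#'   proportions.
#' @param label_weights_true optional list(`eta` = per-topic log-odds vector,
#'   `bias` = scalar); when NULL, `eta` is drawn N(0, 2) and the bias is
#'   calibrated so the stable fraction matches `stability_mix`.
#' @param n_drugs number of antidepressant drug names.
#' @param stability_mix named probabilities (`index_stable`, `later_stable`,
#'   `never_stable`) summing to 1.
#' @param demo_effects when TRUE, demographics are associated with the label
#'   (stable patients drawn slightly older and more often female); default
#'   FALSE keeps demographics independent of outcome so tests can isolate the
#'   topic signal.
#' @param seed integer seed; all generation is deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 5000L, n_topics_true = 10L,
                       vocab_size = 500L, topic_sparsity = 0.1,
                       doc_length_mean = 40, doc_alpha = 0.3,
                       label_weights_true = NULL, n_drugs = 11L,
                       stability_mix = c(index_stable = 0.47,
                                         later_stable = 0.22,
                                         never_stable = 0.31),
                       demo_effects = FALSE, seed = 1L) {
  if (n_patients < 0 || n_patients != floor(n_patients)) {
    stop("n_patients must be a nonnegative integer")
  }
  stopifnot_scalar_count(n_topics_true, "n_topics_true")
  stopifnot_scalar_count(vocab_size, "vocab_size")
  stopifnot_scalar_count(n_drugs, "n_drugs")
  if (vocab_size < n_topics_true) stop("vocab_size must be >= n_topics_true")
  if (topic_sparsity <= 0 || doc_alpha <= 0) stop("concentrations must be > 0")
  if (doc_length_mean <= 0) stop("doc_length_mean must be > 0")
  if (length(stability_mix) != 3L || abs(sum(stability_mix) - 1) > 1e-9 ||
      any(stability_mix < 0)) {
    stop("stability_mix must be 3 nonnegative probabilities summing to 1")
  }
  names(stability_mix) <- c("index_stable", "later_stable", "never_stable")
  structure(list(n_patients = as.integer(n_patients),
                 n_topics_true = as.integer(n_topics_true),
                 vocab_size = as.integer(vocab_size),
                 topic_sparsity = topic_sparsity,
                 doc_length_mean = doc_length_mean,
                 doc_alpha = doc_alpha,
                 label_weights_true = label_weights_true,
                 n_drugs = as.integer(n_drugs),
                 stability_mix = stability_mix,
                 demo_effects = isTRUE(demo_effects),
                 seed = as.integer(seed)),
            class = "sim_config")
}

rdirichlet <- function(n, alpha) {
  # alpha: length-K concentration; returns n x K rows on the simplex
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sw <- rowSums(g)
  zero <- sw == 0  # numerically possible for tiny alpha
  if (any(zero)) {
    idx <- cbind(which(zero), sample.int(k, sum(zero), replace = TRUE))
    g[idx] <- 1
    sw <- rowSums(g)
  }
  g / sw
}

#' Generate the latent ground truth of a synthetic cohort
#'
#' Draws topic-word distributions, per-patient topic proportions, label
#' weights, and intended stability categories. The general stable/nonstable
#' label is Bernoulli with logit `eta . pi + bias`; the bias is calibrated by
#' root-finding so that the expected stable fraction equals
#' `stability_mix["index_stable"] + stability_mix["later_stable"]`; stable
#' patients are then assigned index-stable vs later-stable in the conditional
#' proportions of `stability_mix`.
#'
#' @param config a [sim_config()].
#' @param structure_from optionally, a `sim_ground_truth` whose population
#'   structure (topic-word distributions, label weights and bias) is reused;
#'   only patient-level quantities (topic proportions, labels) are redrawn
#'   under `config$seed`. This produces an external-validation cohort from the
#'   same data-generating process as an earlier cohort.
#' @return a `sim_ground_truth` list: `topics` (K x V, rows on the simplex),
#'   `eta`, `bias`, `pi` (n x K), `general_stable`, `category`, `word_types`
#'   (ICD/CPT/RX assignment of each vocabulary word), `vocab` (word names).
#' @export
generate_ground_truth <- function(config, structure_from = NULL) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_topics_true; V <- config$vocab_size; n <- config$n_patients
  if (!is.null(structure_from)) {
    stopifnot(inherits(structure_from, "sim_ground_truth"),
              identical(dim(structure_from$topics), c(K, V)))
  }
  local_seed(config$seed, {
    topics <- if (is.null(structure_from)) {
      rdirichlet(K, rep(config$topic_sparsity, V))
    } else structure_from$topics
    pi <- rdirichlet(max(n, 1L), rep(config$doc_alpha, K))
    if (n == 0L) pi <- pi[0L, , drop = FALSE]
    if (!is.null(structure_from)) {
      eta <- structure_from$eta
      bias <- structure_from$bias
    } else if (is.null(config$label_weights_true)) {
      eta <- rnorm(K, 0, 2)
      bias <- NA_real_
    } else {
      eta <- config$label_weights_true$eta
      bias <- config$label_weights_true$bias %||% NA_real_
      stopifnot(length(eta) == K)
    }
    p_stable <- unname(config$stability_mix[["index_stable"]] +
                         config$stability_mix[["later_stable"]])
    if (is.na(bias)) {
      lin <- if (n > 0L) drop(pi %*% eta) else rnorm(0)
      if (n > 0L && p_stable > 0 && p_stable < 1) {
        bias <- uniroot(function(b) mean(sigmoid(lin + b)) - p_stable,
                        c(-40, 40), tol = 1e-10)$root
      } else bias <- 0
    }
    lin <- if (n > 0L) drop(pi %*% eta) + bias else numeric(0)
    general_stable <- runif(n) < sigmoid(lin)
    p_index_given_stable <- if (p_stable > 0) {
      unname(config$stability_mix[["index_stable"]]) / p_stable
    } else 0.5
    category <- ifelse(!general_stable, "never-stable",
                       ifelse(runif(n) < p_index_given_stable,
                              "index-stable", "later-stable"))
    word_types <- rep(c("ICD", "CPT", "RX"),
                      times = diff(round(V * c(0, 0.7, 0.9, 1))))
    vocab <- sprintf("C%04d", seq_len(V))
    structure(list(topics = topics, eta = eta, bias = bias, pi = pi,
                   general_stable = general_stable, category = category,
                   word_types = word_types, vocab = vocab,
                   config = config),
              class = "sim_ground_truth")
  })
}

#' Engineer a prescription timeline realizing a stability category
#'
#' For `index-stable`, the first drug's prescriptions satisfy all four
#' stability rules. For `later-stable`, every drug but the last violates at
#' least one rule (the violation is chosen uniformly among short duration,
#' <30-day date spacing, possession ratio below 80%, and a >390-day gap) and
#' the last drug satisfies all four. For `never-stable`, every drug violates a
#' rule. Successive drug trials start 7-60 days after the previous drug's
#' supply ends.
#'
#' @param intended_category one of `"index-stable"`, `"later-stable"`,
#'   `"never-stable"`.
#' @param drug_sequence non-empty character vector of distinct drug names, in
#'   trial order.
#' @param start_date integer day of the index prescription.
#' @return data.frame (date, drug_name, days_supply), one row per
#'   prescription. Uses the current RNG stream.
#' @export
realize_prescription_timeline <- function(intended_category, drug_sequence,
                                          start_date) {
  stopifnot(length(drug_sequence) >= 1L,
            intended_category %in% c("index-stable", "later-stable", "never-stable"))
  n_trials <- length(drug_sequence)
  stable_flags <- switch(intended_category,
    "index-stable" = c(TRUE, rep(FALSE, n_trials - 1L)),
    "later-stable" = c(rep(FALSE, n_trials - 1L), TRUE),
    "never-stable" = rep(FALSE, n_trials))
  if (intended_category == "later-stable" && n_trials < 2L) {
    stop("later-stable requires at least 2 drugs")
  }
  out <- vector("list", n_trials)
  t0 <- as.integer(start_date)
  for (i in seq_len(n_trials)) {
    if (stable_flags[i]) {
      # 2-4 refills of 90-day supply, 40-85 days apart: spacing >= 40,
      # duration >= 130, continuous possession, gap <= 85 -> all rules hold
      n_rx <- sample(2:4, 1L)
      gaps <- sample(40:85, n_rx - 1L, replace = TRUE)
      dates <- t0 + cumsum(c(0L, gaps))
      supply <- rep(90L, n_rx)
    } else {
      viol <- sample(c("spacing", "duration", "mpr", "gap"), 1L)
      pat <- switch(viol,
        spacing  = list(gap = sample(7:29, 1L), supply = 90L),   # spacing < 30
        duration = list(gap = sample(31:45, 1L), supply = 30L),  # duration < 90
        mpr      = list(gap = sample(95:300, 1L), supply = 30L), # possession < 80%
        gap      = list(gap = sample(391:500, 1L), supply = 90L))# segment splits
      dates <- t0 + c(0L, pat$gap)
      supply <- rep(pat$supply, 2L)
    }
    out[[i]] <- data.frame(date = as.integer(dates),
                           drug_name = drug_sequence[i],
                           days_supply = as.integer(supply),
                           stringsAsFactors = FALSE)
    t0 <- max(dates + supply) + sample(7:60, 1L)
  }
  do.call(rbind, out)
}

#' Generate a synthetic cohort realizing the ground truth
#'
#' Builds the patient records: pre-index coded events drawn from the topic
#' mixture, an antidepressant timeline realizing the intended stability
#' category, a few post-index follow-up events, and demographics. Intended
#' per-drug outcomes exist only for drugs actually prescribed.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [generate_ground_truth()] for the same
#'   config.
#' @return list with `cohort` (an `rx_cohort`), `intended` (list `general` /
#'   `per_drug` shaped like [label_cohort()] output, plus `drug_sequence` per
#'   patient), and `truth`.
#' @export
generate_cohort <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_ground_truth"))
  n <- config$n_patients
  drugs <- sprintf("drug_%02d", seq_len(config$n_drugs))
  drug_pop <- 1 / sqrt(seq_len(config$n_drugs))  # popularity weights
  if (n == 0L) {
    empty <- rx_cohort(
      data.frame(patient_id = character(0), date = integer(0),
                 code_type = character(0), code = character(0)),
      data.frame(patient_id = character(0), date = integer(0),
                 drug_name = character(0), days_supply = integer(0)),
      data.frame(patient_id = character(0), sex = character(0),
                 race_ethnicity = character(0), birth_date = integer(0)))
    return(list(cohort = empty,
                intended = list(general = data.frame(), per_drug = data.frame(),
                                drug_sequence = list()),
                truth = truth))
  }
  local_seed(config$seed + 1L, {
    ids <- sprintf("P%06d", seq_len(n))
    index_day <- sample(iso_to_day("2000-01-01"):iso_to_day("2015-12-31"), n,
                        replace = TRUE)
    mix <- truth$pi %*% truth$topics  # n x V per-patient word distributions
    ev_list <- vector("list", n); rx_list <- vector("list", n)
    per_drug_list <- vector("list", n); seqs <- vector("list", n)
    trials_intended <- integer(n)
    for (d in seq_len(n)) {
      n_codes <- max(1L, rpois(1L, config$doc_length_mean))
      cnt <- drop(rmultinom(1L, n_codes, mix[d, ]))
      words <- rep(seq_len(config$vocab_size), cnt)
      lookback <- sample(30:730, 1L)
      ev_dates <- sample(seq(index_day[d] - lookback, index_day[d] - 1L),
                         n_codes, replace = TRUE)
      cat_d <- truth$category[d]
      n_trials <- switch(cat_d,
        "index-stable" = 1L,
        "later-stable" = 1L + sample(1:3, 1L, prob = c(0.5, 0.3, 0.2)),
        "never-stable" = sample(1:3, 1L, prob = c(0.5, 0.3, 0.2)))
      if (cat_d == "later-stable" && config$n_drugs < 2L) {
        stop("later-stable outcomes require n_drugs >= 2")
      }
      n_trials <- min(n_trials, config$n_drugs)
      seq_d <- sample(drugs, n_trials, prob = drug_pop)
      rx_d <- realize_prescription_timeline(cat_d, seq_d, index_day[d])
      trials_intended[d] <- if (cat_d == "never-stable") NA_integer_
                            else n_trials - 1L
      stable_by_drug <- switch(cat_d,
        "index-stable" = stats::setNames(TRUE, seq_d),
        "later-stable" = stats::setNames(c(rep(FALSE, n_trials - 1L), TRUE), seq_d),
        "never-stable" = stats::setNames(rep(FALSE, n_trials), seq_d))
      n_post <- rpois(1L, 3L) + 1L
      care_end <- max(rx_d$date + rx_d$days_supply) + 30L
      post_dates <- sample(seq(index_day[d], care_end), n_post, replace = TRUE)
      post_words <- sample(seq_len(config$vocab_size), n_post, replace = TRUE,
                           prob = mix[d, ])
      all_words <- c(words, post_words)
      ev_list[[d]] <- data.frame(
        patient_id = ids[d],
        date = as.integer(c(ev_dates, post_dates)),
        code_type = truth$word_types[all_words],
        code = truth$vocab[all_words],
        stringsAsFactors = FALSE)
      rx_d$patient_id <- ids[d]
      rx_list[[d]] <- rx_d[c("patient_id", "date", "drug_name", "days_supply")]
      per_drug_list[[d]] <- data.frame(patient_id = ids[d],
                                       drug_name = names(stable_by_drug),
                                       stable = unname(stable_by_drug),
                                       stringsAsFactors = FALSE)
      seqs[[d]] <- seq_d
    }
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.69, 0.31))
    race <- sample(c("White", "Black", "Hispanic", "Asian", "Other"), n,
                   replace = TRUE, prob = c(0.60, 0.14, 0.12, 0.08, 0.06))
    age <- rnorm(n, 48.5, 14.9)
    if (config$demo_effects) {
      age <- age + 3 * truth$general_stable
      flip <- truth$general_stable & sex == "M" & runif(n) < 0.15
      sex[flip] <- "F"
    }
    age <- pmin(pmax(age, 18.5), 80)  # keep synthetic patients inside study ages
    birth <- as.integer(round(index_day - age * 365.25))
    cohort <- rx_cohort(do.call(rbind, ev_list), do.call(rbind, rx_list),
                        data.frame(patient_id = ids, sex = sex,
                                   race_ethnicity = race, birth_date = birth,
                                   stringsAsFactors = FALSE))
    general <- data.frame(patient_id = ids, index_date = as.integer(index_day),
                          general_stable = truth$general_stable,
                          category = truth$category,
                          additional_trials = trials_intended,
                          stringsAsFactors = FALSE)
    per_drug <- do.call(rbind, per_drug_list); rownames(per_drug) <- NULL
    names(seqs) <- ids
    list(cohort = cohort,
         intended = list(general = general, per_drug = per_drug,
                         drug_sequence = seqs),
         truth = truth)
  })
}

#' Write / read the simulation ground truth as a plain-text bundle
#'
#' `topics.csv` (one row per topic, one column per word), `weights.csv`
#' (eta + bias), `patient_truth.csv` (topic proportions and intended labels),
#' `meta.json` (config).
#'
#' @param truth a `sim_ground_truth`.
#' @param directory output directory.
#' @export
write_ground_truth <- function(truth, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  tp <- as.data.frame(truth$topics); names(tp) <- truth$vocab
  write.csv(cbind(topic = seq_len(nrow(tp)), tp),
            file.path(directory, "topics.csv"), row.names = FALSE)
  write.csv(data.frame(parameter = c(sprintf("eta_%d", seq_along(truth$eta)), "bias"),
                       value = c(truth$eta, truth$bias)),
            file.path(directory, "weights.csv"), row.names = FALSE)
  pt <- as.data.frame(truth$pi)
  names(pt) <- sprintf("pi_%d", seq_len(ncol(pt)))
  pt <- cbind(patient_index = seq_len(nrow(pt)), pt,
              general_stable = truth$general_stable, category = truth$category)
  write.csv(pt, file.path(directory, "patient_truth.csv"), row.names = FALSE)
  cfg <- truth$config
  cfg$stability_mix <- as.list(cfg$stability_mix)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(directory, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(directory)
}
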