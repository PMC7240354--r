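#' Model evaluation battery
#'
#' AUROC with percentile-bootstrap confidence intervals, per-drug AUC
#' aggregation over known-outcome subsets, top-3 medication-ranking accuracy
#' with assessability categories, quartile forecasting of additional
#' medication trials, and PPV/NPV curves.
#'
#' @name evaluation
NULL

#' Area under the ROC curve
#'
#' Computed as the pairwise concordance probability between positive and
#' negative scores, ties counted 1/2 (rank formula; exact).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical).
#' @return value in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile-bootstrap confidence interval for the AUC
#'
#' Resamples patients with replacement `B` times, recomputes the AUC on each
#' replicate (replicates with a single class are skipped and counted), and
#' returns the 2.5th and 97.5th percentiles. Deterministic given `seed`.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param B number of bootstrap replicates (5000 in the source study).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with `lo`, `hi`, `point`, `n_skipped`.
#' @export
bootstrap_ci <- function(scores, labels, B = 5000L, seed = 1L, level = 0.95) {
  if (B < 1L) stop("B must be >= 1")
  labels <- as.integer(as.logical(labels))
  n <- length(scores)
  stat <- local_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      lb <- labels[idx]
      if (all(lb == lb[1L])) return(NA_real_)
      auc(scores[idx], lb)
    }, numeric(1))
  })
  skipped <- sum(is.na(stat))
  qs <- quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE,
                 names = FALSE)
  list(lo = qs[1L], hi = qs[2L], point = auc(scores, labels),
       n_skipped = skipped)
}

#' Per-drug AUC and its mean over target drugs
#'
#' Each drug's AUC is computed on the subset of the test set with a known
#' outcome for that drug (patients never given the drug are ignored). Drugs
#' whose test subset has a single class are excluded from the mean with a
#' warning. The bootstrap resamples test *patients* and recomputes the mean
#' across drugs on each replicate.
#'
#' @param scores named list: drug name -> named score vector (patient id ->
#'   score), or a single named numeric vector used for every drug (a general
#'   model evaluated per drug).
#' @param per_drug long data.frame (patient_id, drug_name, stable) of known
#'   test-set outcomes.
#' @param target_drugs drugs to evaluate.
#' @param B,seed bootstrap settings; `B = 0` skips the CI.
#' @return list with `per_drug` (data.frame drug_name, auc, n), `mean_auc`,
#'   `ci` (lo, hi), `excluded` (drug names).
#' @export
per_drug_auc <- function(scores, per_drug, target_drugs, B = 5000L, seed = 1L) {
  get_scores <- function(drug) if (is.list(scores)) scores[[drug]] else scores
  sub <- lapply(target_drugs, function(dr) {
    d <- per_drug[per_drug$drug_name == dr, , drop = FALSE]
    s <- get_scores(dr)
    d <- d[d$patient_id %in% names(s), , drop = FALSE]
    d$score <- s[d$patient_id]
    d
  })
  names(sub) <- target_drugs
  usable <- vapply(sub, function(d) nrow(d) > 0L &&
                     length(unique(d$stable)) > 1L, logical(1))
  excluded <- target_drugs[!usable]
  if (length(excluded) > 0L) {
    warning("drugs excluded from mean AUC (single-class or empty test subset): ",
            paste(excluded, collapse = ", "))
  }
  tab <- data.frame(
    drug_name = target_drugs,
    auc = vapply(sub, function(d) if (nrow(d) > 0L && length(unique(d$stable)) > 1L)
      auc(d$score, d$stable) else NA_real_, numeric(1)),
    n = vapply(sub, nrow, integer(1)), row.names = NULL)
  mean_auc <- mean(tab$auc[usable])
  ci <- c(NA_real_, NA_real_)
  if (B >= 1L) {
    ids <- unique(per_drug$patient_id)
    stat <- local_seed(seed, {
      vapply(seq_len(B), function(b) {
        take <- table(sample(ids, length(ids), replace = TRUE))
        vals <- vapply(sub[usable], function(d) {
          w <- as.integer(take[d$patient_id]); w[is.na(w)] <- 0L
          dd <- d[rep(seq_len(nrow(d)), w), , drop = FALSE]
          if (nrow(dd) == 0L || length(unique(dd$stable)) < 2L) return(NA_real_)
          auc(dd$score, dd$stable)
        }, numeric(1))
        mean(vals, na.rm = TRUE)
      }, numeric(1))
    })
    ci <- quantile(stat, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(per_drug = tab, mean_auc = mean_auc, ci = list(lo = ci[1L], hi = ci[2L]),
       excluded = excluded)
}

#' Top-3 stability accuracy of a medication ranking
#'
#' For each patient, the target drugs are ranked by the drug-specific
#' predicted probability (ties broken by `fallback_ranking`, conventionally
#' the training-set stability-prevalence order) and the top 3 are taken. The
#' patient is *not assessable* when none of the 3 has a known outcome,
#' *assessable and stable* when at least one of the 3 has a known stable
#' outcome, and *assessable and nonstable* otherwise. Accuracy is
#' stable / (stable + nonstable).
#'
#' @param prob_matrix patients x drugs matrix of predicted stability
#'   probabilities (dimnames required), or NULL to use `fallback_ranking`
#'   alone (a fixed-list comparator).
#' @param per_drug long data.frame (patient_id, drug_name, stable) of known
#'   outcomes.
#' @param patient_ids patients to evaluate.
#' @param fallback_ranking character vector of drugs, most preferred first;
#'   also supplies the ranking for drugs missing from `prob_matrix`.
#' @param k number of suggested drugs (3 in the source study).
#' @return list with `accuracy`, `assessable_fraction`, `categories`
#'   (data.frame patient_id, category), `k`.
#' @export
top3_stability_accuracy <- function(prob_matrix, per_drug, patient_ids,
                                    fallback_ranking, k = 3L) {
  drugs <- fallback_ranking
  if (length(drugs) < k) stop("need at least k target drugs")
  fb_rank <- stats::setNames(seq_along(drugs), drugs)
  known <- split(per_drug[c("drug_name", "stable")], per_drug$patient_id)
  category <- vapply(patient_ids, function(id) {
    if (!is.null(prob_matrix) && id %in% rownames(prob_matrix)) {
      p <- stats::setNames(rep(NA_real_, length(drugs)), drugs)
      cols <- intersect(drugs, colnames(prob_matrix))
      p[cols] <- prob_matrix[id, cols]
      # drugs without a score fall back to the fixed ranking, after all
      # scored drugs
      o <- order(-p, fb_rank[drugs], na.last = TRUE)
      top <- drugs[o][seq_len(k)]
    } else {
      top <- drugs[seq_len(k)]
    }
    kn <- known[[id]]
    if (is.null(kn)) return("not-assessable")
    kn <- kn[kn$drug_name %in% top, , drop = FALSE]
    if (nrow(kn) == 0L) "not-assessable"
    else if (any(kn$stable)) "assessable-stable"
    else "assessable-nonstable"
  }, character(1))
  n_stable <- sum(category == "assessable-stable")
  n_non <- sum(category == "assessable-nonstable")
  list(accuracy = n_stable / (n_stable + n_non),
       assessable_fraction = (n_stable + n_non) / length(patient_ids),
       categories = data.frame(patient_id = patient_ids, category = category,
                               stringsAsFactors = FALSE, row.names = NULL),
       k = k)
}

#' Observed-practice medication ranking
#'
#' Builds a per-patient "ranking" from the drugs actually prescribed (trial
#' order), optionally filled up to `k` drugs from a fixed list — the
#' clinical-practice comparators of the ranking evaluation.
#'
#' @param drug_sequences named list: patient id -> character vector of drugs
#'   in initiation order.
#' @param per_drug long data.frame of known outcomes.
#' @param patient_ids patients to evaluate.
#' @param fill_from optional fixed list used to pad sequences shorter than
#'   `k` (NULL leaves them short).
#' @param k list length.
#' @return same structure as [top3_stability_accuracy()].
#' @export
practice_stability_accuracy <- function(drug_sequences, per_drug, patient_ids,
                                        fill_from = NULL, k = 3L) {
  known <- split(per_drug[c("drug_name", "stable")], per_drug$patient_id)
  category <- vapply(patient_ids, function(id) {
    top <- drug_sequences[[id]] %||% character(0)
    if (!is.null(fill_from)) top <- c(top, setdiff(fill_from, top))
    top <- head(top, k)
    kn <- known[[id]]
    if (is.null(kn)) return("not-assessable")
    kn <- kn[kn$drug_name %in% top, , drop = FALSE]
    if (nrow(kn) == 0L) "not-assessable"
    else if (any(kn$stable)) "assessable-stable"
    else "assessable-nonstable"
  }, character(1))
  n_stable <- sum(category == "assessable-stable")
  n_non <- sum(category == "assessable-nonstable")
  list(accuracy = n_stable / (n_stable + n_non),
       assessable_fraction = (n_stable + n_non) / length(patient_ids),
       categories = data.frame(patient_id = patient_ids, category = category,
                               stringsAsFactors = FALSE, row.names = NULL),
       k = k)
}

#' Most-commonly-stable fixed drug list
#'
#' The `k` drugs on which the most training patients were stable, descending
#' (ties lexicographic) — the one-size-fits-all comparator.
#'
#' @param per_drug long data.frame (patient_id, drug_name, stable) of the
#'   training set.
#' @param k list length.
#' @return character vector (all drugs if fewer than `k`).
#' @export
most_common_stable_baseline <- function(per_drug, k = 3L) {
  st <- per_drug[per_drug$stable, , drop = FALSE]
  cnt <- table(factor(st$drug_name, levels = sort(unique(per_drug$drug_name))))
  ranked <- names(cnt)[order(-as.integer(cnt), names(cnt))]
  head(ranked, k)
}

#' Quartile stratification of additional medication trials
#'
#' Patients are stratified into quartiles of the general-stability score
#' (boundaries at the 25th/50th/75th percentiles; scores tied with a
#' boundary go to the lower quartile) and, per quartile, the mean number of
#' additional medication initiations observed before stability is reported
#' with a percentile-bootstrap CI. Never-stable patients (undefined trial
#' count) are excluded by default; `include_never` instead counts their
#' total observed initiations beyond the first as a lower bound.
#'
#' @param scores named numeric vector (patient id -> general stability
#'   score).
#' @param trials named integer vector (patient id -> additional trials; NA
#'   for never-stable).
#' @param B,seed bootstrap settings; `B = 0` skips CIs.
#' @param include_never censored-count mode, see above; requires
#'   `total_initiations`.
#' @param total_initiations named integer vector used in `include_never`
#'   mode.
#' @return data.frame (quartile, n, mean_trials, lo, hi); quartile 1 holds
#'   the lowest scores.
#' @export
quartile_medication_trials <- function(scores, trials, B = 5000L, seed = 1L,
                                       include_never = FALSE,
                                       total_initiations = NULL) {
  if (length(scores) < 4L) stop("need at least 4 patients for quartiles")
  ids <- names(scores)
  y <- trials[ids]
  if (include_never) {
    if (is.null(total_initiations)) stop("include_never requires total_initiations")
    nv <- is.na(y)
    y[nv] <- total_initiations[ids][nv] - 1L
  }
  qb <- quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
  quart <- 1L + (scores > qb[1L]) + (scores > qb[2L]) + (scores > qb[3L])
  one <- function(w) {
    # w: multiplicity weights per patient (bootstrap); NA trials dropped
    vapply(1:4, function(q) {
      sel <- quart == q & !is.na(y) & w > 0
      if (!any(sel)) return(NA_real_)
      sum(y[sel] * w[sel]) / sum(w[sel])
    }, numeric(1))
  }
  pt <- one(rep(1L, length(ids)))
  empty <- is.na(pt)
  if (any(empty)) warning("empty quartile(s): ", paste(which(empty), collapse = ", "))
  lo <- hi <- rep(NA_real_, 4L)
  if (B >= 1L) {
    stat <- local_seed(seed, {
      vapply(seq_len(B), function(b) {
        take <- tabulate(sample.int(length(ids), length(ids), replace = TRUE),
                         nbins = length(ids))
        one(take)
      }, numeric(4L))
    })
    lo <- apply(stat, 1L, quantile, 0.025, na.rm = TRUE, names = FALSE)
    hi <- apply(stat, 1L, quantile, 0.975, na.rm = TRUE, names = FALSE)
  }
  data.frame(quartile = 1:4,
             n = vapply(1:4, function(q) sum(quart == q & !is.na(y)), integer(1)),
             mean_trials = pt, lo = lo, hi = hi)
}

#' Positive and negative predictive value over thresholds
#'
#' Scores at or above a threshold are predicted positive. Undefined cells
#' (no predicted positives or no predicted negatives) are reported as NA,
#' not 0.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param thresholds numeric vector of thresholds.
#' @return data.frame (threshold, ppv, npv, n_positive_pred,
#'   n_negative_pred).
#' @export
ppv_npv <- function(scores, labels, thresholds) {
  labels <- as.logical(labels)
  out <- lapply(thresholds, function(th) {
    pred <- scores >= th
    npos <- sum(pred); nneg <- sum(!pred)
    data.frame(threshold = th,
               ppv = if (npos > 0L) sum(labels[pred]) / npos else NA_real_,
               npv = if (nneg > 0L) sum(!labels[!pred]) / nneg else NA_real_,
               n_positive_pred = npos, n_negative_pred = nneg)
  })
  do.call(rbind, out)
}
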