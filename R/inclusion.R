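#' Inclusion/exclusion criteria and cohort partitioning
#'
#' Mirrors the study's eligibility rules: adults (18 to 80 years at the index
#' prescription), an observation period of at least 90 days, at least 3
#' documented visits (distinct event dates of any code type), and at least one
#' coded event strictly before the index prescription (patients with no
#' pre-index history cannot receive personalized predictions).
#'
#' @name inclusion
NULL

#' Apply inclusion criteria to a cohort
#'
#' A patient is included iff all of, evaluated in this order (the recorded
#' exclusion reason is the first failed rule):
#' \enumerate{
#'   \item has at least one coded event (`no-events`);
#'   \item has at least one antidepressant prescription, which defines the
#'     index date (`no-index-prescription`);
#'   \item is at least 18 and not older than 80 at the index date, i.e. the
#'     81st birthday has not passed (`age`);
#'   \item last event date minus first event date is at least 90 days
#'     (`observation-period`);
#'   \item has at least 3 distinct event dates (`visit-count`);
#'   \item has at least one coded event strictly before the index date
#'     (`no-pre-index-history`).
#' }
#'
#' @param cohort an `rx_cohort`.
#' @param min_age,max_age inclusive age bounds in years at the index date.
#' @param min_observation_days minimum event span.
#' @param min_visits minimum number of distinct event dates.
#' @param diagnosis_allowlist optional character vector of diagnosis codes; if
#'   given, patients without any listed ICD code are excluded first
#'   (`diagnosis`). Synthetic cohorts are all-depressed by construction, so
#'   the default is NULL.
#' @return list with `included` (an `rx_cohort`) and `excluded` (data.frame
#'   patient_id, reason).
#' @export
apply_inclusion_criteria <- function(cohort, min_age = 18, max_age = 80,
                                     min_observation_days = 90L,
                                     min_visits = 3L,
                                     diagnosis_allowlist = NULL) {
  dm <- cohort$demographics
  ev <- cohort$events
  rx <- cohort$prescriptions
  ev_by <- split(ev$date, ev$patient_id)
  dx_by <- if (!is.null(diagnosis_allowlist)) {
    keep <- ev$code_type == "ICD" & ev$code %in% diagnosis_allowlist
    split(keep, ev$patient_id)
  } else NULL
  idx_by <- tapply(rx$date, rx$patient_id, min)
  reason <- character(nrow(dm))
  for (i in seq_len(nrow(dm))) {
    id <- dm$patient_id[i]
    dates <- ev_by[[id]]
    if (!is.null(dx_by) && !(id %in% names(dx_by) && any(dx_by[[id]]))) {
      reason[i] <- "diagnosis"; next
    }
    if (is.null(dates) || length(dates) == 0L) { reason[i] <- "no-events"; next }
    index_date <- idx_by[id]
    if (is.na(index_date)) { reason[i] <- "no-index-prescription"; next }
    age <- (index_date - dm$birth_date[i]) / 365.25
    if (age < min_age || (index_date - dm$birth_date[i]) >= (max_age + 1) * 365.25) {
      reason[i] <- "age"; next
    }
    if (max(dates) - min(dates) < min_observation_days) {
      reason[i] <- "observation-period"; next
    }
    if (length(unique(dates)) < min_visits) { reason[i] <- "visit-count"; next }
    if (!any(dates < index_date)) { reason[i] <- "no-pre-index-history"; next }
  }
  keep <- reason == ""
  list(included = subset_cohort(cohort, dm$patient_id[keep]),
       excluded = data.frame(patient_id = dm$patient_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE, row.names = NULL))
}

#' Random train/validation/test partition
#'
#' Patients are shuffled uniformly at random and assigned to subsets of sizes
#' `floor(n * fraction)` for validation and test, with the remainder going to
#' training (a 50/25/25 split by default, matching the study design).
#'
#' @param patient_ids character vector of included patient ids (or an
#'   `rx_cohort`, whose demographics ids are used).
#' @param fractions length-3 numeric (train, validation, test) summing to 1.
#' @param seed integer seed; assignment is deterministic given it.
#' @return list with disjoint character vectors `train`, `validation`, `test`
#'   (exhaustive over the input), and `seed`.
#' @export
split_cohort <- function(patient_ids, fractions = c(0.5, 0.25, 0.25), seed = 1L) {
  if (inherits(patient_ids, "rx_cohort")) {
    patient_ids <- patient_ids$demographics$patient_id
  }
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0))
  n <- length(patient_ids)
  n_val <- floor(n * fractions[2L])
  n_test <- floor(n * fractions[3L])
  n_train <- n - n_val - n_test
  shuffled <- local_seed(seed, sample(patient_ids, n))
  list(train = shuffled[seq_len(n_train)],
       validation = shuffled[seq_len(n_val) + n_train],
       test = shuffled[seq_len(n_test) + n_train + n_val],
       seed = as.integer(seed))
}
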