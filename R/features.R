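#' Pre-index history featurization
#'
#' Turns each patient's coded history *strictly before* the index prescription
#' date into (i) a sparse count vector over a frequency-thresholded vocabulary
#' of code words (`code_type:code` strings, prescriptions entering as
#' `RX:drug` tokens) and (ii) a small demographics block: one-hot sex and
#' race/ethnicity plus standardized age at index and index date. Events on the
#' index date are never counted — they may be consequences of the index visit
#' — and antidepressant prescriptions at or after index define the outcome, so
#' the strict cutoff keeps them out of the features by construction.
#'
#' @name features
NULL

# token stream for one cohort: code events plus prescriptions as RX:drug
token_events <- function(cohort) {
  ev <- cohort$events
  rx <- cohort$prescriptions
  data.frame(
    patient_id = c(ev$patient_id, rx$patient_id),
    date = c(ev$date, rx$date),
    word = c(paste(ev$code_type, ev$code, sep = ":"),
             paste("RX", rx$drug_name, sep = ":")),
    stringsAsFactors = FALSE)
}

#' Build the code-word vocabulary from training patients
#'
#' A word is retained when it occurs for at least `min_patients` *distinct*
#' training patients before their index dates (repetitions within a patient
#' count once). Ordering is patient-frequency descending, ties lexicographic,
#' so the vocabulary is deterministic. Only training patients may be passed:
#' the vocabulary is a fitted statistic and must not see validation/test data.
#'
#' @param cohort an `rx_cohort`.
#' @param train_ids training patient ids.
#' @param index_dates named integer vector (patient id -> index day) giving
#'   the per-patient cutoff.
#' @param min_patients patient-frequency threshold (50 in the source study).
#' @return an `rx_vocabulary`: list with `words`, `patient_freq`,
#'   `min_patients`, and a content `hash` used to guard against feature
#'   misalignment across cohorts.
#' @export
build_vocabulary <- function(cohort, train_ids, index_dates, min_patients = 50L) {
  tok <- token_events(subset_cohort(cohort, train_ids))
  tok <- tok[tok$date < index_dates[tok$patient_id], , drop = FALSE]
  if (nrow(tok) == 0L) {
    vocab <- list(words = character(0), patient_freq = integer(0),
                  min_patients = as.integer(min_patients))
  } else {
    u <- unique(tok[c("patient_id", "word")])
    freq <- table(u$word)
    freq <- freq[freq >= min_patients]
    o <- order(-as.integer(freq), names(freq))
    vocab <- list(words = names(freq)[o],
                  patient_freq = as.integer(freq)[o],
                  min_patients = as.integer(min_patients))
  }
  vocab$hash <- rlang::hash(vocab$words)
  structure(vocab, class = "rx_vocabulary")
}

#' @export
print.rx_vocabulary <- function(x, ...) {
  cat(sprintf("<rx_vocabulary> %d words (min %d patients per word)\n",
              length(x$words), x$min_patients))
  invisible(x)
}

#' Sparse pre-index count matrix
#'
#' Counts vocabulary words among a patient's tokens with date strictly before
#' that patient's cutoff; out-of-vocabulary tokens are ignored.
#'
#' @param cohort an `rx_cohort`.
#' @param ids patients to featurize (row order of the result).
#' @param vocabulary an `rx_vocabulary`.
#' @param index_dates named integer vector (patient id -> cutoff day).
#' @return a `dgCMatrix` of nonnegative integer counts, `length(ids)` x
#'   `length(vocabulary$words)`, with dimnames.
#' @export
vectorize_history <- function(cohort, ids, vocabulary, index_dates) {
  tok <- token_events(subset_cohort(cohort, ids))
  tok <- tok[tok$date < index_dates[tok$patient_id], , drop = FALSE]
  ri <- match(tok$patient_id, ids)
  ci <- match(tok$word, vocabulary$words)
  keep <- !is.na(ci)
  X <- Matrix::sparseMatrix(i = ri[keep], j = ci[keep], x = 1,
                            dims = c(length(ids), length(vocabulary$words)))
  dimnames(X) <- list(ids, vocabulary$words)
  methods::as(X, "CsparseMatrix")
}

#' Fit the demographics transformer on training patients
#'
#' Learns category levels for sex and race/ethnicity and the training-set
#' mean/sd of age at index (years) and of the index date, used to standardize
#' the two numeric features. Unseen categories at transform time map to an
#' all-zero one-hot block.
#'
#' @param cohort an `rx_cohort`.
#' @param train_ids training patient ids.
#' @param index_dates named integer vector (patient id -> index day).
#' @return an `rx_demographics_transform`.
#' @export
fit_demographics <- function(cohort, train_ids, index_dates) {
  dm <- cohort$demographics
  dm <- dm[match(train_ids, dm$patient_id), , drop = FALSE]
  if (anyNA(dm$birth_date)) stop("missing birth_date")
  age <- (index_dates[train_ids] - dm$birth_date) / 365.25
  idx <- as.numeric(index_dates[train_ids])
  sd_or_1 <- function(x) { s <- sd(x); if (!is.finite(s) || s == 0) 1 else s }
  structure(list(sex_levels = sort(unique(dm$sex)),
                 race_levels = sort(unique(dm$race_ethnicity)),
                 age_mean = mean(age), age_sd = sd_or_1(age),
                 date_mean = mean(idx), date_sd = sd_or_1(idx)),
            class = "rx_demographics_transform")
}

#' Demographics feature block
#'
#' @param cohort an `rx_cohort`.
#' @param ids patients to featurize.
#' @param transform fitted [fit_demographics()] object.
#' @param index_dates named integer vector (patient id -> index day).
#' @return numeric matrix: one-hot sex, one-hot race/ethnicity, standardized
#'   age at index, standardized index date.
#' @export
demographics_features <- function(cohort, ids, transform, index_dates) {
  dm <- cohort$demographics
  dm <- dm[match(ids, dm$patient_id), , drop = FALSE]
  if (anyNA(dm$birth_date)) stop("missing birth_date")
  one_hot <- function(x, levels, prefix) {
    m <- matrix(0, nrow = length(x), ncol = length(levels),
                dimnames = list(NULL, paste0(prefix, levels)))
    hit <- match(x, levels)
    ok <- !is.na(hit)
    m[cbind(which(ok), hit[ok])] <- 1
    m
  }
  age <- (index_dates[ids] - dm$birth_date) / 365.25
  idx <- as.numeric(index_dates[ids])
  out <- cbind(one_hot(dm$sex, transform$sex_levels, "sex_"),
               one_hot(dm$race_ethnicity, transform$race_levels, "race_"),
               age_std = (age - transform$age_mean) / transform$age_sd,
               index_date_std = (idx - transform$date_mean) / transform$date_sd)
  rownames(out) <- ids
  out
}

#' Full feature set for a list of patients
#'
#' Convenience wrapper returning the sparse count block and the demographics
#' block side by side, aligned on `ids`.
#'
#' @inheritParams vectorize_history
#' @param transform fitted [fit_demographics()] object.
#' @return list with `ids`, `counts` (sparse), `demographics` (dense), and
#'   `vocab_hash`.
#' @export
featurize <- function(cohort, ids, vocabulary, transform, index_dates) {
  list(ids = ids,
       counts = vectorize_history(cohort, ids, vocabulary, index_dates),
       demographics = demographics_features(cohort, ids, transform, index_dates),
       vocab_hash = vocabulary$hash)
}

#' Combine counts and demographics into one dense model matrix
#' @param features output of [featurize()].
#' @param binarize if TRUE, count entries are clipped to 0/1.
#' @export
feature_matrix <- function(features, binarize = FALSE) {
  cnt <- as.matrix(features$counts)
  if (binarize) cnt <- (cnt > 0) + 0
  cbind(cnt, features$demographics)
}
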