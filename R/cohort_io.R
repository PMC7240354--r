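#' Longitudinal coded-cohort container
#'
#' An `rx_cohort` bundles the three long-format tables of a coded clinical
#' cohort: dated coded events (diagnoses, procedures, medication codes),
#' antidepressant prescriptions with days of supply, and demographics. Dates
#' are integer day offsets (days since 1970-01-01) internally and ISO-8601
#' strings on disk; all outcome rules are day-granular.
#'
#' @param events data.frame: patient_id, date, code_type (ICD/CPT/RX), code.
#' @param prescriptions data.frame: patient_id, date, drug_name, days_supply.
#' @param demographics data.frame: patient_id, sex, race_ethnicity, birth_date.
#' @return an object of class `rx_cohort`.
#' @export
rx_cohort <- function(events, prescriptions, demographics) {
  stopifnot(all(c("patient_id", "date", "code_type", "code") %in% names(events)),
            all(c("patient_id", "date", "drug_name", "days_supply") %in% names(prescriptions)),
            all(c("patient_id", "sex", "race_ethnicity", "birth_date") %in% names(demographics)))
  bad <- setdiff(unique(events$code_type), c("ICD", "CPT", "RX"))
  if (length(bad) > 0L) stop("unknown code_type: ", paste(bad, collapse = ", "))
  if (anyDuplicated(demographics$patient_id)) stop("duplicate patient_id in demographics")
  events <- events[order(events$patient_id, events$date), , drop = FALSE]
  prescriptions <- prescriptions[order(prescriptions$patient_id, prescriptions$date), , drop = FALSE]
  rownames(events) <- rownames(prescriptions) <- rownames(demographics) <- NULL
  structure(list(events = events, prescriptions = prescriptions,
                 demographics = demographics),
            class = "rx_cohort")
}

#' @export
print.rx_cohort <- function(x, ...) {
  cat(sprintf("<rx_cohort> %d patients, %d coded events, %d prescriptions\n",
              nrow(x$demographics), nrow(x$events), nrow(x$prescriptions)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort an `rx_cohort`.
#' @export
n_patients <- function(cohort) nrow(cohort$demographics)

#' Restrict a cohort to a set of patients
#' @param cohort an `rx_cohort`.
#' @param ids patient ids to keep.
#' @export
subset_cohort <- function(cohort, ids) {
  rx_cohort(cohort$events[cohort$events$patient_id %in% ids, , drop = FALSE],
            cohort$prescriptions[cohort$prescriptions$patient_id %in% ids, , drop = FALSE],
            cohort$demographics[cohort$demographics$patient_id %in% ids, , drop = FALSE])
}

#' Write a cohort to CSV files
#'
#' Writes `events.csv`, `prescriptions.csv` and `demographics.csv` under
#' `directory`, dates as ISO-8601.
#'
#' @param cohort an `rx_cohort`.
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  ev <- cohort$events; ev$date <- day_to_iso(ev$date)
  rx <- cohort$prescriptions; rx$date <- day_to_iso(rx$date)
  dm <- cohort$demographics; dm$birth_date <- day_to_iso(dm$birth_date)
  write.csv(ev, file.path(directory, "events.csv"), row.names = FALSE, quote = FALSE)
  write.csv(rx, file.path(directory, "prescriptions.csv"), row.names = FALSE, quote = FALSE)
  write.csv(dm, file.path(directory, "demographics.csv"), row.names = FALSE, quote = FALSE)
  invisible(directory)
}

read_csv_checked <- function(path, cols) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s) %s", basename(path), paste(missing, collapse = ", ")))
  }
  df
}

parse_date_col <- function(df, col, path) {
  if (nrow(df) == 0L) { df[[col]] <- integer(0); return(df) }
  day <- iso_to_day(df[[col]])
  if (anyNA(day)) {
    i <- which(is.na(day))[1L]
    stop(sprintf("%s: line %d, column '%s': unparseable date '%s'",
                 basename(path), i + 1L, col, df[[col]][i]))
  }
  df[[col]] <- day
  df
}

#' Read a cohort from CSV files
#'
#' Inverse of [write_cohort()]: `read_cohort(write_cohort(x)) == x`
#' field-for-field. Malformed rows raise an error naming the file, line and
#' column.
#'
#' @param directory directory containing `events.csv`, `prescriptions.csv`,
#'   `demographics.csv`.
#' @return an `rx_cohort`.
#' @export
read_cohort <- function(directory) {
  ev_path <- file.path(directory, "events.csv")
  rx_path <- file.path(directory, "prescriptions.csv")
  dm_path <- file.path(directory, "demographics.csv")
  for (p in c(ev_path, rx_path, dm_path)) {
    if (!file.exists(p)) stop("missing input file: ", p)
  }
  ev <- read_csv_checked(ev_path, c("patient_id", "date", "code_type", "code"))
  ev <- parse_date_col(ev, "date", ev_path)
  bad <- which(!ev$code_type %in% c("ICD", "CPT", "RX"))
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d, column 'code_type': unknown code_type '%s'",
                 basename(ev_path), bad[1L] + 1L, ev$code_type[bad[1L]]))
  }
  rx <- read_csv_checked(rx_path, c("patient_id", "date", "drug_name", "days_supply"))
  rx <- parse_date_col(rx, "date", rx_path)
  if (nrow(rx) > 0L) {
    supply <- suppressWarnings(as.integer(rx$days_supply))
    bad <- which(is.na(supply) & nzchar(rx$days_supply))
    if (length(bad) > 0L) {
      stop(sprintf("%s: line %d, column 'days_supply': not an integer '%s'",
                   basename(rx_path), bad[1L] + 1L, rx$days_supply[bad[1L]]))
    }
    rx$days_supply <- supply
  } else rx$days_supply <- integer(0)
  dm <- read_csv_checked(dm_path, c("patient_id", "sex", "race_ethnicity", "birth_date"))
  dm <- parse_date_col(dm, "birth_date", dm_path)
  rx_cohort(ev, rx, dm)
}
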