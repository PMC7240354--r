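#' Treatment-stability outcome engine
#'
#' A *treatment segment* is a maximal run of prescriptions of one
#' antidepressant for one patient, split wherever adjacent prescription dates
#' are more than `max_gap` (default 390) days apart. A segment is *stable* when
#' all four rules hold: at least 2 prescriptions on 2 distinct dates at least
#' 30 days apart; total duration at least 90 days; medication possession ratio
#' at least 80%; and largest gap between adjacent prescription dates at most
#' 390 days. Stability is the study's proxy for an effective, tolerated
#' regimen: a clinician kept renewing the same drug.
#'
#' @name outcomes
NULL

#' Default stability rule thresholds
#'
#' @return list with `min_spacing` (days between first and last distinct
#'   prescription dates), `min_duration` (days), `min_mpr` (fraction), and
#'   `max_gap` (days).
#' @export
stability_rules <- function(min_spacing = 30L, min_duration = 90L,
                            min_mpr = 0.80, max_gap = 390L) {
  stopifnot(min_spacing > 0, min_duration > 0, min_mpr > 0, min_mpr <= 1, max_gap > 0)
  list(min_spacing = as.integer(min_spacing), min_duration = as.integer(min_duration),
       min_mpr = min_mpr, max_gap = as.integer(max_gap))
}

new_segment <- function(drug_name, dates, supplies) {
  o <- order(dates)
  dates <- as.integer(dates[o]); supplies <- as.integer(supplies[o])
  start <- dates[1L]
  coverage_end <- max(dates + supplies)
  seg <- list(
    drug_name = drug_name,
    dates = dates,
    days_supply = supplies,
    start = start,
    coverage_end = coverage_end,
    duration = coverage_end - start,
    max_gap = if (length(dates) > 1L) max(diff(dates)) else 0L,
    n_distinct_dates = length(unique(dates))
  )
  seg$mpr <- medication_possession_ratio(seg)
  structure(seg, class = "treatment_segment")
}

#' Build treatment segments from one patient's prescriptions
#'
#' Prescriptions are grouped per drug and split into maximal runs wherever the
#' gap between adjacent prescription dates exceeds `max_gap` days. Segments of
#' different drugs are independent: starting a second antidepressant does not
#' end the first drug's segment unless `break_dates` is supplied (the stricter
#' polypharmacy reading), in which case runs are additionally split at those
#' dates.
#'
#' @param prescriptions data.frame with columns `date` (integer day),
#'   `drug_name`, `days_supply`.
#' @param max_gap days; adjacent same-drug prescriptions further apart than
#'   this start a new segment.
#' @param days_supply_default used where `days_supply` is missing.
#' @param break_dates optional integer days at which every ongoing segment is
#'   terminated (prescriptions on or after a break date open a new segment).
#' @return list of `treatment_segment` objects, ordered by segment start.
#' @export
build_segments <- function(prescriptions, max_gap = 390L,
                           days_supply_default = 90L, break_dates = NULL) {
  if (is.null(prescriptions) || nrow(prescriptions) == 0L) return(list())
  stopifnot(all(c("date", "drug_name", "days_supply") %in% names(prescriptions)))
  supply <- prescriptions$days_supply
  supply[is.na(supply)] <- days_supply_default
  if (any(supply < 1)) stop("days_supply must be >= 1")
  segs <- list()
  for (drug in unique(prescriptions$drug_name)) {
    sel <- prescriptions$drug_name == drug
    d <- as.integer(prescriptions$date[sel]); s <- as.integer(supply[sel])
    o <- order(d); d <- d[o]; s <- s[o]
    # run id increments where the gap rule or a break date cuts the run
    cut <- c(FALSE, diff(d) > max_gap)
    if (!is.null(break_dates)) {
      for (b in sort(break_dates)) {
        crosses <- c(FALSE, d[-1L] >= b & d[-length(d)] < b)
        cut <- cut | crosses
      }
    }
    run <- cumsum(cut)
    for (r in unique(run)) {
      segs[[length(segs) + 1L]] <- new_segment(drug, d[run == r], s[run == r])
    }
  }
  segs[order(vapply(segs, `[[`, integer(1), "start"))]
}

#' Medication possession ratio of a segment
#'
#' Fraction of days in the segment during which the patient possessed a valid,
#' nonexpired prescription: the union of possession intervals
#' `[date, date + days_supply)`, intersected with `[start, coverage_end)`,
#' divided by the segment duration. Overlapping supplies are never
#' double-counted.
#'
#' @param segment a `treatment_segment`.
#' @return fraction in (0, 1].
#' @export
medication_possession_ratio <- function(segment) {
  lo <- pmax(segment$dates, segment$start)
  hi <- pmin(segment$dates + segment$days_supply, max(segment$dates + segment$days_supply))
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  covered <- 0L; cur_lo <- lo[1L]; cur_hi <- hi[1L]
  if (length(lo) > 1L) for (i in 2L:length(lo)) {
    if (lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      covered <- covered + (cur_hi - cur_lo)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  covered <- covered + (cur_hi - cur_lo)
  duration <- max(hi) - segment$start
  covered / duration
}

#' Test the four stability rules on a segment
#'
#' @param segment a `treatment_segment`.
#' @param rules thresholds from [stability_rules()].
#' @return list with `stable` (logical) and `failed_rules` (character vector,
#'   subset of `c("two-dates", "spacing", "duration", "mpr", "gap")`,
#'   enumerating every violated rule).
#' @export
is_stable_segment <- function(segment, rules = stability_rules()) {
  failed <- character(0)
  dd <- unique(segment$dates)
  if (length(dd) < 2L) failed <- c(failed, "two-dates")
  if (length(dd) >= 2L && (max(dd) - min(dd)) < rules$min_spacing) failed <- c(failed, "spacing")
  if (segment$duration < rules$min_duration) failed <- c(failed, "duration")
  if (segment$mpr < rules$min_mpr) failed <- c(failed, "mpr")
  if (segment$max_gap > rules$max_gap) failed <- c(failed, "gap")
  list(stable = length(failed) == 0L, failed_rules = failed)
}

#' General stability labels for one patient
#'
#' The *index prescription* is the patient's first antidepressant
#' prescription. The patient is `index-stable` if the segment containing the
#' index prescription is stable, `later-stable` if some other segment is
#' stable, and `never-stable` otherwise. `additional_trials` counts distinct
#' drug initiations strictly after the index date and at or before the first
#' stable segment's start (0 for index-stable, NA for never-stable).
#'
#' @param prescriptions data.frame of one patient's antidepressant
#'   prescriptions (`date`, `drug_name`, `days_supply`).
#' @param rules thresholds from [stability_rules()].
#' @inheritParams build_segments
#' @param terminate_on_add if TRUE, starting another antidepressant ends
#'   ongoing segments (stricter polypharmacy reading).
#' @return list with `index_date`, `general_stable`, `category`,
#'   `additional_trials`, `per_drug` (named logical, only drugs with an
#'   observed outcome), and `segments`. Returns NULL if the patient has no
#'   prescriptions (undefined outcome).
#' @export
label_general_stability <- function(prescriptions, rules = stability_rules(),
                                    days_supply_default = 90L,
                                    terminate_on_add = FALSE) {
  if (is.null(prescriptions) || nrow(prescriptions) == 0L) return(NULL)
  index_date <- min(prescriptions$date)
  index_drug <- prescriptions$drug_name[which.min(prescriptions$date)]
  break_dates <- NULL
  if (terminate_on_add) {
    inits <- tapply(prescriptions$date, prescriptions$drug_name, min)
    break_dates <- sort(unique(as.integer(inits)))
  }
  segs <- build_segments(prescriptions, max_gap = rules$max_gap,
                         days_supply_default = days_supply_default,
                         break_dates = break_dates)
  verdicts <- lapply(segs, is_stable_segment, rules = rules)
  stable <- vapply(verdicts, `[[`, logical(1), "stable")
  seg_drug <- vapply(segs, `[[`, character(1), "drug_name")
  seg_start <- vapply(segs, `[[`, integer(1), "start")
  contains_index <- vapply(segs, function(s) s$drug_name == index_drug &&
                             index_date %in% s$dates, logical(1))
  general_stable <- any(stable)
  category <- if (any(stable & contains_index)) "index-stable"
              else if (general_stable) "later-stable"
              else "never-stable"
  per_drug <- vapply(split(stable, seg_drug), any, logical(1))
  if (category == "never-stable") {
    additional_trials <- NA_integer_
  } else if (category == "index-stable") {
    additional_trials <- 0L
  } else {
    first_stable_start <- min(seg_start[stable])
    inits <- tapply(prescriptions$date, prescriptions$drug_name, min)
    inits <- inits[names(inits) != index_drug]
    additional_trials <- sum(inits > index_date & inits <= first_stable_start)
  }
  list(index_date = as.integer(index_date), general_stable = general_stable,
       category = category, additional_trials = as.integer(additional_trials),
       per_drug = per_drug, segments = segs)
}

#' Drug-specific stability label
#'
#' @inheritParams label_general_stability
#' @param drug drug name.
#' @return TRUE if any segment of `drug` is stable, FALSE if the patient
#'   received the drug but no segment is stable, NA if the drug was never
#'   prescribed (unknown outcome).
#' @export
label_drug_specific <- function(prescriptions, drug, rules = stability_rules(),
                                days_supply_default = 90L) {
  if (is.null(prescriptions) || !drug %in% prescriptions$drug_name) return(NA)
  lab <- label_general_stability(prescriptions, rules = rules,
                                 days_supply_default = days_supply_default)
  unname(lab$per_drug[drug])
}

#' Stability labels for a whole cohort
#'
#' @param cohort an `rx_cohort` (see [read_cohort()]).
#' @inheritParams label_general_stability
#' @return list with `general` — data.frame (patient_id, index_date,
#'   general_stable, category, additional_trials); and `per_drug` — long
#'   data.frame (patient_id, drug_name, stable) restricted to observed
#'   outcomes. Patients without prescriptions are omitted from both.
#' @export
label_cohort <- function(cohort, rules = stability_rules(),
                         days_supply_default = 90L, terminate_on_add = FALSE) {
  rx <- cohort$prescriptions
  ids <- unique(rx$patient_id)
  by_pat <- split(rx[c("date", "drug_name", "days_supply")], rx$patient_id)[as.character(ids)]
  labs <- lapply(by_pat, label_general_stability, rules = rules,
                 days_supply_default = days_supply_default,
                 terminate_on_add = terminate_on_add)
  general <- data.frame(
    patient_id = ids,
    index_date = vapply(labs, `[[`, integer(1), "index_date"),
    general_stable = vapply(labs, `[[`, logical(1), "general_stable"),
    category = vapply(labs, `[[`, character(1), "category"),
    additional_trials = vapply(labs, `[[`, integer(1), "additional_trials"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  per_drug <- do.call(rbind, lapply(seq_along(ids), function(i) {
    pd <- labs[[i]]$per_drug
    if (length(pd) == 0L) return(NULL)
    data.frame(patient_id = ids[i], drug_name = names(pd), stable = unname(pd),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_drug)) {
    per_drug <- data.frame(patient_id = character(0), drug_name = character(0),
                           stable = logical(0))
  }
  rownames(per_drug) <- NULL
  list(general = general, per_drug = per_drug)
}

#' Select target drugs with sufficient observed outcomes
#'
#' Drugs qualify when the number of patients with a known (non-missing)
#' drug-specific outcome in the training cohort reaches `min_patients`.
#'
#' @param per_drug long data.frame (patient_id, drug_name, stable) as produced
#'   by [label_cohort()]; pass the training subset only.
#' @param min_patients threshold (1000 in the source study's site A).
#' @return character vector of drug names, sorted by patient count descending
#'   (ties lexicographic).
#' @export
select_target_drugs <- function(per_drug, min_patients = 1000L) {
  if (nrow(per_drug) == 0L) return(character(0))
  cnt <- table(per_drug$drug_name)
  cnt <- cnt[cnt >= min_patients]
  names(cnt)[order(-as.integer(cnt), names(cnt))]
}
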