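#' First relevant drug and diagnosis dates per patient
#'
#' Extracts, for each patient, the dates that bound or shift the observation
#' window: first atomoxetine prescription (always a censoring drug, since
#' co-prescribing with the study drug would blur the exposure contrast),
#' first antidepressant/antipsychotic prescription (censoring only under the
#' psychotropic-censoring scenario), first study-drug (MPH) prescription and
#' first ADHD diagnosis (ICD-9-CM 314.x), both used by the late-entry
#' scenario.
#'
#' @param prescriptions A prescriptions tibble.
#' @param events An events tibble (optional; needed for ADHD dates).
#' @return A tibble with one row per patient appearing in either input:
#'   `patient_id`, `first_atomoxetine`, `first_psychotropic`, `first_mph`,
#'   `first_adhd` (Date, `NA` when absent).
#' @export
key_dates <- function(prescriptions, events = NULL) {
  rx <- tibble::as_tibble(prescriptions)
  first_date <- function(tbl, datecol) {
    if (nrow(tbl) == 0L) return(tibble::tibble(patient_id = character(), date = .as_date(integer())))
    tbl |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(date = min(.data[[datecol]]), .groups = "drop")
  }
  atx <- first_date(rx[rx$drug_class == "atomoxetine", ], "start_date")
  psy <- first_date(rx[rx$drug_class %in% c("antidepressant", "antipsychotic"), ], "start_date")
  mph <- first_date(rx[rx$drug_class == "MPH", ], "start_date")
  ids <- unique(c(rx$patient_id, if (!is.null(events)) events$patient_id))
  out <- tibble::tibble(patient_id = ids)
  out$first_atomoxetine <- atx$date[match(ids, atx$patient_id)]
  out$first_psychotropic <- psy$date[match(ids, psy$patient_id)]
  out$first_mph <- mph$date[match(ids, mph$patient_id)]
  if (!is.null(events)) {
    ev <- tibble::as_tibble(events)
    adhd <- first_date(ev[startsWith(as.character(ev$icd9_code), "314"), ], "event_date")
    out$first_adhd <- adhd$date[match(ids, adhd$patient_id)]
  } else {
    out$first_adhd <- .as_date(rep(NA_integer_, length(ids)))
  }
  out
}

#' Construct per-patient observation windows
#'
#' The observation window opens at the study start or the patient's sixth
#' birthday, whichever is later, and closes at the earliest of: the study
#' end, the day before the twentieth birthday (so age 19 is included, age 20
#' is not), the day before the first atomoxetine prescription, the date of
#' death, and — under the psychotropic-censoring scenario — the day before
#' the first antidepressant/antipsychotic prescription. Censoring at a drug
#' date ends the window the day before first receipt so censored exposure
#' time is never counted; the death day itself remains in the window.
#' `end_reason` records the binding constraint. Patients whose window start
#' exceeds its end are flagged ineligible (`end_reason = "none_eligible"`),
#' which is a value, not an error.
#'
#' Under the late-entry rule (`window_start_rule = "late_entry"`), the start
#' is additionally pushed forward to the latest of the first ADHD diagnosis
#' and the first study-drug prescription — but never into the retained
#' pre-exposure window, i.e. never past `first_mph - pre_exposure_days`, so
#' the pre-exposure contrast stays estimable.
#'
#' @param patients A patients tibble.
#' @param dates A [key_dates()] tibble (or `NULL` for no censoring drugs).
#' @param scenario A [scenario_config()].
#' @param study_start,study_end Study period bounds (ISO dates).
#' @return A tibble `patient_id`, `start_date`, `end_date`, `end_reason`,
#'   `eligible`.
#' @export
build_windows <- function(patients, dates = NULL, scenario = scenario_config(),
                          study_start = .STUDY_START, study_end = .STUDY_END) {
  pt <- tibble::as_tibble(patients)
  n <- nrow(pt)
  dob <- .day_num(pt$date_of_birth)
  ss <- .day_num(study_start); se <- .day_num(study_end)
  if (is.null(dates)) {
    dates <- tibble::tibble(patient_id = character(),
                            first_atomoxetine = .as_date(integer()),
                            first_psychotropic = .as_date(integer()),
                            first_mph = .as_date(integer()),
                            first_adhd = .as_date(integer()))
  }
  j <- match(pt$patient_id, dates$patient_id)
  atx <- .day_num(dates$first_atomoxetine)[j]
  psy <- .day_num(dates$first_psychotropic)[j]
  mph <- .day_num(dates$first_mph)[j]
  adhd <- .day_num(dates$first_adhd)[j]
  death <- .day_num(pt$date_of_death)

  start <- pmax(ss, .add_years(dob, 6L))
  if (identical(scenario$window_start_rule, "late_entry")) {
    late <- pmax(start, pmax(adhd, mph, na.rm = TRUE))
    late[is.na(late)] <- start[is.na(late)]
    cap <- ifelse(is.na(mph), late, mph - scenario$pre_exposure_days)
    start <- pmax(start, pmin(late, cap))
  }

  big <- .day_num("2199-12-01")
  cand <- list(
    study_end = rep(se, n),
    twentieth_birthday = .add_years(dob, 20L) - 1L,
    atomoxetine = ifelse(is.na(atx), big, atx - 1L),
    death = ifelse(is.na(death), big, death),
    psychotropic_censor = if (isTRUE(scenario$censor_psychotropics)) {
      ifelse(is.na(psy), big, psy - 1L)
    } else rep(big, n)
  )
  end <- as.integer(Reduce(pmin, cand))
  reason <- rep(NA_character_, n)
  for (nm in rev(names(cand))) reason[cand[[nm]] == end] <- nm
  eligible <- start <= end
  reason[!eligible] <- "none_eligible"
  tibble::tibble(
    patient_id = pt$patient_id,
    start_date = .as_date(start),
    end_date = .as_date(end),
    end_reason = reason,
    eligible = eligible
  )
}

#' Select each patient's incident outcome event
#'
#' Keeps, per eligible patient, the earliest outcome event inside the
#' observation window. Patients with any qualifying outcome event *before*
#' their window start are excluded entirely, so that only incident cases
#' enter the analysis. Same-day ties are broken by code-group priority
#' (psychosis, then hallucination, then other psychotic disorders), then by
#' lexical code order. Which code groups count as outcomes is set by
#' `scenario$outcomes` (e.g. the hallucination-removal scenario drops 780.1
#' before selection, so a prior hallucination no longer excludes a patient).
#'
#' @param events An events tibble; a `code_group` column is added via
#'   [classify_codes()] if absent.
#' @param windows A [build_windows()] tibble.
#' @param scenario A [scenario_config()].
#' @param code_map Code map used if `events` lacks `code_group`.
#' @return A tibble of selected cases (`patient_id`, `event_date`,
#'   `icd9_code`, `code_group`, `same_day_order`), one row per case, with
#'   attributes `n_excluded_prior_event` and `n_no_event_in_window`.
#' @export
select_incident_events <- function(events, windows, scenario = scenario_config(),
                                   code_map = default_code_map()) {
  ev <- tibble::as_tibble(events)
  if (!"code_group" %in% names(ev)) ev <- classify_codes(ev, code_map)
  if (!"same_day_order" %in% names(ev)) ev$same_day_order <- "unknown"
  ev <- ev[ev$code_group %in% scenario$outcomes, , drop = FALSE]
  win <- windows[windows$eligible, , drop = FALSE]
  j <- match(ev$patient_id, win$patient_id)
  keep <- !is.na(j)
  ev <- ev[keep, , drop = FALSE]; j <- j[keep]
  ws <- .day_num(win$start_date)[j]; we <- .day_num(win$end_date)[j]
  d <- .day_num(ev$event_date)

  prior_ids <- unique(ev$patient_id[d < ws])
  in_win <- d >= ws & d <= we & !ev$patient_id %in% prior_ids
  cand <- ev[in_win, , drop = FALSE]
  pri <- .OUTCOME_PRIORITY[cand$code_group]
  o <- order(cand$patient_id, .day_num(cand$event_date), pri, cand$icd9_code)
  cand <- cand[o, , drop = FALSE]
  sel <- cand[!duplicated(cand$patient_id), , drop = FALSE]
  n_no_event <- nrow(win) - length(prior_ids) - nrow(sel)
  out <- tibble::as_tibble(sel[c("patient_id", "event_date", "icd9_code",
                                 "code_group", "same_day_order")])
  attr(out, "n_excluded_prior_event") <- length(prior_ids)
  attr(out, "n_no_event_in_window") <- n_no_event
  out
}
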