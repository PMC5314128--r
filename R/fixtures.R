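#' Tiny hand-constructed fixtures with known answers
#'
#' Deterministic miniature datasets whose correct analysis results are known
#' in closed form, for documentation and exact testing:
#'
#' * `"irr3_pair"` — two patients, each observed 400 days (2004-01-01 to
#'   2005-02-03) with one 100-day prescription (2004-10-01 to 2005-01-08).
#'   Patient A's event falls in exposed time, patient B's in baseline time.
#'   With no pre-exposure window and no age/season adjustment the
#'   conditional MLE of the exposed IRR is exactly
#'   (1/100) / (1/300) = 3.
#' * `"no_information"` — one patient whose window is entirely baseline:
#'   the conditional likelihood is constant, so [sccs_fit()] raises an
#'   `sccs_estimation_error`.
#' * `"day1_tie"` — one patient whose event falls on the first day of the
#'   prescription and is recorded as `before_treatment`: the tie rule
#'   assigns it to the previous day's (pre-exposure) interval.
#'
#' @param name One of `"irr3_pair"`, `"no_information"`, `"day1_tie"`.
#' @return A list with `patients`, `prescriptions`, `events` tibbles, a
#'   `scenario`, and (where the fixture defines one) a ready-made
#'   `intervals` tibble for direct use with [sccs_fit()].
#' @export
toy_fixture <- function(name = c("irr3_pair", "no_information", "day1_tie")) {
  name <- match.arg(name)
  d <- function(x) as.Date(x)
  if (name == "irr3_pair") {
    patients <- tibble::tibble(
      patient_id = c("A", "B"),
      date_of_birth = d(c("1998-01-01", "1998-01-01")),
      date_of_death = d(c("2005-02-03", "2005-02-03")),
      sex = c("male", "female")
    )
    prescriptions <- tibble::tibble(
      patient_id = c("A", "B"), drug_class = "MPH",
      start_date = d("2004-10-01"), end_date = d("2005-01-08"),
      daily_dose_mg = NA_real_, quantity_mg = NA_real_
    )
    events <- tibble::tibble(
      patient_id = c("A", "B"),
      event_date = d(c("2004-11-15", "2004-03-01")),
      icd9_code = "298.9", same_day_order = "unknown"
    )
    intervals <- tibble::tibble(
      patient_id = rep(c("A", "B"), each = 3L),
      start_date = rep(d(c("2004-01-01", "2004-10-01", "2005-01-09")), 2L),
      end_date = rep(d(c("2004-09-30", "2005-01-08", "2005-02-03")), 2L),
      category = rep(c("baseline", "exposed", "baseline"), 2L),
      age_band = 6L, season = 1L,
      length_days = rep(c(274L, 100L, 26L), 2L),
      events = c(0L, 1L, 0L, 1L, 0L, 0L)
    )
    return(list(patients = patients, prescriptions = prescriptions,
                events = events, intervals = intervals,
                scenario = scenario_config("irr3_pair", pre_exposure_days = 0L)))
  }
  if (name == "no_information") {
    return(list(
      patients = tibble::tibble(
        patient_id = "A", date_of_birth = d("1998-01-01"),
        date_of_death = d(NA_character_), sex = "male"),
      prescriptions = tibble::tibble(
        patient_id = character(), drug_class = character(),
        start_date = d(character()), end_date = d(character()),
        daily_dose_mg = numeric(), quantity_mg = numeric()),
      events = tibble::tibble(
        patient_id = "A", event_date = d("2008-06-01"),
        icd9_code = "298.9", same_day_order = "unknown"),
      intervals = tibble::tibble(
        patient_id = "A", start_date = d("2008-01-01"),
        end_date = d("2008-12-31"), category = "baseline",
        age_band = 10L, season = 1L, length_days = 366L, events = 1L),
      scenario = scenario_config("no_information", pre_exposure_days = 0L)
    ))
  }
  list(
    patients = tibble::tibble(
      patient_id = "A", date_of_birth = d("2000-01-01"),
      date_of_death = d(NA_character_), sex = "male"),
    prescriptions = tibble::tibble(
      patient_id = "A", drug_class = "MPH",
      start_date = d("2010-05-01"), end_date = d("2010-07-09"),
      daily_dose_mg = NA_real_, quantity_mg = NA_real_),
    events = tibble::tibble(
      patient_id = "A", event_date = d("2010-05-01"),
      icd9_code = "298.9", same_day_order = "before_treatment"),
    scenario = scenario_config("day1_tie")
  )
}
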