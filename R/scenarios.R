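#' Declarative analysis scenario
#'
#' A scenario bundles every analytic choice that the primary analysis and
#' its sensitivity battery vary: the pre-exposure window length, a washout
#' window removed from person-time, per-episode exposure extension (a drug
#' non-adherence allowance), age-band width, a minimum-exposure case filter,
#' psychotropic censoring, substance-dependence exclusion, the outcome code
#' groups, first-day event handling, and the observation-start rule. A
#' scenario run is a pure function of (dataset, scenario).
#'
#' @param name Scenario label used in reports.
#' @param pre_exposure_days Days of pre-exposure risk window before the
#'   first-ever exposure episode: 0, 30, 60 or 90.
#' @param washout_days Days immediately before the first episode removed
#'   from analysed person-time entirely (0--21).
#' @param extension_weeks Weeks appended to the end of every exposure
#'   episode (0--10); an extension that reaches the next episode merges them.
#' @param age_band_months Age-band width: 12 or 6 months.
#' @param min_exposure_weeks Cases with no more than this many weeks of
#'   total in-window exposure are excluded: 0 (off) or 10.
#' @param censor_psychotropics Censor the observation window the day before
#'   the first antidepressant/antipsychotic prescription.
#' @param exclude_substance Exclude patients with any substance
#'   misuse/dependence diagnosis (ICD-9-CM 303--305).
#' @param outcomes Code groups that count as outcome events.
#' @param drop_first_day_events Drop cases whose event falls on the first
#'   day of an exposure episode.
#' @param window_start_rule `"default"` or `"late_entry"` (start at the
#'   latest of study start, sixth birthday, first ADHD diagnosis and first
#'   exposure, retaining the pre-exposure window; see [build_windows()]).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(name = "custom",
                            pre_exposure_days = 90L,
                            washout_days = 0L,
                            extension_weeks = 0L,
                            age_band_months = 12L,
                            min_exposure_weeks = 0L,
                            censor_psychotropics = FALSE,
                            exclude_substance = FALSE,
                            outcomes = c("psychosis", "hallucination", "other_psychotic"),
                            drop_first_day_events = FALSE,
                            window_start_rule = c("default", "late_entry")) {
  window_start_rule <- match.arg(window_start_rule)
  stopifnot(
    pre_exposure_days %in% c(0L, 30L, 60L, 90L),
    washout_days >= 0L, washout_days <= 21L,
    extension_weeks >= 0L, extension_weeks <= 10L,
    age_band_months %in% c(12L, 6L),
    min_exposure_weeks %in% c(0L, 10L),
    is.logical(censor_psychotropics), is.logical(exclude_substance),
    is.logical(drop_first_day_events),
    all(outcomes %in% c("psychosis", "hallucination", "other_psychotic"))
  )
  structure(
    list(name = name,
         pre_exposure_days = as.integer(pre_exposure_days),
         washout_days = as.integer(washout_days),
         extension_weeks = as.integer(extension_weeks),
         age_band_months = as.integer(age_band_months),
         min_exposure_weeks = as.integer(min_exposure_weeks),
         censor_psychotropics = censor_psychotropics,
         exclude_substance = exclude_substance,
         outcomes = outcomes,
         drop_first_day_events = drop_first_day_events,
         window_start_rule = window_start_rule),
    class = "scenario_config"
  )
}

#' The built-in scenario battery
#'
#' Returns, in report order: the primary analysis without a pre-exposure
#' window, the primary analysis with the 90-day pre-exposure window, and the
#' sensitivity battery — 6-month age bands; the subset with more than 10
#' weeks of exposure; psychotropic censoring; substance-dependence
#' exclusion; hallucination removal; first-day event removal; 7/14/21-day
#' washouts; late observation entry; 60- and 30-day pre-exposure windows;
#' and per-episode exposure extensions of 1--10 weeks (one sub-scenario per
#' week). All non-primary scenarios keep the 90-day pre-exposure window.
#'
#' @return A named list of 24 [scenario_config()] objects.
#' @export
sccs_scenarios <- function() {
  sc <- list(
    scenario_config("primary", pre_exposure_days = 0L),
    scenario_config("pre90"),
    scenario_config("age_band_6m", age_band_months = 6L),
    scenario_config("exposure_gt_10w", min_exposure_weeks = 10L),
    scenario_config("censor_psychotropics", censor_psychotropics = TRUE),
    scenario_config("exclude_substance", exclude_substance = TRUE),
    scenario_config("exclude_hallucination",
                    outcomes = c("psychosis", "other_psychotic")),
    scenario_config("drop_first_day_events", drop_first_day_events = TRUE),
    scenario_config("washout_7d", washout_days = 7L),
    scenario_config("washout_14d", washout_days = 14L),
    scenario_config("washout_21d", washout_days = 21L),
    scenario_config("late_entry", window_start_rule = "late_entry"),
    scenario_config("pre60", pre_exposure_days = 60L),
    scenario_config("pre30", pre_exposure_days = 30L)
  )
  ext <- lapply(1:10, function(w) {
    scenario_config(paste0("extension_", w, "w"), extension_weeks = w)
  })
  out <- c(sc, ext)
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Run one scenario end to end
#'
#' Executes the full pipeline for a single scenario: episode construction,
#' observation windows, incident-case selection, scenario case filters
#' (substance exclusion, minimum exposure), interval segmentation, event
#' placement, and the conditional Poisson fit with Wald summaries for the
#' pre-exposure and exposed terms. Case exclusions are counted by reason in
#' the report's `funnel`. A scenario with fewer than two informative cases
#' yields a report with `status = "estimation_error"` rather than an error,
#' so batch runs continue.
#'
#' @param cohort A list with `patients`, `prescriptions`, `events` tibbles
#'   (e.g. from [simulate_sccs_cohort()] or the [read_records] readers).
#' @param scenario A [scenario_config()].
#' @param median_days Imputation median for prescription durations (days).
#' @param code_map Code map for outcome classification.
#' @param study_start,study_end Study period bounds.
#' @param contrast_terms Also report the exposed-vs-pre-exposure contrast
#'   when both terms are present.
#' @return A `sccs_scenario_report`: list with `name`, `n_cases`,
#'   `estimates` (tibble of [sccs_wald()] rows), `contrast`, `glance`,
#'   `funnel`, `status`, and the underlying `fit` (or `NULL`).
#' @export
run_scenario <- function(cohort, scenario = scenario_config(),
                         median_days = 70L, code_map = default_code_map(),
                         study_start = .STUDY_START, study_end = .STUDY_END,
                         contrast_terms = TRUE) {
  ev <- classify_codes(cohort$events, code_map)
  episodes <- build_episodes(cohort$prescriptions, median_days = median_days)
  dates <- key_dates(cohort$prescriptions, ev)
  windows <- build_windows(cohort$patients, dates, scenario, study_start, study_end)
  funnel <- list(n_patients = nrow(cohort$patients),
                 n_ineligible_window = sum(!windows$eligible))

  cases <- select_incident_events(ev, windows, scenario, code_map)
  funnel$n_prior_event <- attr(cases, "n_excluded_prior_event")
  funnel$n_no_event_in_window <- attr(cases, "n_no_event_in_window")

  if (isTRUE(scenario$exclude_substance)) {
    substance_ids <- unique(ev$patient_id[ev$code_group == "substance"])
    n0 <- nrow(cases)
    cases <- cases[!cases$patient_id %in% substance_ids, , drop = FALSE]
    funnel$n_substance_excluded <- n0 - nrow(cases)
  } else funnel$n_substance_excluded <- 0L

  if (scenario$min_exposure_weeks > 0L) {
    win <- windows[windows$eligible, , drop = FALSE]
    epi <- episodes
    j <- match(epi$patient_id, win$patient_id)
    s <- pmax(.day_num(epi$start_date), .day_num(win$start_date)[j])
    e <- pmin(.day_num(epi$end_date), .day_num(win$end_date)[j])
    len <- pmax(0L, e - s + 1L)
    tot <- rowsum(len, epi$patient_id, reorder = TRUE)
    enough <- rownames(tot)[tot[, 1L] > scenario$min_exposure_weeks * 7L]
    n0 <- nrow(cases)
    cases <- cases[cases$patient_id %in% enough, , drop = FALSE]
    funnel$n_below_min_exposure <- n0 - nrow(cases)
  } else funnel$n_below_min_exposure <- 0L

  report <- list(name = scenario$name, scenario = scenario, funnel = funnel)
  class(report) <- "sccs_scenario_report"
  if (nrow(cases) < 2L) {
    report$status <- "estimation_error"
    report$n_cases <- nrow(cases)
    report$estimates <- tibble::tibble(term = character(), irr = numeric(),
                                       ci_low = numeric(), ci_high = numeric(),
                                       p_value = numeric())
    return(report)
  }

  ints <- sccs_intervals(cohort$patients, windows, episodes, cases, scenario)
  dropped <- attr(ints, "dropped")
  funnel$n_event_placement_dropped <- nrow(dropped)
  report$funnel <- funnel
  report$dropped <- dropped

  fit <- tryCatch(
    sccs_fit(ints, adjust_age = TRUE, adjust_season = TRUE),
    sccs_estimation_error = function(e) e
  )
  if (inherits(fit, "condition")) {
    report$status <- "estimation_error"
    report$message <- conditionMessage(fit)
    report$n_cases <- length(unique(ints$patient_id))
    report$estimates <- tibble::tibble(term = character(), irr = numeric(),
                                       ci_low = numeric(), ci_high = numeric(),
                                       p_value = numeric())
    return(report)
  }
  terms <- intersect(c("pre_exposure", "exposed"), names(fit$coef))
  report$status <- "ok"
  report$fit <- fit
  report$n_cases <- fit$n_cases_used + fit$n_dropped_noninformative
  report$estimates <- dplyr::bind_rows(lapply(terms, sccs_wald, fit = fit))
  if (contrast_terms && all(c("pre_exposure", "exposed") %in% terms)) {
    report$contrast <- sccs_contrast(fit, "exposed", "pre_exposure")
  }
  report$glance <- glance(fit)
  report
}

#' Run a batch of scenarios
#'
#' @inheritParams run_scenario
#' @param scenarios A list of [scenario_config()]s (default: the built-in
#'   battery of [sccs_scenarios()]).
#' @return A named list of `sccs_scenario_report`s.
#' @export
run_scenarios <- function(cohort, scenarios = sccs_scenarios(), ...) {
  reports <- lapply(scenarios, function(sc) run_scenario(cohort, sc, ...))
  names(reports) <- vapply(scenarios, `[[`, character(1), "name")
  reports
}

#' Tidy a scenario report into one row per estimate
#'
#' @param x An `sccs_scenario_report`.
#' @param ... Unused.
#' @return A tibble `scenario`, `n_cases`, `term`, `irr`, `ci_low`,
#'   `ci_high`, `p_value`, `status`.
#' @method tidy sccs_scenario_report
#' @export
tidy.sccs_scenario_report <- function(x, ...) {
  est <- x$estimates
  if (nrow(est) == 0L) {
    return(tibble::tibble(scenario = x$name, n_cases = x$n_cases %||% 0L,
                          term = NA_character_, irr = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, status = x$status))
  }
  dplyr::mutate(est, scenario = x$name, n_cases = x$n_cases,
                status = x$status, .before = 1)
}

#' @export
print.sccs_scenario_report <- function(x, ...) {
  cat(render_report(list(x), format = "text"), sep = "\n")
  invisible(x)
}

.fmt_irr <- function(x) sprintf("%.2f", x)
.fmt_ci <- function(lo, hi) sprintf("%.2f–%.2f", lo, hi)
.fmt_p <- function(p) ifelse(p < 0.01, "<0.01", sprintf("%.2f", p))

.row_label <- function(term, pre_days) {
  switch(term,
         pre_exposure = paste0(pre_days, " days before first treatment"),
         exposed = "Period with treatment",
         term)
}

#' Render scenario reports as text, CSV rows, or JSON
#'
#' One block per scenario, with rows for the pre-exposure and on-treatment
#' terms, in the column layout `IRR | 95% CI | P-value`. IRRs round to two
#' decimals, confidence intervals render as `a.bc–d.ef`, p-values below 0.01
#' render `<0.01`, and scenarios without estimates render em-dash cells with
#' a status note. Ordering follows the input list, so re-running the same
#' batch yields byte-identical output.
#'
#' @param reports A list of `sccs_scenario_report`s.
#' @param format `"text"`, `"csv"` (a tibble of rows), or `"json"` (a JSON
#'   string).
#' @return A character vector of lines (`text`), a tibble (`csv`), or a JSON
#'   string (`json`).
#' @export
render_report <- function(reports, format = c("text", "csv", "json")) {
  format <- match.arg(format)
  if (inherits(reports, "sccs_scenario_report")) reports <- list(reports)
  rows <- dplyr::bind_rows(lapply(reports, function(r) {
    est <- r$estimates
    if (nrow(est) == 0L) {
      return(tibble::tibble(
        scenario = r$name, n_cases = r$n_cases %||% 0L, term = NA_character_,
        label = "—", irr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, status = r$status))
    }
    tibble::tibble(
      scenario = r$name, n_cases = r$n_cases, term = est$term,
      label = vapply(est$term, .row_label, character(1),
                     pre_days = r$scenario$pre_exposure_days),
      irr = est$irr, ci_low = est$ci_low, ci_high = est$ci_high,
      p_value = est$p_value, status = r$status)
  }))
  if (format == "csv") return(rows)
  if (format == "json") {
    return(jsonlite::toJSON(rows, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, na = "null", pretty = TRUE))
  }
  lines <- character()
  for (r in reports) {
    lines <- c(lines, sprintf("%s (n=%s)", r$name, r$n_cases %||% 0L))
    est <- r$estimates
    if (nrow(est) == 0L) {
      lines <- c(lines, sprintf("  %-38s %5s | %s | %s  [%s]",
                                "—", "—", "—", "—", r$status))
    } else {
      for (i in seq_len(nrow(est))) {
        lines <- c(lines, sprintf(
          "  %-38s %5s | %s | %s",
          .row_label(est$term[i], r$scenario$pre_exposure_days),
          .fmt_irr(est$irr[i]), .fmt_ci(est$ci_low[i], est$ci_high[i]),
          .fmt_p(est$p_value[i])))
      }
    }
    lines <- c(lines, "")
  }
  lines
}
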