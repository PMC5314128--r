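#' Read the canonical patient, prescription and event tables
#'
#' Readers for the three CSV inputs of the pipeline. Each reader checks the
#' header against the documented schema (a missing required column is an
#' error), parses dates as ISO-8601, drops rows that violate a row-level
#' invariant (unparseable required date, death before birth, negative
#' duration), and reports the number of skipped rows as a message and in the
#' `n_skipped` attribute of the result.
#'
#' Schemas (columns in order):
#' * `patients.csv`: `patient_id`, `date_of_birth`, `date_of_death`, `sex`
#' * `prescriptions.csv`: `patient_id`, `drug_class`, `start_date`,
#'   `end_date`, `daily_dose_mg`, `quantity_mg`
#' * `events.csv`: `patient_id`, `event_date`, `icd9_code`, `same_day_order`
#'
#' `drug_class` is one of `MPH`, `atomoxetine`, `antidepressant`,
#' `antipsychotic`, `other`; `sex` is `male`/`female`/`unknown`;
#' `same_day_order` is `before_treatment`/`after_treatment`/`unknown` (the
#' default when blank).
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per valid input row, with attribute `n_skipped`.
#' @name read_records
NULL

.read_checked <- function(path, required, col_types) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path), class = "sccs_input_error")
  tbl <- readr::read_csv(path, col_types = col_types, progress = FALSE,
                         na = c("", "NA"))
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(paste0("schema error in ", basename(path), ": missing column(s) ",
                 paste(missing, collapse = ", ")), class = "sccs_input_error")
  }
  tbl
}

.report_skips <- function(tbl, bad, reasons, what) {
  n_bad <- sum(bad)
  if (n_bad > 0) {
    inform(paste0("skipped ", n_bad, " malformed ", what, " row(s): ",
                  paste(utils::head(unique(reasons[bad]), 5), collapse = "; ")))
  }
  out <- tbl[!bad, , drop = FALSE]
  attr(out, "n_skipped") <- n_bad
  out
}

#' @rdname read_records
#' @export
read_patients <- function(path) {
  tbl <- .read_checked(path, c("patient_id", "date_of_birth"),
                       readr::cols(.default = readr::col_character()))
  if (!"date_of_death" %in% names(tbl)) tbl$date_of_death <- NA_character_
  if (!"sex" %in% names(tbl)) tbl$sex <- "unknown"
  dob <- .parse_iso_date(tbl$date_of_birth)
  dod <- .parse_iso_date(tbl$date_of_death)
  bad <- rep(FALSE, nrow(tbl)); reason <- rep("", nrow(tbl))
  miss_dob <- is.na(dob)
  bad[miss_dob] <- TRUE; reason[miss_dob] <- "unparseable date_of_birth"
  dead_first <- !is.na(dod) & !is.na(dob) & dod < dob
  bad[dead_first] <- TRUE
  reason[dead_first] <- paste0("death before birth (patient_id ",
                               tbl$patient_id[dead_first], ")")
  dup <- duplicated(tbl$patient_id)
  bad[dup] <- TRUE; reason[dup] <- "duplicate patient_id"
  out <- tibble::tibble(
    patient_id = as.character(tbl$patient_id),
    date_of_birth = dob,
    date_of_death = dod,
    sex = ifelse(is.na(tbl$sex) | !tbl$sex %in% c("male", "female"), "unknown", tbl$sex)
  )
  .report_skips(out, bad, reason, "patient")
}

#' @rdname read_records
#' @export
read_prescriptions <- function(path) {
  tbl <- .read_checked(path, c("patient_id", "drug_class", "start_date"),
                       readr::cols(.default = readr::col_character()))
  for (col in c("end_date", "daily_dose_mg", "quantity_mg")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  }
  start <- .parse_iso_date(tbl$start_date)
  end <- .parse_iso_date(tbl$end_date)
  dose <- suppressWarnings(as.numeric(tbl$daily_dose_mg))
  qty <- suppressWarnings(as.numeric(tbl$quantity_mg))
  bad <- rep(FALSE, nrow(tbl)); reason <- rep("", nrow(tbl))
  bad[is.na(start)] <- TRUE; reason[is.na(start)] <- "unparseable start_date"
  rev_dates <- !is.na(start) & !is.na(end) & end < start
  bad[rev_dates] <- TRUE; reason[rev_dates] <- "end_date before start_date"
  bad_class <- !tbl$drug_class %in% c("MPH", "atomoxetine", "antidepressant", "antipsychotic", "other")
  bad[bad_class] <- TRUE; reason[bad_class] <- "unknown drug_class"
  nonpos <- (!is.na(dose) & dose <= 0) | (!is.na(qty) & qty <= 0)
  bad[nonpos] <- TRUE; reason[nonpos] <- "non-positive dose/quantity"
  out <- tibble::tibble(
    patient_id = as.character(tbl$patient_id),
    drug_class = tbl$drug_class,
    start_date = start, end_date = end,
    daily_dose_mg = dose, quantity_mg = qty
  )
  .report_skips(out, bad, reason, "prescription")
}

#' @rdname read_records
#' @export
read_events <- function(path) {
  tbl <- .read_checked(path, c("patient_id", "event_date", "icd9_code"),
                       readr::cols(.default = readr::col_character()))
  if (!"same_day_order" %in% names(tbl)) tbl$same_day_order <- "unknown"
  date <- .parse_iso_date(tbl$event_date)
  bad <- is.na(date)
  reason <- ifelse(bad, "unparseable event_date", "")
  ord <- tbl$same_day_order
  ord[is.na(ord) | !ord %in% c("before_treatment", "after_treatment")] <- "unknown"
  out <- tibble::tibble(
    patient_id = as.character(tbl$patient_id),
    event_date = date,
    icd9_code = as.character(tbl$icd9_code),
    same_day_order = ord
  )
  .report_skips(out, bad, reason, "event")
}

.parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

#' Write the canonical tables back to CSV
#'
#' Inverse of the [read_records] readers; reading a valid file and writing it
#' again round-trips byte-identically.
#'
#' @param x A patients/prescriptions/events tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @name write_records
NULL

.write_canonical <- function(x, path, num_cols = character()) {
  out <- as.data.frame(x)
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
    if (col %in% num_cols) out[[col]] <- ifelse(is.na(out[[col]]), "", format(out[[col]], trim = TRUE, scientific = FALSE))
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
write_patients <- function(x, path) .write_canonical(x, path)

#' @rdname write_records
#' @export
write_prescriptions <- function(x, path) .write_canonical(x, path, c("daily_dose_mg", "quantity_mg"))

#' @rdname write_records
#' @export
write_events <- function(x, path) .write_canonical(x, path)

#' Determine the duration of each prescription
#'
#' The on-medication duration of a prescription is, in order of preference:
#' the recorded start-to-end span (inclusive), the rounded ratio of quantity
#' to daily dose when the end date is missing, and otherwise an imputed
#' dataset median. The chosen rule is reported per row in `duration_source`
#' (`recorded`, `dose_quantity`, `imputed_median`). A dose/quantity ratio
#' below one day is clamped to 1 with a warning.
#'
#' @param prescriptions A prescriptions tibble (see [read_prescriptions()]).
#' @param median_days Imputation value for fully missing durations (days).
#'   The default 70 is the median prescription length observed in the source
#'   cohort; it is dataset-specific and should be overridden when known.
#' @return The input tibble with `duration_days` (positive integer),
#'   `end_date_imputed` (the inclusive end date implied by the duration) and
#'   `duration_source` columns added.
#' @export
#' @examples
#' rx <- tibble::tibble(
#'   patient_id = "P1", drug_class = "MPH",
#'   start_date = as.Date("2010-05-01"),
#'   end_date = as.Date(c("2010-07-09", NA, NA)),
#'   daily_dose_mg = c(NA, 20, NA), quantity_mg = c(NA, 600, NA)
#' )
#' episode_durations(rx)$duration_days  # 70, 30, 70
episode_durations <- function(prescriptions, median_days = 70L) {
  stopifnot(median_days > 0)
  rx <- tibble::as_tibble(prescriptions)
  s <- .day_num(rx$start_date)
  e <- .day_num(rx$end_date)
  recorded <- !is.na(e)
  dur <- e - s + 1L
  if (any(recorded & dur <= 0L)) {
    abort("recorded prescription duration <= 0 days", class = "sccs_input_error")
  }
  has_dq <- !recorded & !is.na(rx$daily_dose_mg) & !is.na(rx$quantity_mg)
  dq <- as.integer(round(rx$quantity_mg / rx$daily_dose_mg))
  if (any(has_dq & dq < 1L)) {
    warn("dose/quantity duration below 1 day clamped to 1")
    dq <- pmax(dq, 1L)
  }
  dur[has_dq] <- dq[has_dq]
  imputed <- !recorded & !has_dq
  dur[imputed] <- as.integer(median_days)
  rx$duration_days <- as.integer(dur)
  rx$end_date_imputed <- .as_date(s + dur - 1L)
  rx$duration_source <- dplyr::case_when(
    recorded ~ "recorded",
    has_dq ~ "dose_quantity",
    TRUE ~ "imputed_median"
  )
  rx
}

#' Build on-medication exposure episodes from prescriptions
#'
#' Collapses a patient's prescriptions for one drug class into contiguous
#' exposure episodes: prescriptions that overlap or abut (next start on the
#' day after the previous end) merge into one episode, since continuous
#' supply implies continuous exposure; any gap of at least one uncovered day
#' separates episodes. Duplicate identical prescription rows are dropped
#' first (with a message). Continuous treatment is never assumed: drug
#' holidays between episodes remain baseline time.
#'
#' @inheritParams episode_durations
#' @param drug_class Drug class to build episodes for (default `"MPH"`).
#' @return A tibble `patient_id`, `start_date`, `end_date` (inclusive),
#'   `duration_days`, `n_prescriptions`, `duration_source` (the per-episode
#'   worst source among its prescriptions: recorded < dose_quantity <
#'   imputed_median), sorted by patient and start date. Attribute
#'   `source_counts` tabulates `duration_source` over prescriptions.
#' @export
build_episodes <- function(prescriptions, median_days = 70L, drug_class = "MPH") {
  rx <- tibble::as_tibble(prescriptions)
  rx <- rx[rx$drug_class == drug_class, , drop = FALSE]
  if (nrow(rx) == 0L) {
    return(tibble::tibble(
      patient_id = character(), start_date = .as_date(integer()),
      end_date = .as_date(integer()), duration_days = integer(),
      n_prescriptions = integer(), duration_source = character()
    ))
  }
  dup <- duplicated(rx[c("patient_id", "start_date", "end_date", "daily_dose_mg", "quantity_mg")])
  if (any(dup)) {
    inform(paste0("dropped ", sum(dup), " duplicate prescription row(s)"))
    rx <- rx[!dup, , drop = FALSE]
  }
  rx <- episode_durations(rx, median_days = median_days)
  src_counts <- table(rx$duration_source)

  s <- .day_num(rx$start_date)
  e <- s + rx$duration_days - 1L
  src_rank <- match(rx$duration_source, c("recorded", "dose_quantity", "imputed_median"))
  o <- order(rx$patient_id, s, e)
  pid <- rx$patient_id[o]; s <- s[o]; e <- e[o]; src_rank <- src_rank[o]

  cm <- stats::ave(e, pid, FUN = cummax)
  n <- length(s)
  new_grp <- c(TRUE, pid[-1] != pid[-n] | s[-1] > cm[-n] + 1L)
  grp <- cumsum(new_grp)
  last_of_grp <- c(which(new_grp)[-1] - 1L, n)
  out <- tibble::tibble(
    patient_id = pid[new_grp],
    start_date = .as_date(s[new_grp]),
    end_date = .as_date(cm[last_of_grp]),
    n_prescriptions = as.integer(tabulate(grp)),
    duration_source = c("recorded", "dose_quantity", "imputed_median")[
      as.integer(tapply(src_rank, grp, max))]
  )
  out$duration_days <- as.integer(.day_num(out$end_date) - .day_num(out$start_date) + 1L)
  out <- out[, c("patient_id", "start_date", "end_date", "duration_days",
                 "n_prescriptions", "duration_source")]
  attr(out, "source_counts") <- src_counts
  out
}
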