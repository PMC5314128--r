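#' Configuration for the synthetic-cohort simulator
#'
#' The simulator emulates a paediatric stimulant-safety cohort drawn from
#' routine electronic medical records: observation between the sixth and
#' twentieth birthdays within a fixed study period, episodic on-medication
#' periods with drug holidays, rare first psychotic events whose
#' piecewise-constant daily hazard carries age and seasonal trends, an
#' elevated rate in a pre-exposure window before the first-ever episode
#' (event-driven treatment initiation), and censoring drugs. Defaults are
#' calibrated to the cohort facts of the motivating study population: median
#' prescription length 70 days, about 2.2 exposed years per case, roughly
#' ten years of follow-up, ~5% atomoxetine switching, and an overall event
#' rate near 6 per 10,000 patient-years.
#'
#' @param n_cases_target Number of case patients to simulate.
#' @param seed Default seed used by [simulate_sccs_cohort()].
#' @param baseline_rate_per_day Baseline daily event hazard.
#' @param true_irr_exposed,true_irr_pre True rate ratios in exposed and
#'   pre-exposure time.
#' @param pre_exposure_days True pre-exposure window length (days).
#' @param age_log_trend_per_band Additive log-hazard per one-year age band
#'   (relative to age six).
#' @param season_multipliers Four positive seasonal multipliers
#'   (Jan--Mar, ..., Oct--Dec); normalised to mean 1.
#' @param episodes_per_patient_mean Mean episode count (1 + Poisson).
#' @param episode_duration_median_days,episode_duration_log_sd Log-normal
#'   episode duration parameters (median in days, sd on the log scale).
#' @param gap_mean_days Mean baseline gap between consecutive episodes.
#' @param dob_year_range Inclusive birth-year range, uniform.
#' @param p_atomoxetine_switch Probability a patient ever receives
#'   atomoxetine (censoring the window at a random date).
#' @param p_event_first_day_before_flag Probability an event on an
#'   episode's first day is recorded as occurring before that day's
#'   treatment.
#' @param p_hallucination Probability the outcome code is a hallucination
#'   (780.1) rather than a psychosis code (298.x).
#' @param p_substance_code Probability of a substance-misuse diagnosis
#'   (ICD-9-CM 304.90) at a random in-window date.
#' @param p_adhd_diagnosis Probability of an ADHD diagnosis code (314.00)
#'   shortly before the first exposure.
#' @param p_psychotropic_rx Probability of a post-event
#'   antidepressant/antipsychotic prescription.
#' @param p_missing_end_date Probability a prescription's end date is
#'   absent (half of those carry dose/quantity instead; the rest fall back
#'   to median imputation downstream).
#' @param study_start,study_end Study period bounds.
#' @return A validated `sccs_sim_config` list.
#' @export
simulation_config <- function(n_cases_target = 100L,
                              seed = 1L,
                              baseline_rate_per_day = 1.7e-6,
                              true_irr_exposed = 1.0,
                              true_irr_pre = 4.64,
                              pre_exposure_days = 90L,
                              age_log_trend_per_band = 0.10,
                              season_multipliers = c(0.95, 0.95, 1.00, 1.10),
                              episodes_per_patient_mean = 14,
                              episode_duration_median_days = 70,
                              episode_duration_log_sd = 0.6,
                              gap_mean_days = 60,
                              dob_year_range = c(1992L, 2005L),
                              p_atomoxetine_switch = 0.05,
                              p_event_first_day_before_flag = 0.5,
                              p_hallucination = 0.20,
                              p_substance_code = 0.155,
                              p_adhd_diagnosis = 0.74,
                              p_psychotropic_rx = 0.25,
                              p_missing_end_date = 0.01,
                              study_start = .STUDY_START,
                              study_end = .STUDY_END) {
  stopifnot(
    n_cases_target >= 1, baseline_rate_per_day >= 0,
    true_irr_exposed > 0, true_irr_pre > 0,
    pre_exposure_days >= 0,
    length(season_multipliers) == 4L, all(season_multipliers > 0),
    episodes_per_patient_mean >= 1,
    episode_duration_median_days > 0, episode_duration_log_sd > 0,
    gap_mean_days > 0,
    length(dob_year_range) == 2L, dob_year_range[1] <= dob_year_range[2]
  )
  for (p in c(p_atomoxetine_switch, p_event_first_day_before_flag,
              p_hallucination, p_substance_code, p_adhd_diagnosis,
              p_psychotropic_rx, p_missing_end_date)) {
    stopifnot(p >= 0, p <= 1)
  }
  if (abs(mean(season_multipliers) - 1) > 1e-8) {
    inform("season_multipliers normalised to mean 1")
    season_multipliers <- season_multipliers / mean(season_multipliers)
  }
  structure(as.list(environment()), class = "sccs_sim_config")
}

# upper bound on any candidate's probability of becoming a case, used for
# the bounded-work rejection step (accept with prob p_case / p_cap)
.sim_p_cap <- function(config) {
  ss <- .day_num(config$study_start); se <- .day_num(config$study_end)
  t_max <- min(se - ss + 1, 14 * 366)
  age_max <- exp(max(0, config$age_log_trend_per_band) * 13)
  s_max <- max(config$season_multipliers)
  base_mult <- max(1, config$true_irr_exposed)
  pre_extra <- config$pre_exposure_days * max(0, config$true_irr_pre - base_mult)
  lam_cap <- config$baseline_rate_per_day * s_max * age_max *
    (t_max * base_mult + pre_extra)
  1 - exp(-lam_cap)
}

# draw m candidate patient structures (window, censoring, episodes) using
# the current RNG stream; returns only eligible candidates
.sim_candidates <- function(config, m) {
  ss <- .day_num(config$study_start); se <- .day_num(config$study_end)
  yr <- config$dob_year_range[1] + floor(runif(m) * (config$dob_year_range[2] - config$dob_year_range[1] + 1))
  dob <- .month_start(as.integer(yr), 0L) + floor(runif(m) * 365)
  ws <- pmax(ss, .add_years(dob, 6L))
  we0 <- pmin(se, .add_years(dob, 20L) - 1L)
  has_atx <- runif(m) < config$p_atomoxetine_switch
  atx <- ws + floor(runif(m) * (we0 - ws + 1))
  atx[!has_atx] <- NA_integer_
  we <- ifelse(is.na(atx), we0, pmin(we0, atx - 1L))
  ok <- ws <= we
  idx <- which(ok)
  n <- length(idx)
  dob <- dob[idx]; ws <- ws[idx]; we <- we[idx]; atx <- atx[idx]
  k <- 1L + rpois(n, config$episodes_per_patient_mean - 1)
  f <- ws + floor(runif(n) * (we - ws + 1))
  K <- sum(k)
  pid <- rep.int(seq_len(n), k)
  dur <- pmax(1, round(rlnorm(K, log(config$episode_duration_median_days),
                              config$episode_duration_log_sd)))
  gap <- 1 + floor(rexp(K, 1 / config$gap_mean_days))
  firstrow <- !duplicated(pid)
  gap[firstrow] <- 0
  inc <- dur + gap
  cs <- cumsum(inc) - inc
  base <- cs[firstrow]
  rel0 <- cs - rep.int(base, k)
  s <- f[pid] + rel0 + gap
  e <- s + dur - 1
  keep <- s <= we[pid]
  epi <- data.frame(pid = pid[keep], s = as.integer(s[keep]),
                    e = as.integer(pmin(e[keep], we[pid][keep])),
                    true_dur = as.integer(dur[keep]))
  list(n = n, dob = dob, ws = ws, we = we, atx = atx, episodes = epi)
}

# piecewise-constant daily hazard over the candidate's true segments
.sim_hazard <- function(cand, config) {
  seg <- .segment_cohort(cand$n, cand$ws, cand$we, cand$dob,
                         cand$episodes$pid, cand$episodes$s, cand$episodes$e,
                         pre_days = config$pre_exposure_days,
                         washout_days = 0L, extension_days = 0L,
                         band_months = 12L)
  ints <- seg$intervals
  catmult <- c(1, config$true_irr_pre, config$true_irr_exposed)[ints$cat]
  lam <- config$baseline_rate_per_day *
    exp(config$age_log_trend_per_band * (ints$band - 6)) *
    config$season_multipliers[ints$season] * catmult
  ints$lam <- lam
  ints$cum <- ints$len * lam
  Lam <- unname(rowsum(ints$cum, ints$pid, reorder = TRUE)[, 1L])
  list(intervals = ints, Lambda = Lam)
}

# invert the cumulative hazard on the day grid at targets E (one per
# patient); returns the event day and the interval row hit
.sim_invert <- function(ints, E) {
  # ints restricted and re-indexed to patients 1..length(E), sorted by pid
  cs <- cumsum(ints$cum)
  firstrow <- !duplicated(ints$pid)
  base <- (cs - ints$cum)[firstrow]
  cum0 <- (cs - ints$cum) - base[ints$pid]
  Eby <- E[ints$pid]
  sel <- which(Eby >= cum0 & Eby < cum0 + ints$cum & ints$lam > 0)
  day <- ints$start[sel] + pmin(ints$len[sel] - 1L,
                                as.integer(floor((Eby[sel] - cum0[sel]) / ints$lam[sel])))
  hit <- data.frame(pid = ints$pid[sel], day = day, cat = ints$cat[sel])
  # float edge: a target landing exactly on a boundary can miss; take the
  # last positive-rate interval of any unmatched patient
  missing <- setdiff(seq_along(E), hit$pid)
  if (length(missing)) {
    idx <- vapply(missing, function(p) {
      rows <- which(ints$pid == p & ints$lam > 0)
      rows[length(rows)]
    }, integer(1))
    hit <- rbind(hit, data.frame(pid = missing, day = ints$end[idx], cat = ints$cat[idx]))
  }
  hit[order(hit$pid), , drop = FALSE]
}

#' Simulate candidate patients (optionally conditioned on an event)
#'
#' Draws `n` patient structures — birth date, observation window with
#' possible atomoxetine censoring, and exposure episodes — and samples the
#' first psychotic event from the piecewise-constant hazard by exact
#' inversion of the cumulative hazard over the day grid. With
#' `condition_on_event = TRUE` the event day is drawn from the exact
#' conditional first-event law given that at least one event occurs in the
#' window (a truncated unit-exponential target on the cumulative-hazard
#' scale); otherwise events are rare and most patients have none.
#'
#' @param config A [simulation_config()].
#' @param n Number of candidates.
#' @param condition_on_event Draw the event day conditionally for every
#'   candidate.
#' @return A list with `patients` (one row per candidate: window, cumulative
#'   hazard `Lambda`, case probability `p_case`, `event_day`,
#'   `event_category`) and `episodes` (true episode table).
#' @export
simulate_sccs_patients <- function(config, n, condition_on_event = FALSE) {
  cand <- .sim_candidates(config, n)
  if (cand$n == 0L) {
    return(list(patients = tibble::tibble(), episodes = tibble::tibble()))
  }
  hz <- .sim_hazard(cand, config)
  Lam <- hz$Lambda
  if (condition_on_event) {
    if (any(Lam <= 0)) abort("zero hazard: cannot condition on an event")
    E <- -log(1 - runif(cand$n) * (1 - exp(-Lam)))
    hit <- .sim_invert(hz$intervals, E)
    event_day <- hit$day; event_cat <- hit$cat
  } else {
    E <- rexp(cand$n)
    has <- E < Lam
    event_day <- rep(NA_integer_, cand$n)
    event_cat <- rep(NA_integer_, cand$n)
    if (any(has)) {
      ints <- hz$intervals[hz$intervals$pid %in% which(has), , drop = FALSE]
      ints$pid <- match(ints$pid, which(has))
      hit <- .sim_invert(ints, E[has])
      event_day[has] <- hit$day
      event_cat[has] <- hit$cat
    }
  }
  pts <- tibble::tibble(
    pid = seq_len(cand$n),
    date_of_birth = .as_date(cand$dob),
    window_start = .as_date(cand$ws),
    window_end = .as_date(cand$we),
    atomoxetine_date = .as_date(cand$atx),
    Lambda = Lam,
    p_case = 1 - exp(-Lam),
    event_day = .as_date(event_day),
    event_category = .CAT_LEVELS[event_cat]
  )
  epi <- tibble::as_tibble(cand$episodes)
  list(patients = pts, episodes = epi)
}

#' Simulate a case series cohort
#'
#' Repeatedly draws candidate patients and retains case patients — patients
#' whose first psychotic event falls inside their observation window — until
#' `n_cases_target` cases are collected. Conditioning is implemented as
#' exact rejection: a candidate structure is accepted with probability
#' proportional to its case probability (bounded by an analytic cap), and
#' the accepted patient's event day is then drawn from the conditional
#' first-event law, which reproduces the simulate-then-select law with
#' bounded work per case. Deterministic given `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param include_noncases Also return the rejected candidate patients (no
#'   outcome events) drawn along the way, for cohort-context tests.
#' @return An `sccs_cohort` list: `patients`, `prescriptions`, `events`
#'   tibbles in the canonical CSV schemas, and `truth` (the config plus
#'   per-case true event category and person-time bookkeeping, candidate
#'   counts and the acceptance rate).
#' @export
simulate_sccs_cohort <- function(config = simulation_config(), seed = config$seed,
                                 include_noncases = FALSE) {
  set.seed(as.integer(seed))
  p_cap <- .sim_p_cap(config)
  target <- as.integer(config$n_cases_target)
  acc <- list(); acc_epi <- list(); non <- list(); non_epi <- list()
  n_cases <- 0L; n_cand <- 0L; n_batches <- 0L
  while (n_cases < target) {
    n_batches <- n_batches + 1L
    if (n_batches > 1000L) {
      abort("simulator failed to reach the case target in 1000 batches; hazard too low?",
            class = "sccs_sim_error")
    }
    m <- max(64L, ceiling((target - n_cases) * 3L))
    cand <- .sim_candidates(config, m)
    if (cand$n == 0L) next
    hz <- .sim_hazard(cand, config)
    p <- 1 - exp(-hz$Lambda)
    if (n_batches == 1L && mean(p) < 1e-9) {
      abort(paste0("expected case acceptance is negligible (mean case probability ",
                   format(mean(p)), "); raise baseline_rate_per_day"),
            class = "sccs_sim_error")
    }
    u <- runif(cand$n)
    take <- which(u < p / p_cap)
    # draw conditional event days only for accepted candidates
    if (length(take)) {
      E <- -log(1 - runif(length(take)) * (1 - exp(-hz$Lambda[take])))
      ints <- hz$intervals[hz$intervals$pid %in% take, , drop = FALSE]
      ints$pid <- match(ints$pid, take)
      hit <- .sim_invert(ints, E)
      keep_n <- min(length(take), target - n_cases)
      sel <- seq_len(keep_n)
      batch <- list(
        dob = cand$dob[take][sel], ws = cand$ws[take][sel],
        we = cand$we[take][sel], atx = cand$atx[take][sel],
        event_day = hit$day[sel], event_cat = hit$cat[sel],
        Lambda = hz$Lambda[take][sel]
      )
      acc[[length(acc) + 1L]] <- batch
      epi <- cand$episodes[cand$episodes$pid %in% take[sel], , drop = FALSE]
      epi$case <- match(epi$pid, take) + n_cases
      acc_epi[[length(acc_epi) + 1L]] <- epi
      n_cases <- n_cases + keep_n
    }
    if (include_noncases) {
      rej <- setdiff(seq_len(cand$n), take)
      non[[length(non) + 1L]] <- list(dob = cand$dob[rej], ws = cand$ws[rej],
                                      we = cand$we[rej], atx = cand$atx[rej])
      epi <- cand$episodes[cand$episodes$pid %in% rej, , drop = FALSE]
      epi$case <- match(epi$pid, rej) + sum(vapply(non, function(b) length(b$dob), 0L)) - length(rej)
      non_epi[[length(non_epi) + 1L]] <- epi
    }
    n_cand <- n_cand + cand$n
  }
  .sim_assemble(config, seed, acc, acc_epi, non, non_epi, n_cand)
}

# turn accepted batches into the canonical patient/prescription/event tables
.sim_assemble <- function(config, seed, acc, acc_epi, non, non_epi, n_cand) {
  dob <- unlist(lapply(acc, `[[`, "dob"))
  ws <- unlist(lapply(acc, `[[`, "ws"))
  we <- unlist(lapply(acc, `[[`, "we"))
  atx <- unlist(lapply(acc, `[[`, "atx"))
  event_day <- unlist(lapply(acc, `[[`, "event_day"))
  event_cat <- unlist(lapply(acc, `[[`, "event_cat"))
  Lambda <- unlist(lapply(acc, `[[`, "Lambda"))
  nc <- length(dob)
  epi <- do.call(rbind, acc_epi)
  epi <- epi[order(epi$case, epi$s), , drop = FALSE]

  n_non <- 0L
  if (length(non)) {
    ndob <- unlist(lapply(non, `[[`, "dob"))
    n_non <- length(ndob)
  }
  id <- sprintf("P%05d", seq_len(nc + n_non))
  case_id <- id[seq_len(nc)]

  se_day <- .day_num(config$study_end)

  patients <- tibble::tibble(
    patient_id = case_id,
    date_of_birth = .as_date(dob),
    date_of_death = .as_date(rep(NA_integer_, nc)),
    sex = ifelse(runif(nc) < 0.699, "male", "female")
  )

  # MPH prescriptions: one row per true episode; a small fraction lack the
  # end date (half of those carry dose/quantity instead)
  K <- nrow(epi)
  miss <- runif(K) < config$p_missing_end_date
  dose_route <- miss & (runif(K) < 0.5)
  rx_end <- .as_date(ifelse(miss, NA_integer_, epi$e))
  rx <- tibble::tibble(
    patient_id = case_id[epi$case],
    drug_class = "MPH",
    start_date = .as_date(epi$s),
    end_date = rx_end,
    daily_dose_mg = ifelse(dose_route, 20, NA_real_),
    quantity_mg = ifelse(dose_route, 20 * (epi$e - epi$s + 1), NA_real_)
  )
  has_atx <- !is.na(atx)
  if (any(has_atx)) {
    rx <- dplyr::bind_rows(rx, tibble::tibble(
      patient_id = case_id[has_atx], drug_class = "atomoxetine",
      start_date = .as_date(atx[has_atx]),
      end_date = .as_date(pmin(atx[has_atx] + 27L, se_day)),
      daily_dose_mg = NA_real_, quantity_mg = NA_real_))
  }
  has_psy <- runif(nc) < config$p_psychotropic_rx
  psy_start <- event_day + 30L + as.integer(floor(rexp(nc, 1 / 150)))
  has_psy <- has_psy & psy_start <= se_day
  if (any(has_psy)) {
    rx <- dplyr::bind_rows(rx, tibble::tibble(
      patient_id = case_id[has_psy],
      drug_class = ifelse(runif(sum(has_psy)) < 0.5, "antidepressant", "antipsychotic"),
      start_date = .as_date(psy_start[has_psy]),
      end_date = .as_date(pmin(psy_start[has_psy] + 27L, se_day)),
      daily_dose_mg = NA_real_, quantity_mg = NA_real_))
  }

  # outcome events (+ day-1 temporal flags), ADHD and substance codes
  first_s <- epi$s[!duplicated(epi$case)]
  first_by_case <- rep(NA_integer_, nc)
  first_by_case[epi$case[!duplicated(epi$case)]] <- first_s
  epkey <- .pid_key(epi$case, epi$s)
  day1 <- .pid_key(seq_len(nc), event_day) %in% epkey
  flag <- rep("unknown", nc)
  day1_before <- day1 & runif(nc) < config$p_event_first_day_before_flag
  flag[day1_before] <- "before_treatment"
  flag[day1 & !day1_before] <- "after_treatment"
  hall <- runif(nc) < config$p_hallucination
  code <- ifelse(hall, "780.1",
                 sample(c("298.0", "298.1", "298.3", "298.8", "298.9"), nc, TRUE))
  events <- tibble::tibble(
    patient_id = case_id, event_date = .as_date(event_day),
    icd9_code = code, same_day_order = flag
  )
  has_adhd <- runif(nc) < config$p_adhd_diagnosis & !is.na(first_by_case)
  adhd_day <- pmax(ws, first_by_case - 30L - as.integer(floor(rexp(nc, 1 / 90))))
  if (any(has_adhd)) {
    events <- dplyr::bind_rows(events, tibble::tibble(
      patient_id = case_id[has_adhd], event_date = .as_date(adhd_day[has_adhd]),
      icd9_code = "314.00", same_day_order = "unknown"))
  }
  has_sub <- runif(nc) < config$p_substance_code
  sub_day <- ws + as.integer(floor(runif(nc) * (we - ws + 1)))
  if (any(has_sub)) {
    events <- dplyr::bind_rows(events, tibble::tibble(
      patient_id = case_id[has_sub], event_date = .as_date(sub_day[has_sub]),
      icd9_code = "304.90", same_day_order = "unknown"))
  }

  if (n_non > 0L) {
    nws <- unlist(lapply(non, `[[`, "ws"))
    nwe <- unlist(lapply(non, `[[`, "we"))
    natx <- unlist(lapply(non, `[[`, "atx"))
    non_id <- id[nc + seq_len(n_non)]
    patients <- dplyr::bind_rows(patients, tibble::tibble(
      patient_id = non_id, date_of_birth = .as_date(ndob),
      date_of_death = .as_date(rep(NA_integer_, n_non)),
      sex = ifelse(runif(n_non) < 0.699, "male", "female")))
    nepi <- do.call(rbind, non_epi)
    if (!is.null(nepi) && nrow(nepi)) {
      rx <- dplyr::bind_rows(rx, tibble::tibble(
        patient_id = non_id[nepi$case], drug_class = "MPH",
        start_date = .as_date(nepi$s), end_date = .as_date(nepi$e),
        daily_dose_mg = NA_real_, quantity_mg = NA_real_))
    }
    nha <- !is.na(natx)
    if (any(nha)) {
      rx <- dplyr::bind_rows(rx, tibble::tibble(
        patient_id = non_id[nha], drug_class = "atomoxetine",
        start_date = .as_date(natx[nha]),
        end_date = .as_date(pmin(natx[nha] + 27L, se_day)),
        daily_dose_mg = NA_real_, quantity_mg = NA_real_))
    }
  }

  rx <- rx[order(rx$patient_id, rx$start_date, rx$drug_class), , drop = FALSE]
  events <- events[order(events$patient_id, events$event_date, events$icd9_code), , drop = FALSE]

  # person-time bookkeeping under the true segmentation, for realism checks
  exp_days <- rowsum(as.numeric(epi$e - epi$s + 1L), epi$case, reorder = TRUE)[, 1L]
  exposed_days <- numeric(nc)
  exposed_days[as.integer(rownames(rowsum(as.numeric(epi$e - epi$s + 1L), epi$case)))] <- exp_days
  truth_cases <- tibble::tibble(
    patient_id = case_id,
    window_days = we - ws + 1L,
    exposed_days = exposed_days,
    event_category = .CAT_LEVELS[event_cat],
    Lambda = Lambda
  )
  structure(
    list(patients = patients, prescriptions = rx, events = events,
         truth = list(config = config, seed = as.integer(seed),
                      cases = truth_cases, n_candidates = n_cand,
                      acceptance_rate = nc / n_cand)),
    class = "sccs_cohort"
  )
}

#' Write a simulated cohort to CSV files (plus the truth as JSON)
#'
#' @param cohort An `sccs_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patients(cohort$patients, file.path(dir, "patients.csv"))
  write_prescriptions(cohort$prescriptions, file.path(dir, "prescriptions.csv"))
  write_events(cohort$events, file.path(dir, "events.csv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir Directory containing `patients.csv`, `prescriptions.csv`,
#'   `events.csv`.
#' @return An `sccs_cohort` list (without `truth` unless `truth.json`
#'   exists).
#' @export
read_cohort <- function(dir) {
  out <- list(
    patients = read_patients(file.path(dir, "patients.csv")),
    prescriptions = read_prescriptions(file.path(dir, "prescriptions.csv")),
    events = read_events(file.path(dir, "events.csv"))
  )
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  structure(out, class = "sccs_cohort")
}
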