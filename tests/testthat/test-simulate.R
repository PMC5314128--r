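flat_config <- function(...) {
  simulation_config(true_irr_exposed = 1, true_irr_pre = 1,
                    age_log_trend_per_band = 0, season_multipliers = rep(1, 4),
                    ...)
}

test_that("simulation is deterministic in the seed", {
  cfg <- simulation_config(n_cases_target = 40L)
  a <- simulate_sccs_cohort(cfg, seed = 12)
  b <- simulate_sccs_cohort(cfg, seed = 12)
  c <- simulate_sccs_cohort(cfg, seed = 13)
  expect_identical(a$patients, b$patients)
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$events, b$events)
  expect_false(identical(a$events, c$events))
})

test_that("configuration validates inputs and normalises seasons", {
  expect_error(simulation_config(baseline_rate_per_day = -1))
  expect_error(simulation_config(season_multipliers = c(1, 1, 1)))
  expect_error(simulation_config(p_hallucination = 1.2))
  expect_message(cfg <- simulation_config(season_multipliers = c(2, 2, 2, 2)),
                 "normalised")
  expect_equal(cfg$season_multipliers, rep(1, 4))
})

test_that("a zero hazard produces no events and a diagnostic on conditioning", {
  cfg <- flat_config(baseline_rate_per_day = 0, n_cases_target = 5L)
  set.seed(1)
  sim <- simulate_sccs_patients(cfg, 50)
  expect_true(all(is.na(sim$patients$event_day)))
  expect_error(simulate_sccs_cohort(cfg, seed = 1), class = "sccs_sim_error")
})

test_that("the sampler's cumulative hazard matches a brute-force daily sum", {
  cfg <- simulation_config(n_cases_target = 10L)
  set.seed(31)
  sim <- simulate_sccs_patients(cfg, 30, condition_on_event = TRUE)
  p <- sim$patients; e <- sim$episodes
  for (i in seq_len(nrow(p))) {
    days <- seq(sccspipe:::.day_num(p$window_start[i]), sccspipe:::.day_num(p$window_end[i]))
    dobn <- sccspipe:::.day_num(p$date_of_birth[i])
    band <- vapply(days, function(d) {
      k <- 0L
      while (sccspipe:::.add_years(dobn, k + 1L) <= d) k <- k + 1L
      k
    }, integer(1))
    seas <- sccspipe:::.season_of(days)
    ep <- e[e$pid == p$pid[i], ]
    expd <- days %in% unlist(mapply(seq, ep$s, ep$e, SIMPLIFY = FALSE))
    f <- min(ep$s)
    pre <- !expd & days >= f - cfg$pre_exposure_days & days < f
    mult <- ifelse(expd, cfg$true_irr_exposed, ifelse(pre, cfg$true_irr_pre, 1))
    brute <- sum(cfg$baseline_rate_per_day * exp(cfg$age_log_trend_per_band * (band - 6)) *
                   cfg$season_multipliers[seas] * mult)
    expect_equal(p$Lambda[i], brute, tolerance = 1e-9)
  }
})

test_that("under a flat hazard the conditional event day is uniform in the window", {
  cfg <- flat_config(n_cases_target = 10L)
  set.seed(77)
  sim <- simulate_sccs_patients(cfg, 20000L, condition_on_event = TRUE)
  p <- sim$patients
  len <- as.numeric(p$window_end - p$window_start) + 1
  u <- (as.numeric(p$event_day - p$window_start) + runif(nrow(p))) / len
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("event days and categories are consistent with the patient's own segments", {
  cfg <- simulation_config(n_cases_target = 120L)
  co <- simulate_sccs_cohort(cfg, seed = 55)
  tc <- co$truth$cases
  expect_true(all(tc$event_category %in% c("baseline", "pre_exposure", "exposed")))
  ev <- co$events[co$events$icd9_code %in%
                    c("298.0", "298.1", "298.3", "298.8", "298.9", "780.1"), ]
  expect_equal(nrow(ev), 120L)  # exactly one outcome event per case
  expect_equal(sort(unique(ev$patient_id)), sort(tc$patient_id))
})

test_that("a strong pre-exposure effect enriches events beyond its time share", {
  cfg <- simulation_config(n_cases_target = 250L)  # true pre IRR 4.64
  co <- simulate_sccs_cohort(cfg, seed = 91)
  tc <- co$truth$cases
  pre_share_time <- cfg$pre_exposure_days / mean(tc$window_days)
  pre_share_events <- mean(tc$event_category == "pre_exposure")
  expect_gt(pre_share_events, 2 * pre_share_time)
})

test_that("default cohorts reproduce the study's scale", {
  cfg <- simulation_config(n_cases_target = 300L)
  co <- simulate_sccs_cohort(cfg, seed = 2024)
  tc <- co$truth$cases
  # ~2.17 exposed years per case, ~10 years of observation, 70-day scripts
  expect_lt(abs(mean(tc$exposed_days) / 365.25 - 2.17), 0.5)
  expect_lt(abs(mean(tc$window_days) / 365.25 - 10.16), 1.5)
  mph <- co$prescriptions[co$prescriptions$drug_class == "MPH", ]
  med <- stats::median(as.numeric(mph$end_date - mph$start_date) + 1, na.rm = TRUE)
  expect_lt(abs(med - 70), 10)
  # baseline event rate near 6 per 10,000 patient-years
  expect_lt(abs(cfg$baseline_rate_per_day * 365.25 - 6e-4), 2e-4)
  # a visible minority switch to atomoxetine or carry substance codes
  expect_gt(sum(co$prescriptions$drug_class == "atomoxetine"), 0L)
  expect_gt(sum(co$events$icd9_code == "304.90"), 0L)
  expect_gt(sum(co$events$icd9_code == "314.00"), 0L)
})

test_that("cohorts round-trip through disk including the truth record", {
  cfg <- simulation_config(n_cases_target = 25L)
  co <- simulate_sccs_cohort(cfg, seed = 8)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_setequal(list.files(d), c("patients.csv", "prescriptions.csv",
                                   "events.csv", "truth.json"))
  back <- suppressMessages(read_cohort(d))
  for (tbl in c("patients", "prescriptions", "events")) {
    attr(back[[tbl]], "n_skipped") <- NULL
    expect_equal(back[[tbl]], co[[tbl]], label = tbl)
  }
  expect_equal(back$truth$config$true_irr_pre, 4.64)
})

test_that("non-case patients can be emitted for cohort context", {
  cfg <- simulation_config(n_cases_target = 30L)
  co <- simulate_sccs_cohort(cfg, seed = 14, include_noncases = TRUE)
  case_ids <- co$truth$cases$patient_id
  noncase_ids <- setdiff(co$patients$patient_id, case_ids)
  expect_gt(length(noncase_ids), 0L)
  expect_false(any(co$events$patient_id %in% noncase_ids &
                     startsWith(co$events$icd9_code, "298")))
})
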