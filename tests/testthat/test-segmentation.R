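win_tbl <- function(pid, ws, we) {
  tibble::tibble(patient_id = pid, start_date = as.Date(ws),
                 end_date = as.Date(we), end_reason = "study_end",
                 eligible = TRUE)
}
epi_tbl <- function(pid, s, e) {
  tibble::tibble(patient_id = pid, start_date = as.Date(s), end_date = as.Date(e),
                 duration_days = as.integer(as.Date(e) - as.Date(s)) + 1L,
                 n_prescriptions = 1L, duration_source = "recorded")
}

test_that("classification tiles the window with the documented precedence", {
  w <- win_tbl("A", "2004-01-01", "2004-12-31")
  ep <- epi_tbl("A", "2004-05-01", "2004-06-30")
  seg <- classify_exposure(w, ep)  # pre 90, no washout
  expect_equal(seg$category, c("baseline", "pre_exposure", "exposed", "baseline"))
  expect_equal(seg$start_date,
               as.Date(c("2004-01-01", "2004-02-01", "2004-05-01", "2004-07-01")))
  expect_equal(seg$end_date,
               as.Date(c("2004-01-31", "2004-04-30", "2004-06-30", "2004-12-31")))
  # exact tiling
  expect_equal(sum(as.integer(seg$end_date - seg$start_date) + 1L), 366L)
})

test_that("washout displaces the tail of the pre-exposure window", {
  w <- win_tbl("A", "2004-01-01", "2004-12-31")
  ep <- epi_tbl("A", "2004-05-01", "2004-06-30")
  seg <- classify_exposure(w, ep, scenario_config(washout_days = 14L))
  expect_equal(seg$category,
               c("baseline", "pre_exposure", "excluded_washout", "exposed", "baseline"))
  expect_equal(seg$start_date[3], as.Date("2004-05-01") - 14)
  expect_equal(seg$end_date[3], as.Date("2004-04-30"))
  # washout consumes the overlapping tail of the 90-day pre window
  expect_equal(seg$start_date[2], as.Date("2004-02-01"))
  expect_equal(as.integer(seg$end_date[2] - seg$start_date[2]) + 1L, 76L)
})

test_that("only the first-ever episode gets a pre-exposure window", {
  w <- win_tbl("A", "2004-01-01", "2005-12-31")
  ep <- dplyr::bind_rows(epi_tbl("A", "2004-05-01", "2004-06-30"),
                         epi_tbl("A", "2005-03-01", "2005-04-30"))
  seg <- classify_exposure(w, ep)
  expect_equal(sum(seg$category == "pre_exposure"), 1L)
  expect_equal(seg$start_date[seg$category == "pre_exposure"], as.Date("2004-02-01"))
})

test_that("pre-exposure windows clip at the window start instead of dropping", {
  w <- win_tbl("A", "2004-04-01", "2004-12-31")
  ep <- epi_tbl("A", "2004-05-01", "2004-06-30")
  seg <- classify_exposure(w, ep)
  pre <- seg[seg$category == "pre_exposure", ]
  expect_equal(pre$start_date, as.Date("2004-04-01"))
  expect_equal(as.integer(pre$end_date - pre$start_date) + 1L, 30L)
})

test_that("episode extension merges episodes it reaches", {
  w <- win_tbl("A", "2004-01-01", "2004-12-31")
  ep <- dplyr::bind_rows(epi_tbl("A", "2004-02-01", "2004-02-29"),
                         epi_tbl("A", "2004-03-15", "2004-03-31"))
  plain <- classify_exposure(w, ep)
  expect_equal(sum(plain$category == "exposed"), 2L)
  ext <- classify_exposure(w, ep, scenario_config(extension_weeks = 3L))
  exp_seg <- ext[ext$category == "exposed", ]
  expect_equal(nrow(exp_seg), 1L)
  expect_equal(exp_seg$start_date, as.Date("2004-02-01"))
  expect_equal(exp_seg$end_date, as.Date("2004-03-31") + 21)
})

test_that("segment categories match a per-day oracle on random cohorts", {
  set.seed(99)
  for (rep in 1:40) {
    ws <- as.Date("2004-01-01") + sample.int(300, 1)
    we <- ws + sample(200:1200, 1)
    k <- sample.int(4, 1)
    s <- sort(sample(seq.int(0, as.integer(we - ws)), k)) + as.integer(unclass(ws))
    e <- s + sample.int(120, k)
    pre <- sample(c(0L, 30L, 60L, 90L), 1)
    washout <- sample(c(0L, 7L, 14L, 21L), 1)
    extw <- sample(0:3, 1)
    sc <- scenario_config(pre_exposure_days = pre, washout_days = washout,
                          extension_weeks = extw)
    seg <- suppressWarnings(classify_exposure(
      win_tbl("A", ws, we),
      epi_tbl("A", as.Date(s, origin = "1970-01-01"),
              as.Date(pmin(e, as.integer(unclass(we))), origin = "1970-01-01")),
      sc))
    oracle <- day_categories(as.integer(unclass(ws)), as.integer(unclass(we)),
                             s, e, pre, washout, extw * 7L)
    expect_equal(segments_to_days(seg, "A"), oracle)
  }
})

test_that("age/season cutting is exhaustive, exclusive, and washout-free", {
  cfg <- simulation_config(n_cases_target = 80L)
  co <- simulate_sccs_cohort(cfg, seed = 505)
  sc <- scenario_config(washout_days = 14L)
  ev <- classify_codes(co$events, default_code_map())
  epi <- build_episodes(co$prescriptions)
  w <- build_windows(co$patients, key_dates(co$prescriptions, ev), sc)
  seg <- classify_exposure(w, epi, sc)
  ints <- cut_age_season(seg, co$patients, sc)
  # conservation: window time minus washout time
  seg_len <- as.integer(seg$end_date - seg$start_date) + 1L
  kept <- tapply(seg_len[seg$category != "excluded_washout"],
                 seg$patient_id[seg$category != "excluded_washout"], sum)
  got <- tapply(ints$length_days, ints$patient_id, sum)
  expect_equal(as.integer(got[names(kept)]), as.integer(kept))
  expect_false(any(ints$category == "excluded_washout"))
  # no interval crosses a quarter boundary or a birthday
  expect_true(all(sccspipe:::.season_of(sccspipe:::.day_num(ints$start_date)) ==
                  sccspipe:::.season_of(sccspipe:::.day_num(ints$end_date))))
  dob <- co$patients$date_of_birth[match(ints$patient_id, co$patients$patient_id)]
  band_at <- function(d) {
    ds <- sccspipe:::.day_num(d); db <- sccspipe:::.day_num(dob)
    out <- integer(length(ds))
    for (i in seq_along(ds)) {
      k <- 0L
      while (sccspipe:::.add_months(db[i], 12L * (k + 1L)) <= ds[i]) k <- k + 1L
      out[i] <- k
    }
    out
  }
  idx <- sample.int(nrow(ints), 200L)
  expect_equal(ints$age_band[idx], band_at(ints$start_date)[idx])
  expect_equal(ints$age_band[idx], band_at(ints$end_date)[idx])
})

test_that("six-month bands anchor at the birthday", {
  w <- win_tbl("A", "2004-01-01", "2004-12-31")
  seg <- classify_exposure(w, epi_tbl("A", "2004-05-01", "2004-06-30"))
  patients <- tibble::tibble(patient_id = "A", date_of_birth = as.Date("1997-03-10"),
                             date_of_death = as.Date(NA), sex = "unknown")
  ints <- cut_age_season(seg, patients, scenario_config(age_band_months = 6L))
  # half-birthday 2004-09-10 must start a new interval with band 15
  expect_true(as.Date("2004-09-10") %in% ints$start_date)
  expect_equal(ints$age_band[ints$start_date == as.Date("2004-09-10")][1], 15L)
  expect_equal(ints$age_band[ints$start_date == as.Date("2004-03-10")][1], 14L)
})

test_that("events land in the containing interval; first-day rules apply", {
  fx <- toy_fixture("day1_tie")
  ev <- classify_codes(fx$events, default_code_map())
  epi <- build_episodes(fx$prescriptions)
  w <- build_windows(fx$patients, key_dates(fx$prescriptions, ev), fx$scenario)
  cases <- select_incident_events(ev, w, fx$scenario, default_code_map())
  ints <- sccs_intervals(fx$patients, w, epi, cases, fx$scenario)
  hit <- ints[ints$events > 0, ]
  expect_equal(hit$category, "pre_exposure")
  expect_equal(hit$end_date, as.Date("2010-04-30"))

  # the same event without the flag stays on exposed day one
  fx2 <- fx
  fx2$events$same_day_order <- "after_treatment"
  ev2 <- classify_codes(fx2$events, default_code_map())
  cases2 <- select_incident_events(ev2, w, fx$scenario, default_code_map())
  ints2 <- sccs_intervals(fx$patients, w, epi, cases2, fx$scenario)
  expect_equal(ints2$category[ints2$events > 0], "exposed")

  # under drop_first_day_events the case disappears entirely
  sc3 <- scenario_config(drop_first_day_events = TRUE)
  ints3 <- sccs_intervals(fx$patients, w, epi, cases, sc3)
  expect_equal(sum(ints3$events), 0L)
  expect_equal(attr(ints3, "dropped")$reason, "event_on_first_exposure_day")
  expect_equal(nrow(ints3), 0L)
})

test_that("events in washout time drop the case", {
  fx <- toy_fixture("day1_tie")
  fx$events$event_date <- as.Date("2010-04-25")
  fx$events$same_day_order <- "unknown"
  sc <- scenario_config(washout_days = 14L)
  ev <- classify_codes(fx$events, default_code_map())
  epi <- build_episodes(fx$prescriptions)
  w <- build_windows(fx$patients, key_dates(fx$prescriptions, ev), sc)
  cases <- select_incident_events(ev, w, sc, default_code_map())
  ints <- sccs_intervals(fx$patients, w, epi, cases, sc)
  expect_equal(attr(ints, "dropped")$reason, "event_in_washout")
})

test_that("a flagged first-day event just after a late window start is dropped", {
  patients <- tibble::tibble(patient_id = "A", date_of_birth = as.Date("2000-01-01"),
                             date_of_death = as.Date(NA), sex = "unknown")
  rx <- tibble::tibble(patient_id = "A", drug_class = "MPH",
                       start_date = as.Date("2010-05-01"),
                       end_date = as.Date("2010-07-09"),
                       daily_dose_mg = NA_real_, quantity_mg = NA_real_)
  events <- tibble::tibble(patient_id = "A", event_date = as.Date("2010-05-01"),
                           icd9_code = "298.9", same_day_order = "before_treatment")
  sc <- scenario_config(pre_exposure_days = 0L)
  ev <- classify_codes(events, default_code_map())
  epi <- build_episodes(rx)
  w <- build_windows(patients, key_dates(rx, ev), sc,
                     study_start = "2010-05-01")  # window opens on the episode day
  cases <- select_incident_events(ev, w, sc, default_code_map())
  ints <- sccs_intervals(patients, w, epi, cases, sc)
  expect_equal(attr(ints, "dropped")$reason, "event_shifted_before_window")
})
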