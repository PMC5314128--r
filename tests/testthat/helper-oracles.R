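# Independent oracles, written without reusing any package internals, for
# cross-checking the likelihood and the segmentation engine.

# interval-table constructor for hand-built fit inputs
mk_ints <- function(pid, cat, len, ev, band = 6L, season = 1L) {
  n <- length(pid)
  tibble::tibble(
    patient_id = as.character(pid),
    start_date = as.Date("2005-01-01"),
    end_date = as.Date("2005-01-01"),
    category = cat,
    age_band = rep_len(band, n),
    season = rep_len(season, n),
    length_days = as.integer(len),
    events = as.integer(ev)
  )
}

# brute-force conditional (multinomial) log-likelihood: loops over patients
# and intervals, no linear algebra shared with the package implementation
brute_loglik <- function(intervals, beta) {
  mult <- function(row) {
    m <- 0
    for (nm in names(beta)) {
      hit <- switch(nm,
        pre_exposure = row$category == "pre_exposure",
        exposed = row$category == "exposed",
        startsWith(nm, "age_band_") && row$age_band == as.integer(sub("age_band_", "", nm)) ||
          startsWith(nm, "season_") && row$season == as.integer(sub("season_", "", nm))
      )
      if (isTRUE(hit)) m <- m + beta[[nm]]
    }
    exp(m)
  }
  ll <- 0
  for (id in unique(intervals$patient_id)) {
    sub <- intervals[intervals$patient_id == id, , drop = FALSE]
    w <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) w[i] <- sub$length_days[i] * mult(sub[i, ])
    for (i in seq_len(nrow(sub))) {
      if (sub$events[i] > 0) ll <- ll + sub$events[i] * log(w[i] / sum(w))
    }
  }
  ll
}

# exhaustive grid search MLE (1 or 2 exposure parameters), refined over
# four rounds to ~1e-5 resolution
grid_fit <- function(intervals, terms) {
  stopifnot(length(terms) %in% 1:2)
  centre <- rep(0, length(terms))
  width <- 4
  for (round in 1:4) {
    pts <- lapply(seq_along(terms), function(i) {
      seq(centre[i] - width, centre[i] + width, length.out = 41)
    })
    grid <- as.matrix(expand.grid(pts))
    vals <- apply(grid, 1, function(b) {
      brute_loglik(intervals, stats::setNames(as.list(b), terms))
    })
    centre <- grid[which.max(vals), ]
    width <- width / 10
  }
  stats::setNames(as.numeric(centre), terms)
}

# per-day exposure-category oracle implementing the documented precedence
# rules (exposed > excluded_washout > pre_exposure > baseline) one day at a
# time; episodes given as raw (unmerged) spans
day_categories <- function(ws, we, epi_s, epi_e, pre_days, washout_days,
                           extension_days) {
  days <- seq.int(ws, we)
  cat <- rep("baseline", length(days))
  exposed_days <- integer()
  for (j in seq_along(epi_s)) {
    exposed_days <- union(exposed_days, seq.int(epi_s[j], epi_e[j] + extension_days))
  }
  exposed_days <- exposed_days[exposed_days >= ws & exposed_days <= we]
  if (length(exposed_days)) {
    f <- min(exposed_days)
    for (i in seq_along(days)) {
      d <- days[i]
      if (d %in% exposed_days) cat[i] <- "exposed"
      else if (washout_days > 0 && d >= f - washout_days && d < f) cat[i] <- "excluded_washout"
      else if (pre_days > 0 && d >= f - pre_days && d < f - washout_days) cat[i] <- "pre_exposure"
    }
  }
  cat
}

# expand a classify_exposure() result for one patient back to days
segments_to_days <- function(segments, id) {
  sub <- segments[segments$patient_id == id, , drop = FALSE]
  sub <- sub[order(sub$start_date), , drop = FALSE]
  unlist(lapply(seq_len(nrow(sub)), function(i) {
    rep(sub$category[i], as.integer(sub$end_date[i] - sub$start_date[i]) + 1L)
  }))
}

# split every analysis interval at its midpoint (refinement of the partition)
refine_intervals <- function(ints) {
  long <- ints$length_days > 1L
  a <- ints
  a$length_days[long] <- ints$length_days[long] %/% 2L
  b <- ints[long, , drop = FALSE]
  b$length_days <- ints$length_days[long] - ints$length_days[long] %/% 2L
  b$events <- 0L  # keep the event count with the first half
  out <- rbind(a, b)
  out[order(out$patient_id), , drop = FALSE]
}

# small default-condition cohort shared by several test files
sim_cohort_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_cases_target = 150L)
      cache <<- simulate_sccs_cohort(cfg, seed = 424242)
    }
    cache
  }
})

# run the single-scenario pipeline on a cohort and return the fit
pipeline_fit <- function(cohort, scenario = scenario_config("pre90")) {
  ev <- classify_codes(cohort$events, default_code_map())
  epi <- build_episodes(cohort$prescriptions)
  w <- build_windows(cohort$patients, key_dates(cohort$prescriptions, ev), scenario)
  cases <- select_incident_events(ev, w, scenario, default_code_map())
  ints <- sccs_intervals(cohort$patients, w, epi, cases, scenario)
  suppressWarnings(sccs_fit(ints))
}
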