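# Interval segmentation engine.
#
# Everything here works on parallel integer vectors (patient index, day
# number) so that whole cohorts are segmented in a handful of vectorised
# passes; the exported wrappers translate to/from tibbles with Date columns.
# Category codes: 1 baseline, 2 pre_exposure, 3 exposed, 4 excluded_washout.

.CAT_LEVELS <- c("baseline", "pre_exposure", "exposed", "excluded_washout")

# merge (after optional extension) and clip episodes; derive pre-exposure and
# washout spans anchored at the first-ever episode; return category segments
# that tile each window exactly.
.classify_segments <- function(n, ws, we, epi_pid, epi_s, epi_e,
                               pre_days, washout_days, extension_days) {
  dropped <- 0L
  if (length(epi_s)) {
    o <- order(epi_pid, epi_s)
    epi_pid <- epi_pid[o]; epi_s <- epi_s[o]
    e2 <- (epi_e[o]) + as.integer(extension_days)
    cm <- stats::ave(e2, epi_pid, FUN = cummax)
    m <- length(epi_s)
    newg <- c(TRUE, epi_pid[-1L] != epi_pid[-m] | epi_s[-1L] > cm[-m] + 1L)
    gl <- c(which(newg)[-1L] - 1L, m)
    ep <- data.frame(pid = epi_pid[newg], s = epi_s[newg], e = cm[gl])
    ep$s <- pmax(ep$s, ws[ep$pid])
    ep$e <- pmin(ep$e, we[ep$pid])
    bad <- ep$s > ep$e
    dropped <- sum(bad)
    ep <- ep[!bad, , drop = FALSE]
  } else {
    ep <- data.frame(pid = integer(), s = integer(), e = integer())
  }

  f <- rep(NA_integer_, n)
  firsts <- ep[!duplicated(ep$pid), , drop = FALSE]
  f[firsts$pid] <- firsts$s

  has <- !is.na(f)
  wash_s <- pmax(ws, f - as.integer(washout_days))
  wash_e <- f - 1L
  haswash <- has & washout_days > 0L & wash_s <= wash_e
  pre_s <- pmax(ws, f - as.integer(pre_days))
  pre_e <- pmin(f - 1L, f - as.integer(washout_days) - 1L)
  haspre <- has & pre_days > 0L & pre_s <= pre_e

  nb <- data.frame(
    pid = c(which(haspre), which(haswash), ep$pid),
    s = c(pre_s[haspre], wash_s[haswash], ep$s),
    e = c(pre_e[haspre], wash_e[haswash], ep$e),
    cat = c(rep(2L, sum(haspre)), rep(4L, sum(haswash)), rep(3L, nrow(ep)))
  )
  o <- order(nb$pid, nb$s)
  nb <- nb[o, , drop = FALSE]

  m <- nrow(nb)
  if (m) {
    firstrow <- c(TRUE, nb$pid[-1L] != nb$pid[-m])
    prev_e <- c(0L, nb$e[-m])
    prev_e[firstrow] <- ws[nb$pid[firstrow]] - 1L
    gs <- prev_e + 1L; ge <- nb$s - 1L
    gok <- gs <= ge
    lastrow <- c(firstrow[-1L], TRUE)
    ts <- nb$e[lastrow] + 1L
    tpid <- nb$pid[lastrow]
    te <- we[tpid]
    tok <- ts <= te
    bare <- setdiff(seq_len(n), nb$pid)
  } else {
    gok <- logical(); tok <- logical()
    gs <- ge <- ts <- te <- tpid <- integer()
    bare <- seq_len(n)
  }
  segs <- data.frame(
    pid = c(nb$pid, nb$pid[gok], tpid[tok], bare),
    s = c(nb$s, gs[gok], ts[tok], ws[bare]),
    e = c(nb$e, ge[gok], te[tok], we[bare]),
    cat = c(nb$cat, rep(1L, sum(gok) + sum(tok) + length(bare)))
  )
  segs <- segs[order(segs$pid, segs$s), , drop = FALSE]
  list(segs = segs, episodes = ep, first_exposed = f,
       washout = data.frame(pid = which(haswash), s = wash_s[haswash], e = wash_e[haswash]),
       n_dropped_episodes = dropped)
}

# split category segments at every age-band change and calendar-quarter
# boundary; drops excluded_washout time from the result.
.cut_segments <- function(segs, n, dob, band_months, keep_washout = FALSE) {
  if (nrow(segs) == 0L) {
    return(data.frame(pid = integer(), start = integer(), end = integer(),
                      len = integer(), cat = integer(), band = integer(),
                      season = integer()))
  }
  pid_lo <- segs$pid[!duplicated(segs$pid)]
  lo <- segs$s[!duplicated(segs$pid)]
  hi <- tapply(segs$e, segs$pid, max)
  pres <- sort(unique(segs$pid))
  lo_by <- rep(NA_integer_, n); hi_by <- rep(NA_integer_, n)
  lo_by[pid_lo] <- lo
  hi_by[pres] <- as.integer(hi[as.character(pres)])

  Q <- .QUARTER_STARTS
  qlo <- findInterval(lo_by[pres], Q) + 1L
  qhi <- findInterval(hi_by[pres], Q)
  nq <- pmax(0L, qhi - qlo + 1L)
  qcut_pid <- rep.int(pres, nq)
  qcut_day <- Q[sequence(nq, from = qlo)]

  kmax <- 252L %/% as.integer(band_months) + 1L
  ser_pid <- rep(pres, each = kmax + 1L)
  ser_k <- rep.int(0L:kmax, length(pres))
  ser_day <- .add_months(dob[ser_pid], as.integer(band_months) * ser_k)
  acut <- ser_day > lo_by[ser_pid] & ser_day <= hi_by[ser_pid]

  cut_pid <- c(segs$pid, qcut_pid, ser_pid[acut], pres)
  cut_day <- c(segs$s, qcut_day, ser_day[acut], hi_by[pres] + 1L)
  o <- order(cut_pid, cut_day)
  cut_pid <- cut_pid[o]; cut_day <- cut_day[o]
  m <- length(cut_day)
  keep <- c(TRUE, cut_pid[-1L] != cut_pid[-m] | cut_day[-1L] != cut_day[-m])
  cut_pid <- cut_pid[keep]; cut_day <- cut_day[keep]
  m <- length(cut_day)

  lastrow <- c(cut_pid[-1L] != cut_pid[-m], TRUE)
  nxt <- c(cut_day[-1L], NA_integer_)
  ipid <- cut_pid[!lastrow]
  ist <- cut_day[!lastrow]
  iend <- nxt[!lastrow] - 1L

  segkey <- .pid_key(segs$pid, segs$s)
  si <- findInterval(.pid_key(ipid, ist), segkey)
  inseg <- ist <= segs$e[si]
  ipid <- ipid[inseg]; ist <- ist[inseg]; iend <- iend[inseg]; si <- si[inseg]
  icat <- segs$cat[si]
  iend <- pmin(iend, segs$e[si])

  serkey <- .pid_key(ser_pid, ser_day)
  bi <- findInterval(.pid_key(ipid, ist), serkey)
  iband <- ser_k[bi]

  out <- data.frame(pid = ipid, start = ist, end = iend,
                    len = iend - ist + 1L, cat = icat,
                    band = iband, season = .season_of(ist))
  if (!keep_washout) out <- out[out$cat != 4L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.segment_cohort <- function(n, ws, we, dob, epi_pid, epi_s, epi_e,
                            pre_days, washout_days, extension_days, band_months) {
  cls <- .classify_segments(n, ws, we, epi_pid, epi_s, epi_e,
                            pre_days, washout_days, extension_days)
  ints <- .cut_segments(cls$segs, n, dob, band_months)
  c(list(intervals = ints), cls[c("episodes", "first_exposed", "washout",
                                  "n_dropped_episodes")])
}

#' Classify each patient's observation time into exposure categories
#'
#' Partitions every eligible observation window into contiguous segments of
#' one exposure category. Episode days are `exposed` (after optional
#' per-episode extension by `extension_weeks`, which merges into any
#' following episode it reaches); the `pre_exposure_days` immediately before
#' the *first-ever* episode are `pre_exposure` (re-initiations get no
#' pre-exposure window); `washout_days` immediately before the first episode
#' are `excluded_washout`, taking precedence over pre-exposure on overlapping
#' days; all remaining window time is `baseline`. Day-level precedence is
#' exposed > excluded_washout > pre_exposure > baseline. Pre-exposure windows
#' that would begin before the window start are clipped, not dropped.
#'
#' @param windows A [build_windows()] tibble.
#' @param episodes A [build_episodes()] tibble.
#' @param scenario A [scenario_config()].
#' @return A tibble `patient_id`, `start_date`, `end_date` (inclusive),
#'   `category`; per patient the segments tile the window exactly.
#' @export
classify_exposure <- function(windows, episodes, scenario = scenario_config()) {
  win <- windows[windows$eligible, , drop = FALSE]
  idx <- .cohort_index(win, episodes)
  cls <- .classify_segments(idx$n, idx$ws, idx$we, idx$epi_pid, idx$epi_s, idx$epi_e,
                            scenario$pre_exposure_days, scenario$washout_days,
                            scenario$extension_weeks * 7L)
  if (cls$n_dropped_episodes > 0) {
    warn(paste0(cls$n_dropped_episodes, " episode(s) fell outside the observation window and were dropped"))
  }
  segs <- cls$segs
  tibble::tibble(
    patient_id = idx$ids[segs$pid],
    start_date = .as_date(segs$s),
    end_date = .as_date(segs$e),
    category = .CAT_LEVELS[segs$cat]
  )
}

# shared translation: patient_id -> integer index 1..n
.cohort_index <- function(win, episodes) {
  ids <- win$patient_id
  epi <- episodes[episodes$patient_id %in% ids, , drop = FALSE]
  list(
    n = length(ids), ids = ids,
    ws = .day_num(win$start_date), we = .day_num(win$end_date),
    epi_pid = match(epi$patient_id, ids),
    epi_s = .day_num(epi$start_date), epi_e = .day_num(epi$end_date)
  )
}

#' Split exposure segments at age-band and season boundaries
#'
#' Cuts each segment at every birthday (or half-birthday for 6-month bands)
#' and at every calendar-quarter boundary, so each resulting interval is
#' homogeneous in exposure category, age band and season. Season is the
#' calendar quarter (Jan--Mar = 1, ..., Oct--Dec = 4); the age-band index is
#' the completed number of band-widths since birth at the interval start
#' (band 6 = age 6 in 12-month bands), anchored at the birthday rather than
#' the calendar year because study entry is the sixth birthday.
#' Excluded-washout segments are removed from the output (and from analysed
#' person-time).
#'
#' @param segments A [classify_exposure()] tibble.
#' @param patients A patients tibble (for dates of birth).
#' @param scenario A [scenario_config()] (for `age_band_months`).
#' @return A tibble `patient_id`, `start_date`, `end_date`, `category`,
#'   `age_band`, `season`, `length_days`, `events` (initialised to 0).
#' @export
cut_age_season <- function(segments, patients, scenario = scenario_config()) {
  ids <- unique(segments$patient_id)
  dob <- rep(NA_integer_, length(ids))
  j <- match(ids, patients$patient_id)
  if (anyNA(j)) abort("segments contain patients absent from `patients`")
  dob <- .day_num(patients$date_of_birth)[j]
  segs <- data.frame(
    pid = match(segments$patient_id, ids),
    s = .day_num(segments$start_date),
    e = .day_num(segments$end_date),
    cat = match(segments$category, .CAT_LEVELS)
  )
  segs <- segs[order(segs$pid, segs$s), , drop = FALSE]
  ints <- .cut_segments(segs, length(ids), dob, scenario$age_band_months)
  tibble::tibble(
    patient_id = ids[ints$pid],
    start_date = .as_date(ints$start),
    end_date = .as_date(ints$end),
    category = .CAT_LEVELS[ints$cat],
    age_band = ints$band,
    season = ints$season,
    length_days = ints$len,
    events = 0L
  )
}

#' Place each case's incident event into its analysis interval
#'
#' Adds the single incident event of each case to the unique interval
#' containing the event date, with two special rules. If the event falls on
#' the first day of an exposure episode and was recorded as occurring before
#' that day's treatment was dispensed (`same_day_order = "before_treatment"`),
#' it is assigned to the interval ending the previous day (normally the
#' pre-exposure interval) instead of exposed day 1. Under
#' `scenario$drop_first_day_events`, any case whose event falls on an
#' episode's first day is dropped. Cases whose event lies in excluded washout
#' time are dropped for that scenario. Dropped cases have all their intervals
#' removed, and are tallied in the `dropped` attribute of the result.
#'
#' @param intervals A [cut_age_season()] tibble.
#' @param cases A [select_incident_events()] tibble (one row per case).
#' @param windows,episodes,scenario Pipeline objects; `episodes` must be the
#'   merged episodes actually used for segmentation.
#' @return The intervals tibble with `events` filled in (sums to 1 per
#'   retained case); attribute `dropped` is a tibble `patient_id`, `reason`.
#' @export
attach_events <- function(intervals, cases, windows, episodes,
                          scenario = scenario_config()) {
  if (nrow(cases) == 0L) {
    attr(intervals, "dropped") <- tibble::tibble(patient_id = character(), reason = character())
    return(intervals)
  }
  ids <- unique(intervals$patient_id)
  pid <- match(cases$patient_id, ids)
  if (anyNA(pid)) abort("case patient with no analysis intervals: upstream inconsistency")
  day <- .day_num(cases$event_date)
  win <- windows[match(cases$patient_id, windows$patient_id), , drop = FALSE]
  ws <- .day_num(win$start_date)

  # recompute merged/clipped episode starts and washout span per case
  cls <- .classify_segments(
    length(ids),
    ws = .day_num(windows$start_date)[match(ids, windows$patient_id)],
    we = .day_num(windows$end_date)[match(ids, windows$patient_id)],
    epi_pid = match(episodes$patient_id[episodes$patient_id %in% ids], ids),
    epi_s = .day_num(episodes$start_date)[episodes$patient_id %in% ids],
    epi_e = .day_num(episodes$end_date)[episodes$patient_id %in% ids],
    pre_days = scenario$pre_exposure_days,
    washout_days = scenario$washout_days,
    extension_days = scenario$extension_weeks * 7L
  )
  ep <- cls$episodes; wash <- cls$washout

  drop_reason <- rep(NA_character_, nrow(cases))
  epkey <- .pid_key(ep$pid, ep$s)
  day1 <- .pid_key(pid, day) %in% epkey
  if (isTRUE(scenario$drop_first_day_events)) {
    drop_reason[day1 & is.na(drop_reason)] <- "event_on_first_exposure_day"
  }
  assign_day <- day
  shift <- day1 & cases$same_day_order == "before_treatment" & is.na(drop_reason)
  assign_day[shift] <- day[shift] - 1L
  if (nrow(wash)) {
    # a first-day event shifted back by the tie rule can land in the washout
    wj <- match(pid, wash$pid)
    in_wash <- is.na(drop_reason) & !is.na(wj) &
      assign_day >= wash$s[wj] & assign_day <= wash$e[wj]
    drop_reason[in_wash] <- "event_in_washout"
  }
  pre_window <- assign_day < ws & is.na(drop_reason)
  drop_reason[pre_window] <- "event_shifted_before_window"

  keep <- is.na(drop_reason)
  ipid <- match(intervals$patient_id, ids)
  ikey <- .pid_key(ipid, .day_num(intervals$start_date))
  o <- order(ikey)
  ii <- findInterval(.pid_key(pid[keep], assign_day[keep]), ikey[o])
  row <- as.integer(ifelse(ii >= 1L, o[pmax(ii, 1L)], NA_integer_))
  ok <- !is.na(row) & ipid[row] == pid[keep] &
    assign_day[keep] <= .day_num(intervals$end_date)[row]
  if (!all(ok)) {
    abort(paste0("event outside every analysis interval for patient(s) ",
                 paste(cases$patient_id[keep][!ok], collapse = ", "),
                 " (upstream inconsistency)"))
  }
  ev <- intervals$events
  tab <- tabulate(row[!is.na(row)], nbins = nrow(intervals))
  intervals$events <- ev + tab

  dropped <- tibble::tibble(patient_id = cases$patient_id[!keep],
                            reason = drop_reason[!keep])
  if (nrow(dropped)) {
    intervals <- intervals[!intervals$patient_id %in% dropped$patient_id, , drop = FALSE]
  }
  attr(intervals, "dropped") <- dropped
  intervals
}

#' Build the analysis-interval table for one scenario
#'
#' Composes [classify_exposure()], [cut_age_season()] and [attach_events()]:
#' the result is the exact input to [sccs_fit()] and can be exported as
#' `intervals.csv` so third parties can fit the same model with other
#' software.
#'
#' @inheritParams attach_events
#' @param patients,windows,episodes,cases Pipeline tibbles.
#' @param scenario A [scenario_config()].
#' @return An intervals tibble (see [cut_age_season()]) with events placed;
#'   attribute `dropped` as in [attach_events()].
#' @export
sccs_intervals <- function(patients, windows, episodes, cases,
                           scenario = scenario_config()) {
  win <- windows[windows$eligible & windows$patient_id %in% cases$patient_id, , drop = FALSE]
  segs <- classify_exposure(win, episodes, scenario)
  ints <- cut_age_season(segs, patients, scenario)
  attach_events(ints, cases, win, episodes, scenario)
}
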