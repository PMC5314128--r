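# Internal calendar arithmetic on integer day numbers (days since 1970-01-01).
# All analysis intervals are half-open day ranges [start, end + 1) at 1-day
# resolution; inclusive end dates are used at the tibble/CSV surface only.
# Month tables are precomputed so the hot simulation/segmentation paths never
# touch strptime.

# first day-number of every month 1900-01 .. 2199-12
.MONTH_TABLE_ORIGIN <- 1900L
.MONTH_STARTS <- as.integer(unclass(seq(
  as.Date("1900-01-01"), as.Date("2199-12-01"), by = "month"
)))

.day_num <- function(x) {
  if (inherits(x, "Date")) return(as.integer(unclass(x)))
  as.integer(unclass(as.Date(x)))
}

.as_date <- function(d) as.Date(d, origin = "1970-01-01")

# first day-number of month m0 (0-based, may exceed 11) of year y
.month_start <- function(y, m0) {
  idx <- (y - .MONTH_TABLE_ORIGIN) * 12L + m0 + 1L
  .MONTH_STARTS[idx]
}

# calendar components of a day-number without strptime
.day_ymd <- function(day) {
  idx <- findInterval(day, .MONTH_STARTS)
  list(
    year = .MONTH_TABLE_ORIGIN + (idx - 1L) %/% 12L,
    mon0 = (idx - 1L) %% 12L,
    mday = day - .MONTH_STARTS[idx] + 1L
  )
}

# date plus k calendar months, rolling 29/30/31 back to the last day of a
# short month (so the 6th/20th "birthday" of a Feb 29 birth is Feb 28)
.add_months <- function(day, k) {
  p <- .day_ymd(day)
  mtot <- p$mon0 + k
  y2 <- p$year + mtot %/% 12L
  m2 <- mtot %% 12L
  ms <- .month_start(y2, m2)
  n_days <- .month_start(y2, m2 + 1L) - ms
  ms + pmin(p$mday, n_days) - 1L
}

.add_years <- function(day, k) .add_months(day, 12L * k)

# quarter starts covering the month table; season = 1..4 (Jan-Mar = 1)
.QUARTER_STARTS <- .MONTH_STARTS[seq(1L, length(.MONTH_STARTS), by = 3L)]

.season_of <- function(day) {
  qi <- findInterval(day, .QUARTER_STARTS)
  (qi - 1L) %% 4L + 1L
}

# composite sort key so one global findInterval can do per-patient interval
# lookups; day numbers stay far below 1e5 for the supported calendar range
.KEY_OFFSET <- 1e5
.pid_key <- function(pid, day) as.numeric(pid) * .KEY_OFFSET + as.numeric(day)
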