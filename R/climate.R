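# Canadian Fire Weather Index Drought Code (Van Wagner 1987) and the
# centered/scaled monthly anomalies used to flag drought episodes.

# Monthly day-length factors Lf for the DC, northern hemisphere.
dc_day_length_factor <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4,
                          5.0, 2.4, 0.4, -1.6, -1.6)

#' Daily Drought Code update
#'
#' One day of the standard Drought Code recursion. Potential
#' evapotranspiration is `V = max(0, 0.36 (T + 2.8) + Lf(month))` with the
#' temperature floored at -2.8 degC; when rain exceeds 2.8 mm the moisture
#' equivalent `Q = 800 exp(-DC/400)` is recharged by `3.937 (0.83 P - 1.27)`
#' before evaporation is added as `0.5 V`.
#'
#' @param dc_prev Previous day's DC (>= 0). Vectorized.
#' @param tmean Noon/mean temperature, degC.
#' @param precip 24-h precipitation, mm.
#' @param month Calendar month 1-12 (selects the day-length factor).
#' @return Updated DC, always >= 0.
#' @export
#' @examples
#' drought_code_step(200, tmean = 20, precip = 0, month = 7) # 207.304
drought_code_step <- function(dc_prev, tmean, precip, month) {
  if (any(month < 1L | month > 12L | month != as.integer(month))) {
    stop_input("month must be an integer in 1-12")
  }
  if (any(dc_prev < 0)) stop_input("dc_prev must be >= 0")
  t <- pmax(tmean, -2.8)
  v <- pmax(0.36 * (t + 2.8) + dc_day_length_factor[month], 0)
  dc <- dc_prev
  rainy <- precip > 2.8
  if (any(rainy)) {
    rw <- 0.83 * precip[rainy] - 1.27
    q <- 800 * exp(-dc[rainy] / 400) + 3.937 * rw
    dc[rainy] <- pmax(400 * log(800 / q), 0)
  }
  pmax(dc + 0.5 * v, 0)
}

#' Monthly mean Drought Code over a daily climate series
#'
#' Iterates the daily DC within each fire season (April 1 to October 31 by
#' default), restarting from `overwinter_reset` every spring, and averages the
#' daily values per calendar month. Months outside the fire season are not
#' reported.
#'
#' @param series Daily climate tibble with columns `date`, `tmean`, `precip`;
#'   dates must be contiguous.
#' @param overwinter_reset DC value at the start of each fire season.
#' @param season_months Integer months making up the fire season.
#' @return Tibble with columns `year`, `month`, `dc_raw`.
#' @export
monthly_dc <- function(series, overwinter_reset = 15,
                       season_months = 4:10) {
  check_columns(series, c("date", "tmean", "precip"), "climate series")
  d <- as.Date(series$date)
  if (any(diff(d) != 1L)) {
    gaps <- d[which(diff(d) != 1L)]
    missing <- unlist(lapply(gaps, function(g) {
      format(seq(g + 1, d[which(d == g) + 1] - 1, by = "day"))
    }))
    stop_input(sprintf("gap(s) in daily dates; missing: %s",
                       paste(head(missing, 10L), collapse = ", ")))
  }
  if (any(series$precip < 0)) stop_input("precipitation must be >= 0")
  yr <- as.integer(format(d, "%Y"))
  mo <- as.integer(format(d, "%m"))
  in_season <- mo %in% season_months
  n <- length(d)
  dc <- rep(NA_real_, n)
  cur <- overwinter_reset
  first_month <- min(season_months)
  prev_in <- FALSE
  for (i in seq_len(n)) {
    if (!in_season[i]) {
      prev_in <- FALSE
      next
    }
    if (!prev_in) cur <- overwinter_reset # spring reset at season start
    cur <- drought_code_step(cur, series$tmean[i], series$precip[i], mo[i])
    dc[i] <- cur
    prev_in <- TRUE
  }
  out <- tibble(year = yr[in_season], month = mo[in_season],
                dc = dc[in_season])
  out <- dplyr::summarise(dplyr::group_by(out, .data$year, .data$month),
                          dc_raw = mean(.data$dc), .groups = "drop")
  dplyr::arrange(out, .data$year, .data$month)
}

#' Center and scale monthly Drought Code anomalies
#'
#' Per calendar month, subtracts the baseline-period mean and divides by the
#' baseline-period standard deviation, the form used to identify drier- and
#' wetter-than-usual months.
#'
#' @param monthly Tibble from [monthly_dc()] (columns `year`, `month`,
#'   `dc_raw`).
#' @param baseline Length-2 year range used as the climatological baseline.
#' @return Input tibble with an added `dc_scaled` column; the baseline is
#'   recorded in attribute `"baseline"`.
#' @export
scale_monthly <- function(monthly, baseline = c(1985, 2015)) {
  check_columns(monthly, c("year", "month", "dc_raw"), "monthly index table")
  base <- monthly[monthly$year >= baseline[1] & monthly$year <= baseline[2], ]
  if (nrow(base) == 0L) stop_input("no baseline years present")
  stats <- dplyr::summarise(
    dplyr::group_by(base, .data$month),
    n = dplyr::n(), m = mean(.data$dc_raw), s = sd(.data$dc_raw),
    .groups = "drop"
  )
  if (any(stats$n < 2L)) {
    stop_input(sprintf("baseline needs >= 2 years per month (month %s)",
                       paste(stats$month[stats$n < 2L], collapse = ", ")))
  }
  if (any(stats$s == 0)) {
    stop_input(sprintf("zero baseline SD for month %s",
                       paste(stats$month[stats$s == 0], collapse = ", ")))
  }
  out <- dplyr::left_join(monthly, stats[, c("month", "m", "s")], by = "month")
  out$dc_scaled <- (out$dc_raw - out$m) / out$s
  out$m <- NULL
  out$s <- NULL
  attr(out, "baseline") <- baseline
  out
}
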