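# Tree-ring processing: BAI conversion, frequency-response spline detrending,
# dating quality control, robust-mean chronologies and bootstrapped
# climate-growth correlations. Ring data travel as tidy tibbles with columns
# id, year, value.

#' Convert ring widths to basal area increments
#'
#' `BAI_t = pi (r_t^2 - r_(t-1)^2)` with `r_t = r0 + cumulative width`,
#' assuming growth from the pith when `r0 = 0`.
#'
#' @param rings Tibble with columns `id`, `year`, `width` (mm); years must be
#'   contiguous within each series.
#' @param r0 Initial radius (mm) at the first measured ring.
#' @return Tibble with columns `id`, `year`, `bai` (mm2).
#' @export
#' @examples
#' width_to_bai(tibble::tibble(id = "t", year = 1:2, width = c(1, 1)))
width_to_bai <- function(rings, r0 = 0) {
  check_columns(rings, c("id", "year", "width"), "ring series")
  bad <- rings$width <= 0
  if (any(bad)) {
    stop_input(sprintf("non-positive ring width for %s in year %d",
                       rings$id[bad][1], rings$year[bad][1]))
  }
  rings <- dplyr::arrange(rings, .data$id, .data$year)
  dplyr::mutate(
    dplyr::group_by(rings, .data$id),
    r = r0 + cumsum(.data$width),
    bai = pi * (.data$r^2 - dplyr::lag(.data$r, default = r0)^2),
    r = NULL,
    width = NULL
  ) |> dplyr::ungroup()
}

#' Convert basal area increments back to ring widths
#'
#' Exact inverse of [width_to_bai()] for the same `r0`.
#'
#' @param rings Tibble with columns `id`, `year`, `bai` (mm2).
#' @inheritParams width_to_bai
#' @return Tibble with columns `id`, `year`, `width` (mm).
#' @export
bai_to_width <- function(rings, r0 = 0) {
  check_columns(rings, c("id", "year", "bai"), "ring series")
  if (any(rings$bai <= 0)) stop_input("BAI must be strictly positive")
  rings <- dplyr::arrange(rings, .data$id, .data$year)
  dplyr::mutate(
    dplyr::group_by(rings, .data$id),
    r = sqrt(r0^2 + cumsum(.data$bai) / pi),
    width = .data$r - dplyr::lag(.data$r, default = r0),
    r = NULL,
    bai = NULL
  ) |> dplyr::ungroup()
}

# Cubic smoothing spline parameterized by its frequency response `f` at a
# given wavelength (Cook-Peters). The classical parameter p (csaps
# convention, minimize p*RSS + (1-p)*roughness) maps to the smooth.spline
# lambda after accounting for its internal rescaling of x to [0, 1].
cook_peters_p <- function(f, wavelength) {
  cc <- cos(2 * pi / wavelength)
  1 / (((cc + 2) * (1 - f)) / (12 * f * (cc - 1)^2) + 1)
}

fit_cook_peters_spline <- function(year, value, f, wavelength) {
  p <- cook_peters_p(f, wavelength)
  lambda_years <- (1 - p) / p
  r <- diff(range(year))
  fit <- smooth.spline(year, value, lambda = lambda_years / r^3,
                       all.knots = TRUE, keep.data = FALSE)
  predict(fit, year)$y
}

#' Detrend ring series with a frequency-response spline
#'
#' Fits, per series, a cubic smoothing spline whose frequency response equals
#' `f` at the given wavelength (default two-thirds of the series length, the
#' dendrochronological convention when only `f` is stated) and returns the
#' ratio of raw values to the fitted curve as a dimensionless growth index.
#'
#' @param rings Tibble with columns `id`, `year` and a value column.
#' @param f Frequency response in (0, 1) at `wavelength`.
#' @param wavelength Wavelength in years at which the response equals `f`;
#'   `NULL` means 0.67 times each series' length.
#' @param value_col Name of the value column to detrend (default `"bai"`).
#' @return Tibble with columns `id`, `year`, `index`.
#' @export
detrend_spline <- function(rings, f = 0.7, wavelength = NULL,
                           value_col = "bai") {
  check_columns(rings, c("id", "year", value_col), "ring series")
  if (f <= 0 || f >= 1) stop_input("f must lie in (0, 1)")
  rings <- dplyr::arrange(rings, .data$id, .data$year)
  out <- lapply(split(rings, rings$id), function(s) {
    if (nrow(s) < 4L) {
      stop_input(sprintf("series %s too short to detrend (%d < 4 years)",
                         s$id[1], nrow(s)))
    }
    wl <- wavelength %||% (0.67 * nrow(s))
    curve <- fit_cook_peters_spline(s$year, s[[value_col]], f, wl)
    if (any(curve <= 0)) {
      stop_input(sprintf(
        "fitted detrending curve is non-positive for series %s; consider a stiffer spline or a different detrending method",
        s$id[1]
      ))
    }
    tibble(id = s$id, year = s$year, index = s[[value_col]] / curve)
  })
  dplyr::bind_rows(out)
}

#' Cross-dating quality check against a leave-one-out site master
#'
#' For each series, computes the Pearson correlation between its detrended
#' index and the arithmetic mean of all other series over the overlapping
#' years, and flags series falling below `threshold` (or with too little
#' overlap) for inspection.
#'
#' @param index Tibble with columns `id`, `year`, `index` (detrended values).
#' @param threshold Correlation below which a series is flagged.
#' @param min_overlap Minimum overlapping years required to test a series.
#' @return Tibble with columns `id`, `n_overlap`, `correlation`, `flag`
#'   (`"ok"`, `"low_correlation"` or `"insufficient_overlap"`).
#' @export
check_dating <- function(index, threshold = 0.2, min_overlap = 5L) {
  check_columns(index, c("id", "year", "index"), "index series")
  ids <- unique(index$id)
  if (length(ids) < 3L) stop_input("dating check needs at least 3 series")
  wide <- tidyr::pivot_wider(index, id_cols = "year", names_from = "id",
                             values_from = "index")
  wide <- dplyr::arrange(wide, .data$year)
  m <- as.matrix(wide[, ids, drop = FALSE])
  totals <- rowSums(m, na.rm = TRUE)
  counts <- rowSums(!is.na(m))
  res <- lapply(ids, function(id) {
    x <- m[, id]
    have <- !is.na(x) & (counts - !is.na(x)) >= 1L
    master <- (totals[have] - ifelse(is.na(x[have]), 0, x[have])) /
      (counts[have] - 1L)
    x <- x[have]
    if (sum(have) < min_overlap) {
      return(tibble(id = id, n_overlap = sum(have),
                    correlation = NA_real_, flag = "insufficient_overlap"))
    }
    r <- suppressWarnings(cor(x, master))
    tibble(id = id, n_overlap = sum(have), correlation = r,
           flag = if (!is.finite(r) || r < threshold) "low_correlation" else "ok")
  })
  dplyr::bind_rows(res)
}

# Tukey's biweight robust mean (c = 9, median start, iterated).
tbrm <- function(x, c = 9) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  m <- median(x)
  for (i in 1:50) {
    s <- median(abs(x - m))
    if (s == 0) return(m)
    u <- (x - m) / (c * s)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < 1e-12) break
    m <- m_new
  }
  m_new
}

#' Build a robust-mean chronology
#'
#' Per-year Tukey biweight robust mean of the detrended indices, with the
#' number of contributing series recorded as sample depth. Years below
#' `min_depth` (or, when `min_frac` is given, below that fraction of the
#' total series count) are dropped.
#'
#' @inheritParams check_dating
#' @param min_depth Minimum sample depth for a year to be reported.
#' @param min_frac Optional minimum fraction of all series that must be
#'   present in a year (e.g. 0.5 to require at least half of the trees).
#' @return Tibble with columns `year`, `index`, `depth`.
#' @export
build_chronology <- function(index, min_depth = 1L, min_frac = NULL) {
  check_columns(index, c("id", "year", "index"), "index series")
  if (nrow(index) == 0L) stop_input("empty index input")
  n_series <- length(unique(index$id))
  out <- dplyr::summarise(
    dplyr::group_by(index, .data$year),
    index = tbrm(.data$index),
    depth = dplyr::n(),
    .groups = "drop"
  )
  keep <- out$depth >= min_depth
  if (!is.null(min_frac)) keep <- keep & out$depth >= min_frac * n_series
  dplyr::arrange(out[keep, ], .data$year)
}

#' Bootstrapped correlations between a chronology and monthly climate
#'
#' Pearson correlations between the chronology and a monthly climate index
#' for each requested month of the current and/or preceding year, with a
#' percentile bootstrap confidence interval obtained by resampling years with
#' replacement. A correlation is flagged significant when its interval
#' excludes zero.
#'
#' @param chron Chronology tibble (`year`, `index`) from
#'   [build_chronology()].
#' @param climate Monthly climate tibble (`year`, `month` plus `value_col`),
#'   e.g. from [scale_monthly()].
#' @param months Months of the growing season to correlate.
#' @param lags Either of `"current"` and `"previous"` (climate of year t vs
#'   growth of year t, or climate of year t-1 vs growth of year t).
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level of the percentile interval.
#' @param value_col Climate value column (default `"dc_scaled"`).
#' @param seed Seed for the bootstrap.
#' @return Tibble with columns `month`, `lag`, `estimate`, `conf_low`,
#'   `conf_high`, `significant`, `n_years`.
#' @export
bootstrap_climate_correlation <- function(chron, climate, months = 5:8,
                                          lags = c("previous", "current"),
                                          n_boot = 1000L, conf = 0.95,
                                          value_col = "dc_scaled",
                                          seed = 1L) {
  check_columns(chron, c("year", "index"), "chronology")
  check_columns(climate, c("year", "month", value_col), "climate table")
  lags <- match.arg(lags, c("previous", "current"), several.ok = TRUE)
  combos <- expand.grid(month = months, lag = lags,
                        stringsAsFactors = FALSE)
  with_seed(seed, {
    res <- lapply(seq_len(nrow(combos)), function(k) {
      mth <- combos$month[k]
      lag <- combos$lag[k]
      clim <- climate[climate$month == mth, c("year", value_col)]
      clim_year <- clim$year + if (lag == "previous") 1L else 0L
      idx <- match(chron$year, clim_year)
      ok <- !is.na(idx)
      x <- chron$index[ok]
      y <- clim[[value_col]][idx[ok]]
      n <- length(x)
      if (n < 8L) {
        stop_input(sprintf(
          "only %d overlapping years for month %d (%s year); need >= 8",
          n, mth, lag
        ))
      }
      r <- cor(x, y)
      boots <- vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        suppressWarnings(cor(x[i], y[i]))
      }, numeric(1))
      ci <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                     na.rm = TRUE, names = FALSE)
      tibble(month = mth, lag = lag, estimate = r,
             conf_low = min(ci[1], r), conf_high = max(ci[2], r),
             significant = ci[1] > 0 | ci[2] < 0, n_years = n)
    })
    dplyr::bind_rows(res)
  })
}
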