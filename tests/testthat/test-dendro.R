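# Ring-width processing: BAI, spline detrending, dating QC, chronologies,
# climate-growth bootstrap.

test_that("BAI follows the annulus areas and telescopes", {
  b <- width_to_bai(tibble::tibble(id = "t", year = 1:2, width = c(1, 1)))
  expect_equal(b$bai, c(pi, 3 * pi), tolerance = 1e-12)
  w <- runif(15, 0.3, 4)
  b2 <- width_to_bai(tibble::tibble(id = "t", year = 1:15, width = w))
  expect_equal(sum(b2$bai), pi * sum(w)^2, tolerance = 1e-9)
  # with a starting radius
  b3 <- width_to_bai(tibble::tibble(id = "t", year = 1, width = 2), r0 = 3)
  expect_equal(b3$bai, pi * (25 - 9), tolerance = 1e-12)
  expect_error(
    width_to_bai(tibble::tibble(id = "t", year = 1:2, width = c(1, -1))),
    "year 2"
  )
})

test_that("spline detrending reproduces constants and interpolates at f -> 1", {
  const <- tibble::tibble(id = "c", year = 1:40, bai = rep(7, 40))
  idx <- detrend_spline(const)
  expect_equal(idx$index, rep(1, 40), tolerance = 1e-8)
  lin <- tibble::tibble(id = "l", year = 1:40, bai = 5 + 0.5 * (1:40))
  idx_l <- detrend_spline(lin, f = 0.999, wavelength = 5)
  expect_equal(idx_l$index, rep(1, 40), tolerance = 1e-4)
  expect_error(detrend_spline(const[1:3, ]), "too short")
})

test_that("ratio detrending is mean-preserving and scale-invariant", {
  set.seed(99)
  means <- vapply(1:100, function(i) {
    n <- sample(25:60, 1)
    y <- 200 * (1 - exp(-(1:n) / 6)) * exp(rnorm(n, sd = 0.2))
    mean(detrend_spline(tibble::tibble(id = "s", year = 1:n, bai = y))$index)
  }, numeric(1))
  expect_true(mean(means) > 0.95 && mean(means) < 1.05)
  expect_gte(mean(means > 0.9 & means < 1.1), 0.95)

  y <- 100 + cumsum(rnorm(30))
  base <- detrend_spline(tibble::tibble(id = "s", year = 1:30, bai = y))
  scaled <- detrend_spline(tibble::tibble(id = "s", year = 1:30, bai = 3.7 * y))
  expect_equal(base$index, scaled$index, tolerance = 1e-8)
})

test_that("dating check flags misdated series against the site master", {
  yrs <- 2000:2019
  saw <- rep(c(0.6, 1.4), 10) # sawtooth signal shared by the site
  set.seed(5)
  idx <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(id = paste0("s", i), year = yrs,
                   index = saw + rnorm(20, sd = 0.05))
  }))
  dup <- tibble::tibble(id = "dup", year = yrs, index = saw)
  shifted <- tibble::tibble(id = "bad", year = yrs,
                            index = c(saw[-1], saw[1])) # +1 year shift
  flags <- check_dating(dplyr::bind_rows(idx, dup, shifted))
  expect_identical(flags$flag[flags$id == "dup"], "ok")
  expect_gt(flags$correlation[flags$id == "dup"], 0.9)
  expect_identical(flags$flag[flags$id == "bad"], "low_correlation")
  expect_lt(flags$correlation[flags$id == "bad"], 0.2)

  short <- tibble::tibble(id = "short", year = 2000:2002, index = 1)
  flags2 <- check_dating(dplyr::bind_rows(idx, short))
  expect_identical(flags2$flag[flags2$id == "short"], "insufficient_overlap")
  expect_error(check_dating(idx[idx$id %in% c("s1", "s2"), ]), "3 series")
})

test_that("robust-mean chronology resists outliers and tracks depth", {
  yrs <- 1:25
  one <- tibble::tibble(id = "a", year = yrs, index = sin(yrs / 3) / 5 + 1)
  chron1 <- build_chronology(dplyr::bind_rows(
    one, dplyr::mutate(one, id = "b"), dplyr::mutate(one, id = "c")
  ))
  expect_equal(chron1$index, one$index, tolerance = 1e-12)
  expect_true(all(chron1$depth == 3L))

  set.seed(11)
  many <- dplyr::bind_rows(lapply(1:10, function(i) {
    tibble::tibble(id = paste0("t", i), year = yrs,
                   index = 1 + rnorm(25, sd = 0.05))
  }))
  clean_mean <- mean(many$index[many$year == 10])
  spiked <- many
  spiked$index[spiked$id == "t1" & spiked$year == 10] <- 15 # gross outlier
  chron <- build_chronology(spiked)
  expect_lt(abs(chron$index[chron$year == 10] - clean_mean) / clean_mean, 0.02)
  expect_equal(sum(chron$depth), nrow(many))
  expect_error(build_chronology(many[0, ]), "empty")
})

test_that("minimum-fraction subsetting drops sparse years", {
  idx <- dplyr::bind_rows(
    tibble::tibble(id = "a", year = 1:10, index = 1),
    tibble::tibble(id = "b", year = 6:10, index = 1)
  )
  chron <- build_chronology(idx, min_frac = 0.5)
  expect_true(all(chron$depth >= 1))
  chron2 <- build_chronology(idx, min_frac = 0.9)
  expect_identical(chron2$year, 6:10)
})

test_that("climate-growth bootstrap recovers perfect dependence and lags", {
  yrs <- 1991:2015
  set.seed(21)
  dc <- tibble::tibble(year = rep(yrs, each = 2), month = rep(7:8, 25),
                       dc_scaled = rnorm(50))
  jul <- dc[dc$month == 7, ]
  chron <- tibble::tibble(year = yrs, index = -jul$dc_scaled)
  res <- bootstrap_climate_correlation(chron, dc, months = 7:8,
                                       lags = "current", n_boot = 200,
                                       seed = 1)
  r_jul <- res[res$month == 7, ]
  expect_equal(r_jul$estimate, -1, tolerance = 1e-12)
  expect_true(r_jul$significant)
  expect_true(all(res$conf_low <= res$estimate &
                    res$estimate <= res$conf_high))

  # previous-year alignment: growth in year t against climate of year t - 1
  chron_prev <- tibble::tibble(year = yrs, index = NA_real_)
  chron_prev$index <- dc$dc_scaled[match(paste(yrs - 1, 7),
                                         paste(dc$year, dc$month))]
  chron_prev <- chron_prev[!is.na(chron_prev$index), ]
  res_prev <- bootstrap_climate_correlation(chron_prev, dc, months = 7,
                                            lags = "previous", n_boot = 100,
                                            seed = 2)
  expect_equal(res_prev$estimate, 1, tolerance = 1e-12)

  expect_error(
    bootstrap_climate_correlation(chron[1:5, ], dc, months = 7,
                                  lags = "current"),
    "overlapping"
  )
})

test_that("bootstrap keeps its nominal type-I error under independence", {
  yrs <- 1981:2010
  set.seed(42)
  hits <- vapply(1:100, function(r) {
    dc <- tibble::tibble(year = yrs, month = 7, dc_scaled = rnorm(30))
    chron <- tibble::tibble(year = yrs, index = rnorm(30))
    res <- bootstrap_climate_correlation(chron, dc, months = 7,
                                         lags = "current", n_boot = 400,
                                         seed = r)
    res$significant
  }, logical(1))
  expect_lte(mean(hits), 0.1)
})

test_that("bootstrap intervals narrow as overlap grows", {
  set.seed(77)
  width_at <- function(n, r) {
    yrs <- seq_len(n) + 1980
    dc <- tibble::tibble(year = yrs, month = 7, dc_scaled = rnorm(n))
    chron <- tibble::tibble(year = yrs,
                            index = 0.5 * dc$dc_scaled + rnorm(n, sd = 1))
    res <- bootstrap_climate_correlation(chron, dc, months = 7,
                                         lags = "current", n_boot = 300,
                                         seed = r)
    res$conf_high - res$conf_low
  }
  short <- mean(vapply(1:25, function(r) width_at(12, r), numeric(1)))
  long <- mean(vapply(1:25, function(r) width_at(45, r), numeric(1)))
  expect_lt(long, short)
})
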