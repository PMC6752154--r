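test_that("Hargreaves ET0 vanishes at zero diurnal range or Tmean = -17.8", {
  w <- tibble::tibble(date = as.Date("2000-07-01"),
                      tmin = 15, tmax = 15, tmean = 15)
  expect_equal(hargreaves_et0(w, 55)$et0_mm, 0)
  w2 <- tibble::tibble(date = as.Date("2000-07-01"),
                       tmin = -25, tmax = -10, tmean = -17.8)
  expect_equal(hargreaves_et0(w2, 55)$et0_mm, 0)
  # colder still: clamped at zero, never negative
  w3 <- dplyr::mutate(w2, tmean = -30)
  expect_equal(hargreaves_et0(w3, 55)$et0_mm, 0)
})

test_that("a worked day matches the independent solar-geometry oracle", {
  # 1 July (doy 182), 55.28 N, Tmin 10, Tmax 25, Tmean 17.5; expected values
  # frozen from a line-by-line independent computation of the standard
  # clear-sky formulas (dr, declination, sunset hour angle, Ra, ET0)
  expect_equal(extraterrestrial_radiation(182, 55.28), 16.800334, tolerance = 1e-6)
  w <- tibble::tibble(date = as.Date("2000-07-01"),  # leap year: doy 183
                      tmin = 10, tmax = 25, tmean = 17.5)
  got <- hargreaves_et0(dplyr::mutate(w, date = as.Date("2001-07-01")), 55.28)$et0_mm
  expect_equal(got, 5.282823, tolerance = 1e-4)
})

test_that("Ra is symmetric about the summer solstice and ET0 grows with diurnal range", {
  ra_before <- extraterrestrial_radiation(171 - (1:60), 55.28)
  ra_after <- extraterrestrial_radiation(171 + (1:60), 55.28)
  expect_true(all(abs(ra_before - ra_after) / ra_before < 0.01))

  ranges <- seq(2, 20, by = 2)
  et0 <- sapply(ranges, function(dr) {
    w <- tibble::tibble(date = as.Date("2000-06-21"),
                        tmean = 15, tmin = 15 - dr / 2, tmax = 15 + dr / 2)
    hargreaves_et0(w, 55.28)$et0_mm
  })
  expect_true(all(diff(et0) > 0))
})

test_that("polar latitudes degrade gracefully via the sunset-angle clamp", {
  # midsummer above the arctic circle: 24 h day, Ra finite and positive
  expect_gt(extraterrestrial_radiation(172, 75), 0)
  # midwinter: no sunrise, Ra clamps to 0
  expect_equal(extraterrestrial_radiation(355, 75), 0)
})

test_that("daily deficits and annual CMD behave at the bounds", {
  days <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
  base <- tibble::tibble(date = days, tmean = 10, tmin = 5, tmax = 15)
  wet <- dplyr::mutate(base, precip = 50)
  expect_equal(annual_cmd(daily_deficit(wet, 55))$cmd_mm, 0)

  dry <- dplyr::mutate(base, precip = 0)
  d <- daily_deficit(dry, 55)
  expect_equal(annual_cmd(d)$cmd_mm, sum(d$et0_mm))

  # monthly aggregation equals daily aggregation
  monthly <- d |>
    dplyr::mutate(month = format(date, "%m")) |>
    dplyr::group_by(month) |>
    dplyr::summarise(cmd = sum(deficit_mm))
  expect_equal(sum(monthly$cmd), annual_cmd(d)$cmd_mm)

  expect_error(daily_deficit(dplyr::mutate(base, precip = -1), 55), "non-negative")
  expect_error(hargreaves_et0(dplyr::mutate(base, tmax = 0), 55), "tmax < tmin")
})

test_that("missing days are excluded and counted, not imputed", {
  days <- seq(as.Date("2000-06-01"), as.Date("2000-06-30"), by = "day")
  w <- tibble::tibble(date = days, tmean = 15, tmin = 10, tmax = 20, precip = 0)
  w$tmean[5] <- NA
  d <- suppressWarnings(daily_deficit(w, 55))
  cmd <- annual_cmd(d)
  expect_equal(cmd$n_missing, 1L)
  expect_equal(cmd$n_days, 29L)
  expect_equal(cmd$cmd_mm, sum(d$deficit_mm[-5]))
})

test_that("anomalies vanish against their own climatology and integrate exactly", {
  days <- seq(as.Date("2001-01-01"), as.Date("2003-12-31"), by = "day")
  doy <- as.integer(format(days, "%j"))
  w <- tibble::tibble(date = days, x = 10 + 5 * sin(2 * pi * doy / 365))
  clim <- daily_climatology(w, "x", smooth_window = 1L)
  a <- anomaly_series(w, clim, "x")
  expect_lt(max(abs(a$anomaly)), 1e-9)
  expect_equal(anomaly_integral(a, "2002-03-01", "2002-03-30")$integral, 0,
               tolerance = 1e-9)

  # a uniform +1 anomaly over 30 days integrates to 30
  w2 <- dplyr::mutate(w, x = x + as.integer(date >= "2002-06-01" & date <= "2002-06-30"))
  a2 <- anomaly_series(w2, clim, "x")
  i2 <- anomaly_integral(a2, "2002-06-01", "2002-06-30")
  expect_equal(i2$integral, 30, tolerance = 1e-9)
  expect_equal(i2$completeness, 1)
})

test_that("the anomaly integral recovers injected drought anomaly mass", {
  # many replicate drought years against a fixed climatology: the mean
  # integral must converge on the injected precipitation shortfall
  cfg <- test_config(seed = 31)
  n_rep <- 40
  wet_p <- cfg$weather$wet_prob * cfg$weather$precip_mean_mm  # E[daily precip]
  scale <- 0.5
  window_days <- 60
  injected <- window_days * wet_p * (scale - 1)
  withr::local_seed(31)
  integrals <- replicate(n_rep, {
    n <- 366
    precip <- stats::rbinom(n, 1, cfg$weather$wet_prob) *
      stats::rgamma(n, cfg$weather$precip_shape,
                    scale = cfg$weather$precip_mean_mm / cfg$weather$precip_shape)
    dates <- seq(as.Date("2000-01-01"), by = "day", length.out = n)
    idx <- 150 + seq_len(window_days)
    precip[idx] <- precip[idx] * scale
    a <- anomaly_series(tibble::tibble(date = dates, precip = precip),
                        tibble::tibble(doy = 1:366, normal = wet_p), "precip")
    anomaly_integral(a, dates[idx[1]], dates[idx[window_days]])$integral
  })
  mc_se <- sd(integrals) / sqrt(n_rep)
  expect_lt(abs(mean(integrals) - injected), 3 * mc_se)
  expect_lt(abs(mean(integrals) - injected) / abs(injected), 0.15)
})

test_that("derived bioclimatic normals follow their closed forms", {
  monthly <- tibble::tibble(month = 1:12, tmean_c = 10, precip_mm = 100)
  d <- derived_normals(monthly)
  expect_equal(d$mat_c, 10)
  expect_equal(d$td_c, 0)
  expect_equal(d$map_mm, 1200)
  expect_equal(d$msp_mm, 500)
  expect_equal(d$ahm, 20 / 1.2)
  expect_equal(d$shm, 10 / 0.5)

  # continentality is shift-invariant in temperature
  withr::local_seed(37)
  m2 <- tibble::tibble(month = 1:12, tmean_c = rnorm(12, 5, 10),
                       precip_mm = runif(12, 20, 120))
  expect_equal(derived_normals(m2)$td_c,
               derived_normals(dplyr::mutate(m2, tmean_c = tmean_c + 11.3))$td_c)

  expect_error(derived_normals(dplyr::filter(monthly, month != 5)), "12 months")
})

test_that("site normals reproduce the published continentality identity", {
  normals <- region_climate_normals()
  site <- dplyr::filter(normals, grepl("field site", location))
  expect_equal(site$td_c, site$mwmt_c - site$mcmt_c, tolerance = 0.05)
  # regional rows satisfy the same identity within printed rounding
  reg <- dplyr::filter(normals, !grepl("field site", location))
  expect_true(all(abs(reg$td_c - (reg$mwmt_c - reg$mcmt_c)) <= 0.4))
  expect_true(all(reg$msp_mm <= reg$map_mm))
})

test_that("drier generator years have strictly larger CMD", {
  cfg <- test_config(seed = 41)
  w <- simulate_weather(cfg)
  d <- daily_deficit(w, cfg$weather$latitude)
  cmd <- annual_cmd(d)
  drought_year <- dplyr::filter(cmd, year == 2002)$cmd_mm
  normal_years <- dplyr::filter(cmd, !year %in% c(1998, 1999, 2002))$cmd_mm
  expect_gt(drought_year, stats::quantile(normal_years, 0.75))
})
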