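test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- test_config(seed = 101)
  expect_identical(simulate_traits(cfg), simulate_traits(cfg))
  expect_identical(simulate_chronologies(cfg), simulate_chronologies(cfg))
  expect_identical(simulate_weather(cfg), simulate_weather(cfg))
  expect_identical(simulate_provenance_climate(cfg), simulate_provenance_climate(cfg))
  cfg2 <- test_config(seed = 102)
  expect_false(identical(simulate_traits(cfg)$height_cm,
                         simulate_traits(cfg2)$height_cm))
  # simulation does not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simulate_chronologies(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the design mirrors the trial dimensions", {
  d <- simulate_traits(test_config(seed = 103))
  expect_equal(nrow(d), 33 * 5 * 5)                      # 825 trees
  expect_equal(dplyr::n_distinct(d$provenance_id), 33)
  expect_equal(dplyr::n_distinct(d$region), 6)
  expect_equal(dplyr::n_distinct(d$block), 5)
  expect_equal(sum(d$cored), 165)                        # 1 / provenance / block
  cored <- dplyr::count(dplyr::filter(d, cored), provenance_id, block)
  expect_true(all(cored$n == 1))
  # 5-tree row plots, one per provenance and block
  expect_true(all(dplyr::count(d, plot)$n == 5))
})

test_that("zero noise and unit multipliers reduce widths to the scaled age trend", {
  cfg <- no_drought_config(seed = 104, tree_sd = 0, year_sd = 0, core_sd = 0,
                           block_sd = 0)
  cfg$regions$growth_multiplier <- rep(1, 6)
  rings <- simulate_chronologies(cfg)
  trend <- generator_truth(rings)$trend
  joined <- dplyr::left_join(rings, trend, by = "year")
  expect_equal(joined$width_mm, joined$trend_mm, tolerance = 1e-12)
})

test_that("injected drought multipliers act in the event years", {
  cfg <- test_config(seed = 105, tree_sd = 0, year_sd = 0, core_sd = 0,
                     block_sd = 0,
                     drought = list(event_years = c(1999L, 2002L),
                                    recovery_lag = 0L, lag_decay = 0.5))
  design <- simulate_traits(cfg)
  rings <- simulate_chronologies(cfg, design)
  truth <- generator_truth(rings)
  one <- rings |>
    dplyr::inner_join(dplyr::select(design, tree_id, region), by = "tree_id") |>
    dplyr::filter(region == "Boreal Cordillera", core_id == core_id[1])
  trend <- truth$trend$trend_mm[match(one$year, truth$trend$year)]
  ratio <- one$width_mm / (trend * truth$region_growth[["Boreal Cordillera"]] *
                             truth$block_multipliers[[as.character(
                               design$block[design$tree_id == one$tree_id[1]])]] *
                             truth$tree_multipliers[[one$tree_id[1]]])
  expect_equal(ratio[one$year == 1999], 0.69, tolerance = 1e-12)
  expect_equal(ratio[one$year == 2002], 0.64, tolerance = 1e-12)
  expect_equal(ratio[one$year == 1998], 1, tolerance = 1e-12)
  expect_equal(ratio[one$year == 2000], 1, tolerance = 1e-12)  # lag 0
})

test_that("the recovery lag decays geometrically after an event", {
  cfg <- test_config(seed = 106, tree_sd = 0, year_sd = 0, core_sd = 0,
                     block_sd = 0,
                     drought = list(event_years = 1999L, recovery_lag = 3L,
                                    lag_decay = 0.5))
  cfg$regions <- cfg$regions[1, ]  # single region, m = 0.69
  cfg$regions$n_provenances <- 2L
  rings <- simulate_chronologies(cfg)
  truth <- generator_truth(rings)
  one <- dplyr::filter(rings, core_id == rings$core_id[1])
  trend <- truth$trend$trend_mm[match(one$year, truth$trend$year)]
  base <- truth$region_growth[[1]] * truth$block_multipliers[[1]] *
    truth$tree_multipliers[[one$tree_id[1]]]
  ratio <- one$width_mm / (trend * base)
  m <- 0.69
  expect_equal(ratio[one$year == 1999], m, tolerance = 1e-12)
  expect_equal(ratio[one$year == 2000], m^0.5, tolerance = 1e-12)
  expect_equal(ratio[one$year == 2001], m^0.25, tolerance = 1e-12)
  expect_equal(ratio[one$year == 2002], m^0.125, tolerance = 1e-12)
  expect_equal(ratio[one$year == 2003], 1, tolerance = 1e-12)
})

test_that("averaging two cores halves the core-noise variance", {
  cfg <- test_config(seed = 107, tree_sd = 0, year_sd = 0, block_sd = 0,
                     core_sd = 0.2)
  cfg$regions$resistance_1999 <- 1; cfg$regions$resistance_2002 <- 1
  cfg$regions$growth_multiplier <- rep(1, 6)
  rings <- simulate_chronologies(cfg)
  truth <- generator_truth(rings)
  trend <- truth$trend
  # log-residual of each core around its tree's known noise-free series
  resid <- rings |>
    dplyr::left_join(trend, by = "year") |>
    dplyr::left_join(tibble::tibble(tree_id = names(truth$tree_multipliers),
                                    u = unname(truth$tree_multipliers)),
                     by = "tree_id") |>
    dplyr::mutate(e = log(width_mm) - log(trend_mm) - log(u))
  per_core <- stats::var(resid$e)
  per_tree <- resid |>
    dplyr::group_by(tree_id, year) |>
    dplyr::summarise(e = mean(e), .groups = "drop") |>
    dplyr::pull(e) |>
    stats::var()
  expect_lt(abs(per_tree / per_core - 0.5), 0.1)
})

test_that("trait simulation honors degenerate settings", {
  cfg <- test_config(seed = 108,
                     trait_vc = list(height = c(prov = 0, block = 0, plot = 0, resid = 0),
                                     dbh = c(prov = 0, block = 0, plot = 0, resid = 0)))
  cfg$regions$survival <- rep(1, 6)
  d <- simulate_traits(cfg)
  means <- generator_truth(d)$region_height_cm
  expect_equal(d$height_cm, unname(means[d$region]))
  expect_true(all(d$survival == 1L))
})

test_that("simulated weather has the configured climate and drought windows", {
  cfg <- test_config(seed = 109)
  w <- simulate_weather(cfg)
  expect_true(all(w$tmax >= w$tmin))
  expect_true(all(w$precip >= 0))
  expect_equal(mean(w$tmean), cfg$weather$tmean_mean, tolerance = 0.5)
  # annual precipitation near the site normal (~490 mm)
  ann <- w |>
    dplyr::mutate(y = format(date, "%Y")) |>
    dplyr::group_by(y) |>
    dplyr::summarise(p = sum(precip))
  expect_lt(abs(mean(ann$p) - 491), 80)
  # drought window 1998-99 clearly drier than the same months in other years
  win <- dplyr::filter(w, date >= "1998-05-01", date <= "1999-08-31")
  other <- dplyr::filter(w, format(date, "%m") %in% sprintf("%02d", 4:8),
                         !format(date, "%Y") %in% c("1998", "1999", "2002"))
  expect_lt(mean(win$precip), 0.7 * mean(other$precip))
})

test_that("synthetic provenance climate satisfies its structural identities", {
  cfg <- test_config(seed = 110)
  clim <- simulate_provenance_climate(cfg)
  expect_equal(nrow(clim), 33)
  expect_equal(clim$td, clim$mwmt - clim$mcmt, tolerance = 1e-12)
  expect_true(all(clim$msp <= clim$map))
  expect_equal(clim$ahm, (clim$mat + 10) / (clim$map / 1000), tolerance = 1e-12)
  # regional separation survives the noise: BC drier than MM on average
  by_region <- clim |>
    dplyr::group_by(region) |>
    dplyr::summarise(map = mean(map))
  expect_lt(by_region$map[by_region$region == "Boreal Cordillera"],
            by_region$map[by_region$region == "Maritime Mixedwood"])
})
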