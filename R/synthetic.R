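# Synthetic provenance-trial generator.
#
# Emulates the Calling Lake white spruce trial at its real dimensions: 33
# provenances in 6 climatic regions, a randomized complete block design with
# 5 blocks and 5-tree row plots (25 trees per provenance for height/DBH and
# survival), and a core-sampling subset of one tree per provenance per block
# (165 cored trees, 2 cores each). Ring widths follow a negative-exponential
# age trend scaled by multiplicative region, block, tree, year and core
# lognormal effects, with drought events injected as multiplicative growth
# shocks whose exponent decays geometrically after the event year (growth does
# not rebound instantly). Every sampled effect is recorded in a truth
# attribute so that pipeline estimates can be compared against known values.

#' Reference tables for the regional defaults
#'
#' Published regional summaries for the Calling Lake provenance trial, shipped
#' as plain CSV: `region_climate_normals()` gives 1961-1990 climate normals of
#' the provenance regions and the test site (MAT, MWMT, MCMT, TD, MAP, MSP,
#' CMD with between-provenance SDs); `region_trait_estimates()` gives the
#' regional BLUEs, standard errors and letter groups for height (age 32),
#' DBH (age 27), survival and the drought indices of the 1999/2002 events.
#' They parameterize the generator defaults and serve as plausibility anchors.
#'
#' @return A tibble.
#' @export
region_climate_normals <- function() {
  readr::read_csv(path_extdata("region_climate_normals.csv"), show_col_types = FALSE)
}

#' @rdname region_climate_normals
#' @export
region_trait_estimates <- function() {
  readr::read_csv(path_extdata("region_trait_estimates.csv"), show_col_types = FALSE)
}

default_region_table <- function() {
  est <- region_trait_estimates()
  est |>
    transmute(
      region = .data$region,
      n_provenances = c(4L, 4L, 3L, 9L, 9L, 4L)[match(
        .data$region,
        c("Boreal Cordillera", "Montane Cordillera", "Maritime Mixedwood",
          "Boreal Plains", "Boreal Shield", "Temperate Mixedwood")
      )],
      growth_multiplier = .data$height32_cm / mean(.data$height32_cm),
      height_mean_cm = .data$height32_cm,
      dbh_mean_mm = .data$dbh27_mm,
      survival = .data$survival,
      resistance_1999 = .data$resistance_1999,
      resistance_2002 = .data$resistance_2002
    )
}

#' Configuration for the synthetic trial generator
#'
#' All defaults mirror the real trial: 6 regions whose provenance counts,
#' relative growth rates, drought-resistance multipliers and survival rates
#' come from the shipped regional estimates ([region_trait_estimates()]);
#' 5 blocks; 5-tree row plots; 2 cores per cored tree; ring years 1988-2017;
#' drought events in 1999 and 2002. Weather defaults approximate the test
#' site: MAT 0.6 C with a seasonal amplitude reproducing the warmest/coldest
#' month normals, about 490 mm annual precipitation from a thinned gamma
#' process, and drought windows in 1998-1999 and 2002 with reduced
#' precipitation and elevated temperature.
#'
#' @param seed Integer seed; every `simulate_*` function derives its RNG
#'   stream from it, so a config is fully reproducible.
#' @param regions Tibble with one row per region: `region`, `n_provenances`,
#'   `growth_multiplier`, `height_mean_cm`, `dbh_mean_mm`, `survival`,
#'   `resistance_1999`, `resistance_2002` (event columns must match
#'   `drought$event_years`).
#' @param n_blocks,trees_per_plot,cores_per_tree Design sizes.
#' @param years Ring-width window `c(first, last)`.
#' @param age_trend List `a_mm` (initial excess width), `tau_yr` (decay time),
#'   `c_mm` (asymptote), `t0` (year of trend origin): the expected raw ring
#'   width is `a_mm * exp(-(year - t0)/tau_yr) + c_mm` before multipliers.
#' @param tree_sd,year_sd,core_sd,block_sd Lognormal (sdlog) dispersions of
#'   the tree, tree-year, core-year and block multipliers.
#' @param drought List `event_years`, `recovery_lag` (years with after-effect)
#'   and `lag_decay` in (0, 1): in event year `e` growth is multiplied by the
#'   region's resistance `m`; `k` years later by `m^(lag_decay^k)` while
#'   `k <= recovery_lag`.
#' @param trait_vc Variance components (response-units squared) for the trait
#'   simulator, as `list(height = c(prov, block, plot, resid), dbh = ...)`.
#' @param weather Weather process parameters; see the default for the fields.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(
    seed = 1L,
    regions = default_region_table(),
    n_blocks = 5L,
    trees_per_plot = 5L,
    cores_per_tree = 2L,
    years = c(1988L, 2017L),
    age_trend = list(a_mm = 2.5, tau_yr = 15, c_mm = 1.0, t0 = 1988L),
    tree_sd = 0.25,
    year_sd = 0.30,
    core_sd = 0.15,
    block_sd = 0.05,
    drought = list(event_years = c(1999L, 2002L), recovery_lag = 3L, lag_decay = 0.5),
    trait_vc = list(height = c(prov = 1600, block = 900, plot = 400, resid = 6400),
                    dbh = c(prov = 64, block = 36, plot = 16, resid = 225)),
    weather = list(
      latitude = 55.28, years = c(1988L, 2017L),
      tmean_mean = 0.6, tmean_amp = 16.8, tmean_sd = 3.0, diurnal_range = 10,
      wet_prob = 0.45, precip_shape = 0.8, precip_mean_mm = 3.0,
      droughts = tibble(
        start = as.Date(c("1998-05-01", "2002-04-01")),
        end = as.Date(c("1999-08-31", "2002-08-31")),
        precip_scale = c(0.45, 0.5),
        temp_anomaly_c = c(2.0, 1.0)
      )
    )) {
  check_columns(regions, c("region", "n_provenances", "growth_multiplier", "survival"),
                "regions")
  for (e in drought$event_years) {
    check_columns(regions, paste0("resistance_", e), "regions")
    m <- regions[[paste0("resistance_", e)]]
    if (any(m <= 0 | m > 1)) abort("Resistance multipliers must be in (0, 1].")
  }
  if (any(regions$n_provenances < 1) || n_blocks < 1 || trees_per_plot < 1 ||
      cores_per_tree < 1) {
    abort("Design sizes must be >= 1.")
  }
  if (any(c(tree_sd, year_sd, core_sd, block_sd) < 0)) abort("Noise SDs must be >= 0.")
  if (drought$lag_decay <= 0 || drought$lag_decay >= 1) abort("`lag_decay` must be in (0, 1).")
  years <- check_window(years, "years")
  structure(
    list(seed = as.integer(seed), regions = regions, n_blocks = as.integer(n_blocks),
         trees_per_plot = as.integer(trees_per_plot),
         cores_per_tree = as.integer(cores_per_tree), years = years,
         age_trend = age_trend, tree_sd = tree_sd, year_sd = year_sd,
         core_sd = core_sd, block_sd = block_sd, drought = drought,
         trait_vc = trait_vc, weather = weather),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic trial config: %d provenances / %d regions, %d blocks, %d-tree plots, cores %d/tree, years %d-%d, events %s (seed %d)\n",
    sum(x$regions$n_provenances), nrow(x$regions), x$n_blocks, x$trees_per_plot,
    x$cores_per_tree, x$years[1], x$years[2],
    paste(x$drought$event_years, collapse = "/"), x$seed))
  invisible(x)
}

# deterministic provenance / tree labels for a config
design_skeleton <- function(cfg) {
  initials <- vapply(strsplit(cfg$regions$region, "\\s+"), function(w) {
    paste(toupper(substr(w, 1, 1)), collapse = "")
  }, character(1))
  provs <- cfg$regions |>
    mutate(.abbr = make.unique(initials, sep = "")) |>
    rowwise() |>
    reframe(region = .data$region,
            provenance_id = sprintf("%s%02d", .data$.abbr, seq_len(.data$n_provenances)))
  tidyr::expand_grid(provs, block = seq_len(cfg$n_blocks),
                     tree_in_plot = seq_len(cfg$trees_per_plot)) |>
    mutate(
      plot = paste0("B", .data$block, "-", .data$provenance_id),
      tree_id = paste0(.data$provenance_id, "-B", .data$block, "-T", .data$tree_in_plot)
    )
}

#' Simulate the trial design with trait measurements
#'
#' Trees are laid out as one 5-tree row plot per provenance and block. Height
#' and DBH follow the trial's mixed-model structure: region mean plus
#' independent normal provenance-within-region, block, plot-within-block and
#' residual effects with the configured variance components. Survival is
#' Bernoulli with the region's configured probability. One tree per provenance
#' and block is marked `cored` — the dendrochronology subsample.
#'
#' @param cfg A [generator_config()].
#' @return A design tibble (`tree_id`, `provenance_id`, `region`, `block`,
#'   `plot`, `height_cm`, `dbh_mm`, `survival`, `cored`) with a `"truth"`
#'   attribute recording every sampled effect and the true region means.
#' @export
simulate_traits <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  skel <- design_skeleton(cfg)
  with_seed(sub_seed(cfg$seed, 1L), {
    draw_trait <- function(mean_by_region, vc) {
      provs <- unique(skel$provenance_id)
      blocks <- unique(skel$block)
      plots <- unique(skel$plot)
      eff_prov <- setNames(rnorm(length(provs), 0, sqrt(vc[["prov"]])), provs)
      eff_block <- setNames(rnorm(length(blocks), 0, sqrt(vc[["block"]])), as.character(blocks))
      eff_plot <- setNames(rnorm(length(plots), 0, sqrt(vc[["plot"]])), plots)
      y <- mean_by_region[skel$region] +
        eff_prov[skel$provenance_id] +
        eff_block[as.character(skel$block)] +
        eff_plot[skel$plot] +
        rnorm(nrow(skel), 0, sqrt(vc[["resid"]]))
      list(y = unname(y), prov = eff_prov, block = eff_block, plot = eff_plot)
    }
    h_mean <- setNames(cfg$regions$height_mean_cm, cfg$regions$region)
    d_mean <- setNames(cfg$regions$dbh_mean_mm, cfg$regions$region)
    p_surv <- setNames(cfg$regions$survival, cfg$regions$region)
    h <- draw_trait(h_mean, cfg$trait_vc$height)
    d <- draw_trait(d_mean, cfg$trait_vc$dbh)
    surv <- rbinom(nrow(skel), 1L, p_surv[skel$region])

    cored_pick <- skel |>
      group_by(.data$provenance_id, .data$block) |>
      slice_sample(n = 1) |>
      ungroup() |>
      pull(.data$tree_id)

    design <- skel |>
      mutate(height_cm = h$y, dbh_mm = d$y, survival = as.integer(surv),
             cored = .data$tree_id %in% cored_pick) |>
      select("tree_id", "provenance_id", "region", "block", "plot",
             "height_cm", "dbh_mm", "survival", "cored")
    attr(design, "truth") <- list(
      region_height_cm = h_mean, region_dbh_mm = d_mean, region_survival = p_surv,
      height_effects = h[c("prov", "block", "plot")],
      dbh_effects = d[c("prov", "block", "plot")],
      trait_vc = cfg$trait_vc
    )
    design
  })
}

# multiplicative drought factor for one region's resistances across years
drought_multiplier <- function(years, event_years, m_by_event, lag, decay) {
  out <- rep(1, length(years))
  for (i in seq_along(event_years)) {
    k <- years - event_years[i]
    active <- k >= 0 & k <= lag
    out[active] <- out[active] * m_by_event[i]^(decay^k[active])
  }
  out
}

#' Simulate core ring-width series
#'
#' For the cored tree subset (1 tree per provenance per block), ring width in
#' year `t` is
#' `trend(t) * G_region * b_block * u_tree * eps_tree_year * prod_e m_e^(d_e(t))`
#' with `trend(t) = a_mm * exp(-(t - t0)/tau_yr) + c_mm`, lognormal block,
#' tree and tree-year multipliers, and the drought factor decaying
#' geometrically after each event year. Each of the tree's cores observes the
#' tree series through independent lognormal core-year noise, so averaging two
#' cores halves the core-noise variance.
#'
#' @param cfg A [generator_config()].
#' @param design Optional design from [simulate_traits()] (its `cored` trees
#'   are used); generated from `cfg` when omitted.
#' @return A core tibble (`core_id`, `tree_id`, `year`, `width_mm`) with a
#'   `"truth"` attribute holding the age-trend parameters and every region,
#'   block and tree multiplier.
#' @export
simulate_chronologies <- function(cfg, design = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  design <- design %||% simulate_traits(cfg)
  cored <- design |> filter(.data$cored)
  years <- seq(cfg$years[1], cfg$years[2])
  with_seed(sub_seed(cfg$seed, 2L), {
    trend <- cfg$age_trend$a_mm * exp(-(years - cfg$age_trend$t0) / cfg$age_trend$tau_yr) +
      cfg$age_trend$c_mm
    g_region <- setNames(cfg$regions$growth_multiplier, cfg$regions$region)
    blocks <- sort(unique(cored$block))
    b_block <- setNames(rlnorm(length(blocks), 0, cfg$block_sd), as.character(blocks))
    u_tree <- setNames(rlnorm(nrow(cored), 0, cfg$tree_sd), cored$tree_id)

    m_cols <- paste0("resistance_", cfg$drought$event_years)
    m_region <- as.matrix(cfg$regions[, m_cols, drop = FALSE])
    rownames(m_region) <- cfg$regions$region

    cores <- purrr::pmap_dfr(
      cored[, c("tree_id", "region", "block")],
      function(tree_id, region, block) {
        dmult <- drought_multiplier(years, cfg$drought$event_years,
                                    m_region[region, ], cfg$drought$recovery_lag,
                                    cfg$drought$lag_decay)
        tree_series <- trend * g_region[[region]] * b_block[[as.character(block)]] *
          u_tree[[tree_id]] * rlnorm(length(years), 0, cfg$year_sd) * dmult
        purrr::map_dfr(seq_len(cfg$cores_per_tree), function(cc) {
          tibble(
            core_id = paste0(tree_id, LETTERS[cc]),
            tree_id = tree_id,
            year = years,
            width_mm = tree_series * rlnorm(length(years), 0, cfg$core_sd)
          )
        })
      }
    )
    attr(cores, "truth") <- list(
      trend = tibble(year = years, trend_mm = trend),
      region_growth = g_region,
      block_multipliers = b_block,
      tree_multipliers = u_tree,
      resistance = m_region,
      recovery_lag = cfg$drought$recovery_lag,
      lag_decay = cfg$drought$lag_decay
    )
    cores
  })
}

#' Simulate daily weather at the test site
#'
#' Daily mean temperature is a sinusoidal seasonal cycle (peaking in late
#' July) plus normal noise; maxima and minima sit half the diurnal range above
#' and below it. Precipitation is a thinned gamma process (wet days Bernoulli,
#' amounts gamma). Within each configured drought window precipitation is
#' scaled down and temperature shifted up by the configured anomaly, so the
#' injected anomaly mass is known exactly.
#'
#' @param cfg A [generator_config()].
#' @return Daily tibble `date`, `tmin`, `tmax`, `tmean` (C), `precip` (mm)
#'   with a `"truth"` attribute recording the process parameters.
#' @export
simulate_weather <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  w <- cfg$weather
  dates <- seq(as.Date(sprintf("%d-01-01", w$years[1])),
               as.Date(sprintf("%d-12-31", w$years[2])), by = "day")
  with_seed(sub_seed(cfg$seed, 3L), {
    doy <- as.integer(format(dates, "%j"))
    seasonal <- w$tmean_mean + w$tmean_amp * cos(2 * pi * (doy - 205) / 365.25)
    tmean <- seasonal + rnorm(length(dates), 0, w$tmean_sd)
    wet <- rbinom(length(dates), 1L, w$wet_prob)
    amount <- rgamma(length(dates), shape = w$precip_shape,
                     scale = w$precip_mean_mm / w$precip_shape)
    precip <- wet * amount
    anomaly_t <- rep(0, length(dates))
    scale_p <- rep(1, length(dates))
    if (!is.null(w$droughts) && nrow(w$droughts) > 0) {
      for (i in seq_len(nrow(w$droughts))) {
        in_win <- dates >= w$droughts$start[i] & dates <= w$droughts$end[i]
        scale_p[in_win] <- w$droughts$precip_scale[i]
        anomaly_t[in_win] <- w$droughts$temp_anomaly_c[i]
      }
    }
    out <- tibble(
      date = dates,
      tmean = tmean + anomaly_t,
      tmin = tmean + anomaly_t - w$diurnal_range / 2,
      tmax = tmean + anomaly_t + w$diurnal_range / 2,
      precip = precip * scale_p
    ) |>
      select("date", "tmin", "tmax", "tmean", "precip")
    attr(out, "truth") <- list(seasonal_peak_doy = 205, params = w)
    out
  })
}

#' Synthetic provenance climate-normal table
#'
#' Draws, for each provenance, the seven region-characterized normals (MAT,
#' MWMT, MCMT, TD, MAP, MSP, CMD) from the published regional means and
#' between-provenance SDs ([region_climate_normals()]) and fills the remaining
#' six ordination variables (PAS, DD>5, DD<0, FFP, AHM, SHM) with smooth,
#' physically plausible functions of the drawn normals. This is a *synthetic*
#' stand-in for a downscaled climate table — adequate for exercising the PCA
#' and association machinery, not a climatological product.
#'
#' @param cfg A [generator_config()].
#' @return Tibble with `provenance_id`, `region` and 13 climate variables.
#' @export
simulate_provenance_climate <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  normals <- region_climate_normals() |> filter(!is.na(.data$n_provenances))
  provs <- design_skeleton(cfg) |> distinct(.data$provenance_id, .data$region)
  missing <- setdiff(provs$region, normals$location)
  if (length(missing) > 0) {
    abort(sprintf("No climate normals for region(s): %s.", paste(missing, collapse = ", ")))
  }
  with_seed(sub_seed(cfg$seed, 4L), {
    n <- normals[match(provs$region, normals$location), ]
    draw <- function(mean, sd) rnorm(nrow(provs), mean, sd)
    mat <- draw(n$mat_c, n$mat_sd)
    mwmt <- draw(n$mwmt_c, n$mwmt_sd)
    mcmt <- pmin(draw(n$mcmt_c, n$mcmt_sd), mwmt - 5)
    map <- pmax(draw(n$map_mm, n$map_sd), 150)
    msp <- pmin(pmax(draw(n$msp_mm, n$msp_sd), 80), map)
    cmd <- pmax(draw(n$cmd_mm, n$cmd_sd), 0)
    tibble(
      provenance_id = provs$provenance_id,
      region = provs$region,
      mat = mat, mwmt = mwmt, mcmt = mcmt, td = mwmt - mcmt,
      map = map, msp = msp,
      pas = map * pmin(0.6, pmax(0.1, 0.22 - 0.012 * mcmt)) *
        rlnorm(nrow(provs), 0, 0.05),
      dd5 = pmax(50, 1500 + 120 * mat + rnorm(nrow(provs), 0, 50)),
      dd0 = pmax(0, 250 - 95 * mcmt + rnorm(nrow(provs), 0, 50)),
      ffp = pmax(30, 105 + 6 * mat + rnorm(nrow(provs), 0, 5)),
      ahm = (mat + 10) / (map / 1000),
      shm = mwmt / (msp / 1000),
      cmd = cmd
    )
  })
}

#' Extract a generator's truth record
#'
#' @param x An object returned by a `simulate_*` function.
#' @return The `"truth"` attribute (a list), or an error if absent.
#' @export
generator_truth <- function(x) {
  truth <- attr(x, "truth", exact = TRUE)
  if (is.null(truth)) abort("`x` carries no truth record.")
  truth
}
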