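#' Provenance-level trait means
#'
#' Aggregates the design table (and optionally the per-tree drought indices)
#' to one row per provenance: mean height, DBH and survival rate, plus the
#' mean of every index column present in `resilience`. These provenance means
#' are the trait side of the trait-climate association screen.
#'
#' @param design Trial design tibble with measurements.
#' @param resilience Optional per-tree index tibble from [compute_resilience()].
#' @return Tibble with one row per provenance.
#' @export
provenance_trait_means <- function(design, resilience = NULL) {
  check_columns(design, c("tree_id", "provenance_id", "height_cm", "dbh_mm", "survival"),
                "design")
  out <- design |>
    group_by(.data$provenance_id) |>
    summarise(
      height_cm = mean(.data$height_cm, na.rm = TRUE),
      dbh_mm = mean(.data$dbh_mm, na.rm = TRUE),
      survival = mean(.data$survival, na.rm = TRUE),
      .groups = "drop"
    )
  if (!is.null(resilience)) {
    check_columns(resilience, c("tree_id", "provenance_id"), "resilience")
    idx <- c(grep("^(resistance|recovery)_", names(resilience), value = TRUE),
             intersect("resilience", names(resilience)))
    res_means <- resilience |>
      group_by(.data$provenance_id) |>
      summarise(dplyr::across(dplyr::all_of(idx), mean), .groups = "drop")
    out <- out |> left_join(res_means, by = "provenance_id")
  }
  out
}

#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()]. With
#' `simulate = TRUE` (the default when no input paths are given) all inputs
#' are generated by the synthetic module from `seed`; otherwise `rings`
#' (RWL or long CSV, chosen by extension), `design`, `weather` and
#' `climate_normals` paths are read. A configuration can also be written
#' to / read from YAML with [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param rings,design,weather,climate_normals Input file paths (or `NULL`).
#' @param simulate Generate all inputs synthetically from `seed`.
#' @param seed Integer seed for the synthetic generator and manifest.
#' @param window Analysis window, calendar years.
#' @param stiffness Common-spline smoothing parameter in (0, 1].
#' @param events,pre_window,post_window Drought [event_scheme()] components.
#' @param latitude Site latitude (degrees) for the Hargreaves computation.
#' @param holm_family `"matrix"` or `"per_trait"` (see [spearman_holm()]).
#' @param out_dir Output directory; created if missing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rings = NULL, design = NULL, weather = NULL,
                            climate_normals = NULL,
                            simulate = is.null(rings) && is.null(design),
                            seed = 1L,
                            window = c(1988L, 2017L),
                            stiffness = 0.7,
                            events = c(1999L, 2002L),
                            pre_window = c(1993L, 1997L),
                            post_window = c(2003L, 2007L),
                            latitude = 55.28,
                            holm_family = "matrix",
                            out_dir = tempfile("gardenring-run-")) {
  if (stiffness <= 0 || stiffness > 1) abort("`stiffness` must be in (0, 1].")
  if (!simulate) {
    for (p in c(rings = rings, design = design)) {
      if (is.null(p)) abort("Without `simulate`, `rings` and `design` paths are required.")
    }
    for (p in c(rings, design, weather, climate_normals)) {
      if (!is.null(p) && !file.exists(p)) abort(sprintf("Input file not found: '%s'.", p))
    }
  }
  structure(
    list(rings = rings, design = design, weather = weather,
         climate_normals = climate_normals, simulate = simulate,
         seed = as.integer(seed), window = check_window(window),
         stiffness = stiffness,
         scheme = event_scheme(events, pre_window, post_window),
         latitude = latitude, holm_family = holm_family, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: '%s'.", path))
  y <- yaml::read_yaml(path)
  pipeline_config(
    rings = y$rings, design = y$design, weather = y$weather,
    climate_normals = y$climate_normals,
    simulate = y$simulate %||% (is.null(y$rings) && is.null(y$design)),
    seed = y$seed %||% 1L,
    window = unlist(y$window %||% c(1988L, 2017L)),
    stiffness = y$stiffness %||% 0.7,
    events = unlist(y$events %||% c(1999L, 2002L)),
    pre_window = unlist(y$pre_window %||% c(1993L, 1997L)),
    post_window = unlist(y$post_window %||% c(2003L, 2007L)),
    latitude = y$latitude %||% 55.28,
    holm_family = y$holm_family %||% "matrix",
    out_dir = y$out_dir %||% tempfile("gardenring-run-")
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- list(
    rings = config$rings, design = config$design, weather = config$weather,
    climate_normals = config$climate_normals, simulate = config$simulate,
    seed = config$seed, window = as.list(config$window),
    stiffness = config$stiffness,
    events = as.list(config$scheme$event_years),
    pre_window = as.list(config$scheme$pre_window),
    post_window = as.list(config$scheme$post_window),
    latitude = config$latitude, holm_family = config$holm_family,
    out_dir = config$out_dir
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — data input (or synthesis), per-tree
#' chronology assembly, cross-dating statistics, common-spline detrending with
#' reversed standardization, Lloret indices with regional mixed-model tables,
#' daily water deficit / annual CMD and deficit anomaly integrals, regional
#' BLUEs for height and DBH, the survival GLMM, the Spearman/Holm
#' trait-climate screen, and the climate PCA — writing every tabular output
#' as CSV plus a JSON summary and a reproducibility manifest (resolved config,
#' its MD5 hash, package version, seed) into `config$out_dir`. Stage failures
#' propagate with the stage name prefixed.
#'
#' @param config A [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return Invisibly, a named list with every intermediate and final object.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  log_msg <- function(...) message(sprintf(...))

  # --- input -----------------------------------------------------------
  truth <- NULL
  if (config$simulate) {
    cfg <- generator_config(seed = config$seed, years = config$window)
    design <- stage("simulate", simulate_traits(cfg))
    rings <- stage("simulate", simulate_chronologies(cfg, design))
    weather <- stage("simulate", simulate_weather(cfg))
    climate <- stage("simulate", simulate_provenance_climate(cfg))
    truth <- list(design = generator_truth(design), rings = generator_truth(rings))
    log_msg("simulate: %d cores / %d trees, %d weather days, %d provenances",
            dplyr::n_distinct(rings$core_id), dplyr::n_distinct(rings$tree_id),
            nrow(weather), nrow(climate))
  } else {
    rings <- stage("ringio", {
      if (grepl("\\.rwl$", config$rings, ignore.case = TRUE)) read_rwl(config$rings)
      else read_rings_csv(config$rings)
    })
    design <- stage("ringio", read_design_csv(config$design))
    weather <- if (!is.null(config$weather)) {
      stage("climate", {
        w <- readr::read_csv(config$weather, show_col_types = FALSE)
        check_columns(w, c("date", "tmin", "tmax", "tmean", "precip"), "weather csv")
        w
      })
    }
    climate <- if (!is.null(config$climate_normals)) {
      stage("climate", readr::read_csv(config$climate_normals, show_col_types = FALSE))
    }
    log_msg("ringio: %d cores / %d trees read", dplyr::n_distinct(rings$core_id),
            dplyr::n_distinct(rings$tree_id))
  }

  # --- chronology ------------------------------------------------------
  chronos <- stage("chronology", build_tree_chronologies(rings, design, config$window))
  crossdating <- stage("crossdate", interseries_correlations(chronos))
  detrended <- stage("detrend", detrend_chronologies(chronos, config$stiffness))
  log_msg("chronology: %d trees, EPS = %.3f", dplyr::n_distinct(chronos$tree_id),
          crossdating$eps)
  readr::write_csv(tidy(crossdating), file.path(config$out_dir, "crossdating_trees.csv"))
  jsonlite::write_json(as.list(glance(crossdating)),
                       file.path(config$out_dir, "crossdating_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(detrended, file.path(config$out_dir, "detrended_chronologies.csv"))

  # --- resilience ------------------------------------------------------
  res_trees <- stage("resilience", compute_resilience(detrended, config$scheme))
  res_regional <- stage("resilience", regional_resilience_table(res_trees))
  readr::write_csv(res_trees, file.path(config$out_dir, "resilience_trees.csv"))
  readr::write_csv(res_regional, file.path(config$out_dir, "resilience_regional.csv"))

  # --- climate ---------------------------------------------------------
  deficits <- cmd <- deficit_anomalies <- anomaly_integrals <- NULL
  if (!is.null(weather)) {
    deficits <- stage("deficit", daily_deficit(weather, config$latitude))
    cmd <- stage("deficit", annual_cmd(deficits))
    clim <- stage("deficit", daily_climatology(deficits, "deficit_mm"))
    deficit_anomalies <- stage("deficit", anomaly_series(deficits, clim, "deficit_mm"))
    anomaly_integrals <- purrr::map_dfr(config$scheme$event_years, function(e) {
      anomaly_integral(deficit_anomalies,
                       sprintf("%d-04-01", e), sprintf("%d-09-30", e)) |>
        mutate(event_year = e, .before = 1)
    })
    readr::write_csv(deficits, file.path(config$out_dir, "deficit_daily.csv"))
    readr::write_csv(cmd, file.path(config$out_dir, "annual_cmd.csv"))
    readr::write_csv(anomaly_integrals, file.path(config$out_dir, "anomaly_integrals.csv"))
  }

  # --- inference -------------------------------------------------------
  blues_height <- stage("blues", fit_lmm_blues(design, "height_cm", preset = "growth"))
  blues_dbh <- stage("blues", fit_lmm_blues(design, "dbh_mm", preset = "growth"))
  surv <- stage("blues", fit_glmm_survival(design))
  region_estimates <- dplyr::bind_rows(
    tidy(blues_height) |> mutate(trait = "height_cm", .before = 1),
    tidy(blues_dbh) |> mutate(trait = "dbh_mm", .before = 1),
    tidy(surv) |> select(-dplyr::any_of("separation")) |>
      mutate(trait = "survival", .before = 1)
  )
  readr::write_csv(region_estimates, file.path(config$out_dir, "region_estimates.csv"))

  associations <- pca <- NULL
  if (!is.null(climate)) {
    traits <- provenance_trait_means(design, res_trees)
    associations <- stage("associate",
      spearman_holm(traits, climate |> select(-dplyr::any_of("region")),
                    family = config$holm_family))
    pca <- stage("pca", climate_pca(climate |> select(-dplyr::any_of("region"))))
    readr::write_csv(tidy(associations), file.path(config$out_dir, "associations.csv"))
    readr::write_csv(augment(pca), file.path(config$out_dir, "pca_scores.csv"))
    readr::write_csv(tidy(pca), file.path(config$out_dir, "pca_loadings.csv"))
    readr::write_csv(glance(pca), file.path(config$out_dir, "pca_variance.csv"))
  }

  # --- manifest --------------------------------------------------------
  cfg_path <- file.path(config$out_dir, "resolved_config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    package = "gardenring",
    version = as.character(utils::packageVersion("gardenring")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_trees = dplyr::n_distinct(chronos$tree_id),
    n_cores = dplyr::n_distinct(rings$core_id),
    eps = crossdating$eps
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    config = config, rings = rings, design = design, weather = weather,
    climate = climate, chronos = chronos, crossdating = crossdating,
    detrended = detrended, resilience = res_trees,
    resilience_regional = res_regional, deficits = deficits, cmd = cmd,
    anomaly_integrals = anomaly_integrals, blues_height = blues_height,
    blues_dbh = blues_dbh, survival = surv, associations = associations,
    pca = pca, truth = truth, manifest = manifest
  ))
}
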