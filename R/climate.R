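#' Extraterrestrial radiation (Ra) in water-equivalent mm/day
#'
#' Standard clear-sky solar geometry: inverse relative Earth-Sun distance
#' `dr = 1 + 0.033 cos(2 pi J / 365)`, solar declination
#' `delta = 0.409 sin(2 pi J / 365 - 1.39)`, sunset hour angle
#' `ws = acos(-tan(phi) tan(delta))` (argument clamped to \[-1, 1\] so polar
#' day/night degrade gracefully to ws = pi or 0), and
#' `Ra = (24*60/pi) * Gsc * dr * (ws sin(phi) sin(delta) + cos(phi) cos(delta) sin(ws))`
#' with solar constant `Gsc = 0.0820` MJ m^-2 min^-1. The MJ m^-2 day^-1
#' result is converted to evaporation-equivalent depth with the factor 0.408.
#'
#' @param doy Day of year, 1-366 (vectorized).
#' @param latitude Site latitude in decimal degrees (north positive).
#' @return Ra in mm/day.
#' @export
extraterrestrial_radiation <- function(doy, latitude) {
  if (any(doy < 1 | doy > 366)) abort("`doy` must be in 1..366.")
  if (abs(latitude) > 90) abort("`latitude` must be in [-90, 90] degrees.")
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  ra_mj <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  0.408 * pmax(ra_mj, 0)
}

#' Hargreaves reference evapotranspiration
#'
#' Temperature-and-radiation based daily reference evapotranspiration:
#' \deqn{ET_0 = 0.0023 \, R_a \, (T_{mean} + 17.8) \sqrt{T_{max} - T_{min}}}
#' with `Ra` from [extraterrestrial_radiation()] in mm/day. Negative values
#' (possible for `Tmean < -17.8` degrees C) are clamped to zero, as is the
#' zero-diurnal-range case. Days with a missing temperature get `NA` and are
#' counted in a warning.
#'
#' @param weather Daily weather tibble with columns `date` (Date), `tmin`,
#'   `tmax`, `tmean` (degrees C).
#' @param latitude Site latitude, decimal degrees.
#' @return The input tibble with an `et0_mm` column added.
#' @export
hargreaves_et0 <- function(weather, latitude) {
  check_columns(weather, c("date", "tmin", "tmax", "tmean"), "weather")
  bad_range <- !is.na(weather$tmax) & !is.na(weather$tmin) & weather$tmax < weather$tmin
  if (any(bad_range)) {
    abort(sprintf("tmax < tmin on %d day(s), first on %s.",
                  sum(bad_range), format(weather$date[bad_range][1])))
  }
  doy <- as.integer(format(as.Date(weather$date), "%j"))
  ra <- extraterrestrial_radiation(doy, latitude)
  et0 <- 0.0023 * ra * (weather$tmean + 17.8) * sqrt(pmax(weather$tmax - weather$tmin, 0))
  et0 <- pmax(et0, 0)
  n_missing <- sum(is.na(et0))
  if (n_missing > 0) {
    warn(sprintf("ET0 undefined on %d day(s) with missing temperature; set to NA.", n_missing))
  }
  weather |> mutate(et0_mm = et0)
}

#' Daily water deficit and annual climatic moisture deficit (CMD)
#'
#' The daily deficit is the unmet atmospheric demand
#' `max(0, ET0 - precipitation)`; the annual CMD is its calendar-year sum.
#' Days with missing temperature or precipitation are excluded from the sum
#' and reported per year, without imputation.
#'
#' @param weather Daily weather tibble (`date`, `tmin`, `tmax`, `tmean`,
#'   `precip` in mm/day).
#' @param latitude Site latitude, decimal degrees.
#' @return The input tibble with `et0_mm` and `deficit_mm` columns.
#' @export
daily_deficit <- function(weather, latitude) {
  check_columns(weather, c("date", "tmin", "tmax", "tmean", "precip"), "weather")
  if (any(weather$precip < 0, na.rm = TRUE)) abort("`precip` must be non-negative.")
  suppressWarnings(hargreaves_et0(weather, latitude)) |>
    mutate(deficit_mm = pmax(0, .data$et0_mm - .data$precip))
}

#' @rdname daily_deficit
#' @param deficits Output of `daily_deficit()`.
#' @return `annual_cmd()`: a tibble per calendar year with `cmd_mm`,
#'   `n_days` (days contributing) and `n_missing`.
#' @export
annual_cmd <- function(deficits) {
  check_columns(deficits, c("date", "deficit_mm"), "deficits")
  deficits |>
    mutate(year = as.integer(format(as.Date(.data$date), "%Y"))) |>
    group_by(.data$year) |>
    summarise(
      cmd_mm = sum(.data$deficit_mm, na.rm = TRUE),
      n_days = sum(!is.na(.data$deficit_mm)),
      n_missing = sum(is.na(.data$deficit_mm)),
      .groups = "drop"
    )
}

#' Day-of-year climatology over a reference period
#'
#' Computes day-of-year means of a daily variable over a reference period and
#' smooths them with a circular running mean (default 15 days) so that anomaly
#' baselines are not dominated by single-year noise.
#'
#' @param weather Daily tibble with `date` and the variable column.
#' @param var Variable column name.
#' @param reference_years `c(first, last)` calendar years of the normal
#'   period; default uses all years present.
#' @param smooth_window Width (days, odd) of the circular running mean.
#' @return Tibble `doy`, `normal` for days 1-366.
#' @export
daily_climatology <- function(weather, var, reference_years = NULL, smooth_window = 15L) {
  check_columns(weather, c("date", var), "weather")
  if (smooth_window %% 2 != 1) abort("`smooth_window` must be odd.")
  d <- weather |>
    mutate(year = as.integer(format(as.Date(.data$date), "%Y")),
           doy = as.integer(format(as.Date(.data$date), "%j")))
  if (!is.null(reference_years)) {
    reference_years <- check_window(reference_years, "reference_years")
    d <- d |> filter(.data$year >= reference_years[1], .data$year <= reference_years[2])
  }
  if (nrow(d) == 0) abort("No days in the reference period.")
  clim <- d |>
    group_by(.data$doy) |>
    summarise(normal = mean(.data[[var]], na.rm = TRUE), .groups = "drop")
  full <- tibble(doy = 1:366) |>
    left_join(clim, by = "doy") |>
    # day 366 is rarely observed: borrow day 365 before smoothing
    mutate(normal = ifelse(.data$doy == 366L & !is.finite(.data$normal),
                           .data$normal[365], .data$normal))
  half <- (smooth_window - 1L) %/% 2L
  x <- full$normal
  n <- length(x)
  sm <- vapply(seq_len(n), function(i) {
    idx <- ((i - half - 1L):(i + half - 1L)) %% n + 1L
    mean(x[idx], na.rm = TRUE)
  }, numeric(1))
  tibble(doy = 1:366, normal = sm)
}

#' Daily anomalies against a climatology
#'
#' @param weather Daily tibble with `date` and the variable column.
#' @param climatology Tibble `doy`, `normal` from [daily_climatology()].
#' @param var Variable column name.
#' @return The input with `normal` and `anomaly = value - normal` columns.
#' @export
anomaly_series <- function(weather, climatology, var) {
  check_columns(weather, c("date", var), "weather")
  check_columns(climatology, c("doy", "normal"), "climatology")
  doy <- as.integer(format(as.Date(weather$date), "%j"))
  idx <- match(doy, climatology$doy)
  if (anyNA(idx) || anyNA(climatology$normal[idx])) {
    abort("Climatology does not cover all days of year present.")
  }
  weather |>
    mutate(normal = climatology$normal[idx],
           anomaly = .data[[var]] - .data$normal)
}

#' Windowed anomaly integral
#'
#' Sums signed daily anomalies over a date window: the "area between the curve
#' and its climatology" that summarizes both the size and the duration of an
#' extreme event (for deficit anomalies, positive = drier than normal).
#' Missing days are dropped from the sum; the completeness fraction of the
#' window is reported alongside so sparsely observed windows are visible.
#'
#' @param anomalies Tibble with `date` and `anomaly` (see [anomaly_series()]).
#' @param from,to Window bounds (inclusive), coerced with [as.Date()].
#' @return One-row tibble: `from`, `to`, `integral`, `n_days`, `completeness`.
#' @export
anomaly_integral <- function(anomalies, from, to) {
  check_columns(anomalies, c("date", "anomaly"), "anomalies")
  from <- as.Date(from); to <- as.Date(to)
  if (from > to) abort("`from` must be <= `to`.")
  w <- anomalies |> filter(as.Date(.data$date) >= from, as.Date(.data$date) <= to)
  n_window <- as.integer(to - from) + 1L
  tibble(
    from = from, to = to,
    integral = sum(w$anomaly, na.rm = TRUE),
    n_days = sum(!is.na(w$anomaly)),
    completeness = sum(!is.na(w$anomaly)) / n_window
  )
}

#' Bioclimatic variables derivable from monthly normals
#'
#' From 12 monthly mean temperatures and precipitation sums computes the
#' annual summaries used to characterize provenance origin climates:
#' mean annual temperature (MAT, degrees C), warmest/coldest month mean
#' (MWMT/MCMT), continentality (TD = MWMT - MCMT), annual and May-September
#' growing-season precipitation (MAP/MSP, mm), and the annual and summer
#' heat-moisture indices `AHM = (MAT + 10) / (MAP / 1000)` and
#' `SHM = MWMT / (MSP / 1000)`. Variables that need daily downscaling
#' (degree-days, frost-free period, snow fraction, CMD normals) are not
#' computed here; they come with the provenance climate input table.
#'
#' @param monthly Tibble with columns `month` (1-12), `tmean_c`, `precip_mm`,
#'   and optionally id columns (e.g. `provenance_id`) to group by.
#' @return One row per group: `mat_c`, `mwmt_c`, `mcmt_c`, `td_c`, `map_mm`,
#'   `msp_mm`, `ahm`, `shm`.
#' @export
derived_normals <- function(monthly) {
  check_columns(monthly, c("month", "tmean_c", "precip_mm"), "monthly")
  id_cols <- setdiff(names(monthly), c("month", "tmean_c", "precip_mm"))
  grouped <- monthly |> group_by(dplyr::pick(dplyr::all_of(id_cols)))
  sizes <- grouped |> summarise(n = dplyr::n_distinct(.data$month), .groups = "drop")
  if (any(sizes$n != 12) || any(!monthly$month %in% 1:12)) {
    abort("Each group needs exactly the 12 months 1..12.")
  }
  grouped |>
    summarise(
      mat_c = mean(.data$tmean_c),
      mwmt_c = max(.data$tmean_c),
      mcmt_c = min(.data$tmean_c),
      td_c = max(.data$tmean_c) - min(.data$tmean_c),
      map_mm = sum(.data$precip_mm),
      msp_mm = sum(.data$precip_mm[.data$month %in% 5:9]),
      .groups = "drop"
    ) |>
    mutate(
      ahm = (.data$mat_c + 10) / (.data$map_mm / 1000),
      shm = .data$mwmt_c / (.data$msp_mm / 1000)
    )
}
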