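#' Expressed population signal (EPS)
#'
#' EPS quantifies how well the mean of `n` tree chronologies, each carrying a
#' common signal of strength `r_bar` (the mean interseries correlation),
#' represents the hypothetical population chronology:
#' \deqn{EPS = \frac{n \bar r}{n \bar r + (1 - \bar r)}}
#' EPS lies in \[0, 1\] for `r_bar` in \[0, 1\], increases in both arguments,
#' and tends to 1 as `n` grows for any positive `r_bar`. An EPS of 0.85 is the
#' conventional adequacy threshold for natural-stand chronologies; common
#' gardens, where the environment is experimentally shared, can reach far
#' higher values.
#'
#' @param n Number of series (vectorized).
#' @param r_bar Mean interseries correlation (vectorized).
#' @return EPS, a numeric vector.
#' @export
eps_wigley <- function(n, r_bar) {
  if (any(n < 1)) abort("`n` must be >= 1.")
  n * r_bar / (n * r_bar + (1 - r_bar))
}

#' Cross-dating statistics: interseries correlations and EPS
#'
#' Each tree's chronology is correlated (Pearson) with the mean chronology of
#' all *other* trees over their common years; the mean of these leave-one-out
#' correlations is the mean interseries correlation, from which the expressed
#' population signal follows via [eps_wigley()]. This is the validation
#' statistic used to judge cross-dating quality after ring measurement.
#'
#' @param chronos Chronology tibble from [build_tree_chronologies()] (columns
#'   `tree_id`, `year`, and the value column).
#' @param value Name of the value column to correlate (default `"width_mm"`;
#'   `"detrended_mm"` gives post-detrending statistics).
#' @param min_overlap Minimum number of common years required for a tree's
#'   correlation (default 5).
#' @return An object of class `crossdating_report`; see [tidy.crossdating_report()]
#'   for the per-tree table and [glance.crossdating_report()] for the
#'   `n_series`/`r_bar`/`eps` summary.
#' @export
interseries_correlations <- function(chronos, value = "width_mm", min_overlap = 5L) {
  check_columns(chronos, c("tree_id", "year", value), "chronos")
  wide <- chronos |>
    select("tree_id", "year", value = dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "tree_id", values_from = "value") |>
    arrange(.data$year)
  m <- as.matrix(wide[, -1, drop = FALSE])
  ids <- colnames(m)
  n <- length(ids)
  if (n < 3) abort("Interseries correlations need at least 3 trees.")

  r <- vapply(seq_len(n), function(j) {
    others <- rowMeans(m[, -j, drop = FALSE], na.rm = TRUE)
    ok <- is.finite(m[, j]) & is.finite(others)
    if (sum(ok) < min_overlap) return(NA_real_)
    if (sd(m[ok, j]) == 0 || sd(others[ok]) == 0) return(NA_real_)
    cor(m[ok, j], others[ok])
  }, numeric(1))
  n_overlap <- vapply(seq_len(n), function(j) {
    others <- rowMeans(m[, -j, drop = FALSE], na.rm = TRUE)
    sum(is.finite(m[, j]) & is.finite(others))
  }, integer(1))

  if (max(n_overlap) < min_overlap) {
    abort(sprintf("Fewer than %d overlapping years across series.", min_overlap))
  }
  if (anyNA(r)) {
    warn(sprintf(
      "Interseries correlation undefined for %d tree(s) (zero variance or short overlap); excluded from r_bar: %s.",
      sum(is.na(r)), paste(ids[is.na(r)], collapse = ", ")
    ))
  }
  r_bar <- mean(r, na.rm = TRUE)
  structure(
    list(
      trees = tibble(tree_id = ids, r = r, n_overlap = n_overlap),
      n_series = sum(!is.na(r)),
      r_bar = r_bar,
      eps = eps_wigley(sum(!is.na(r)), r_bar),
      value = value
    ),
    class = "crossdating_report"
  )
}

#' @export
print.crossdating_report <- function(x, ...) {
  cat(sprintf("Cross-dating report (%s): n = %d, mean interseries r = %.3f, EPS = %.3f\n",
              x$value, x$n_series, x$r_bar, x$eps))
  invisible(x)
}

#' Tidiers for cross-dating reports
#'
#' @param x A `crossdating_report`.
#' @param ... Unused.
#' @return `tidy()`: one row per tree (`tree_id`, `r`, `n_overlap`);
#'   `glance()`: one row with `n_series`, `r_bar`, `eps`.
#' @method tidy crossdating_report
#' @export
tidy.crossdating_report <- function(x, ...) x$trees

#' @rdname tidy.crossdating_report
#' @method glance crossdating_report
#' @export
glance.crossdating_report <- function(x, ...) {
  tibble(n_series = x$n_series, r_bar = x$r_bar, eps = x$eps)
}

#' Normalize chronologies to per-tree z-scores
#'
#' Each tree's series is centred and scaled by its own window mean and sample
#' standard deviation (n - 1 denominator): `z = (width - mean) / sd`. The
#' anchors `raw_mean_mm` / `raw_sd_mm` stay in the table so the
#' standardization can be reversed exactly after detrending.
#'
#' @param chronos Chronology tibble from [build_tree_chronologies()]. If the
#'   `raw_mean_mm`/`raw_sd_mm` columns are absent they are computed over the
#'   rows present.
#' @return The input tibble with a `z` column added.
#' @export
normalize_chronologies <- function(chronos) {
  check_columns(chronos, c("tree_id", "year", "width_mm"), "chronos")
  if (!all(c("raw_mean_mm", "raw_sd_mm") %in% names(chronos))) {
    chronos <- chronos |>
      group_by(.data$tree_id) |>
      mutate(raw_mean_mm = mean(.data$width_mm), raw_sd_mm = sd(.data$width_mm)) |>
      ungroup()
  }
  bad <- chronos |>
    distinct(.data$tree_id, .data$raw_sd_mm) |>
    filter(!is.finite(.data$raw_sd_mm) | .data$raw_sd_mm <= 0)
  if (nrow(bad) > 0) {
    abort(sprintf("Cannot normalize zero-variance chronolog%s: %s.",
                  if (nrow(bad) > 1) "ies" else "y",
                  paste(sort(bad$tree_id), collapse = ", ")))
  }
  chronos |> mutate(z = (.data$width_mm - .data$raw_mean_mm) / .data$raw_sd_mm)
}

#' Fit the common age-trend spline to pooled normalized chronologies
#'
#' A single cubic smoothing spline is fitted to *all* (year, z) points of all
#' trees pooled together, so the estimated age trend has the same shape for
#' every tree. This matters in a common garden: detrending each tree with its
#' own spline would absorb part of the genetic growth differences between
#' populations, which are exactly the quantity under study. The `stiffness`
#' is the dimensionless smoothing parameter `spar` of [stats::smooth.spline()],
#' mapped to the roughness penalty via `lambda = r * 256^(3*spar - 1)`; the
#' default 0.7 gives a stiff spline that tracks the age-related decline but
#' not year-to-year climate variation.
#'
#' @param chronos Normalized chronology tibble (needs `year` and `z`; see
#'   [normalize_chronologies()]).
#' @param stiffness Smoothing parameter in (0, 1]; default 0.7.
#' @return An object of class `common_spline` with the fitted
#'   [stats::smooth.spline] object, the stiffness, and the year support.
#' @export
fit_common_spline <- function(chronos, stiffness = 0.7) {
  check_columns(chronos, c("year", "z"), "chronos")
  if (length(stiffness) != 1 || !is.finite(stiffness) || stiffness <= 0 || stiffness > 1) {
    abort("`stiffness` must be a single value in (0, 1].")
  }
  pts <- chronos |> filter(is.finite(.data$z))
  if (length(unique(pts$year)) < 4) {
    abort("Common spline needs at least 4 distinct years.")
  }
  fit <- smooth.spline(pts$year, pts$z, spar = stiffness, cv = FALSE)
  structure(
    list(
      fit = fit,
      stiffness = stiffness,
      years = range(pts$year),
      n_points = nrow(pts),
      fitted = tibble(year = sort(unique(pts$year)),
                      f = predict(fit, sort(unique(pts$year)))$y)
    ),
    class = "common_spline"
  )
}

#' @export
print.common_spline <- function(x, ...) {
  cat(sprintf("Common detrending spline: stiffness %.2f, %d pooled points, years %d-%d\n",
              x$stiffness, x$n_points, x$years[1], x$years[2]))
  invisible(x)
}

#' Evaluate a common spline at given years
#'
#' @param object A `common_spline`.
#' @param years Calendar years inside the fitted support.
#' @param ... Unused.
#' @return Numeric vector of spline values (z units).
#' @export
predict.common_spline <- function(object, years, ...) {
  outside <- years < object$years[1] | years > object$years[2]
  if (any(outside)) {
    abort(sprintf("Years outside spline support %d-%d: %s.",
                  object$years[1], object$years[2],
                  paste(unique(years[outside]), collapse = ", ")))
  }
  predict(object$fit, as.numeric(years))$y
}

#' Detrend with reversed standardization
#'
#' Removes the common spline from each tree's z-scores and then *reverses* the
#' standardization with that tree's own mean and standard deviation:
#' `detrended = (z - f(year)) * raw_sd + raw_mean`. The result is in
#' millimetres and keeps absolute, between-tree level differences — in a
#' same-age common garden the absolute growth value carries the population
#' signal, so the conventional unit-variance index chronology is deliberately
#' not used. The operation is exactly invertible given the spline and the
#' stored per-tree anchors.
#'
#' @param chronos Normalized chronology tibble (see [normalize_chronologies()]).
#' @param spline A `common_spline` from [fit_common_spline()].
#' @return The input tibble with a `detrended_mm` column added.
#' @export
detrend_reverse <- function(chronos, spline) {
  check_columns(chronos, c("year", "z", "raw_mean_mm", "raw_sd_mm"), "chronos")
  if (!inherits(spline, "common_spline")) abort("`spline` must be a `common_spline`.")
  f <- predict(spline, chronos$year)
  chronos |> mutate(detrended_mm = (.data$z - f) * .data$raw_sd_mm + .data$raw_mean_mm)
}

#' One-step detrending: normalize, fit the common spline, reverse
#'
#' Convenience wrapper chaining [normalize_chronologies()],
#' [fit_common_spline()] and [detrend_reverse()]. The fitted spline is
#' attached as the `"common_spline"` attribute of the result.
#'
#' @inheritParams normalize_chronologies
#' @inheritParams fit_common_spline
#' @return The chronology tibble with `z` and `detrended_mm` columns; the
#'   fitted `common_spline` in `attr(, "common_spline")`.
#' @export
detrend_chronologies <- function(chronos, stiffness = 0.7) {
  normed <- normalize_chronologies(chronos)
  spline <- fit_common_spline(normed, stiffness = stiffness)
  out <- detrend_reverse(normed, spline)
  attr(out, "common_spline") <- spline
  out
}
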