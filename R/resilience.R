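#' Define drought events and shared reference windows
#'
#' The Lloret indices compare growth in a drought year against reference
#' periods before and after the disturbance. When two droughts fall close
#' together — at Calling Lake, 1999 and 2002, too close for growth to recover
#' in between — a *shared* pre-disturbance window before the first event and a
#' shared post-disturbance window after the second event are used for both, so
#' the second event's baseline is not contaminated by the first event's
#' after-effect. Defaults follow that design: events 1999 and 2002, reference
#' windows 1993-1997 and 2003-2007.
#'
#' @param event_years Calendar years of the drought events.
#' @param pre_window Inclusive pre-disturbance reference window, `c(first, last)`;
#'   must end before the first event.
#' @param post_window Inclusive post-disturbance window; must start after the
#'   last event.
#' @return An `event_scheme` list.
#' @export
event_scheme <- function(event_years = c(1999L, 2002L),
                         pre_window = c(1993L, 1997L),
                         post_window = c(2003L, 2007L)) {
  event_years <- sort(as.integer(event_years))
  pre_window <- check_window(pre_window, "pre_window")
  post_window <- check_window(post_window, "post_window")
  if (length(event_years) < 1) abort("At least one event year is required.")
  if (pre_window[2] >= min(event_years)) {
    abort("`pre_window` must end before the first event year.")
  }
  if (post_window[1] <= max(event_years)) {
    abort("`post_window` must start after the last event year.")
  }
  structure(
    list(event_years = event_years, pre_window = pre_window, post_window = post_window),
    class = "event_scheme"
  )
}

#' @export
print.event_scheme <- function(x, ...) {
  cat(sprintf("Drought events %s; pre %d-%d, post %d-%d\n",
              paste(x$event_years, collapse = ", "),
              x$pre_window[1], x$pre_window[2], x$post_window[1], x$post_window[2]))
  invisible(x)
}

#' Lloret drought indices per tree
#'
#' For each tree, with `preD` and `postD` the arithmetic means of detrended
#' growth (mm) over the shared reference windows and `D_e` the detrended
#' growth in event year `e`:
#' * resistance `Rt_e = D_e / preD` — the fraction of pre-drought growth
#'   maintained during the event (1 = no loss);
#' * recovery `Rc_e = postD / D_e` — the rebound after the event;
#' * resilience `Rs = postD / preD` — one overall index, shared across events
#'   because the windows are shared; by construction `Rs = Rt_e * Rc_e` for
#'   every event.
#'
#' Indices are ratios of positive growth, so a tree with non-positive mean
#' pre-disturbance growth or non-positive event-year growth is an error
#' (`floor` substitutes a small positive value instead, off by default).
#'
#' @param chronos Detrended chronology tibble (needs `tree_id`, `year`, and
#'   the `value` column; typically from [detrend_chronologies()]).
#' @param scheme An [event_scheme()].
#' @param value Column holding growth in mm (default `"detrended_mm"`).
#' @param floor Optional small positive growth floor (mm) substituted for
#'   non-positive event-year or window means; `NULL` (default) errors instead.
#' @return A tibble, one row per tree: any design columns present
#'   (`provenance_id`, `region`, `block`), `pre_mm`, `post_mm`, per-event
#'   `d_<year>`, `resistance_<year>`, `recovery_<year>`, and `resilience`.
#' @export
compute_resilience <- function(chronos, scheme = event_scheme(),
                               value = "detrended_mm", floor = NULL) {
  check_columns(chronos, c("tree_id", "year", value), "chronos")
  if (!inherits(scheme, "event_scheme")) abort("`scheme` must be an `event_scheme`.")
  if (!is.null(floor) && (floor <= 0 || !is.finite(floor))) {
    abort("`floor` must be a positive number or NULL.")
  }

  need <- c(scheme$pre_window[1]:scheme$pre_window[2],
            scheme$event_years,
            scheme$post_window[1]:scheme$post_window[2])
  cover <- chronos |>
    group_by(.data$tree_id) |>
    summarise(missing = list(setdiff(need, .data$year)), .groups = "drop") |>
    mutate(n_missing = lengths(.data$missing)) |>
    filter(.data$n_missing > 0)
  if (nrow(cover) > 0) {
    first <- cover$tree_id[1]
    abort(sprintf(
      "%d tree(s) do not cover all scheme years (e.g. tree %s misses %s).",
      nrow(cover), first, paste(cover$missing[[1]], collapse = ", ")
    ))
  }

  g <- chronos |>
    select("tree_id", "year", g = dplyr::all_of(value))
  win_mean <- function(w) {
    g |>
      filter(.data$year >= w[1], .data$year <= w[2]) |>
      group_by(.data$tree_id) |>
      summarise(m = mean(.data$g), .groups = "drop")
  }
  base <- win_mean(scheme$pre_window) |>
    rename(pre_mm = "m") |>
    left_join(win_mean(scheme$post_window) |> rename(post_mm = "m"), by = "tree_id")
  for (e in scheme$event_years) {
    de <- g |> filter(.data$year == e) |>
      select("tree_id", m = "g") |>
      setNames(c("tree_id", paste0("d_", e)))
    base <- base |> left_join(de, by = "tree_id")
  }

  apply_floor <- function(x, label) {
    bad <- x <= 0
    if (any(bad)) {
      if (is.null(floor)) {
        abort(sprintf("Non-positive %s for tree(s): %s (ratio undefined).",
                      label, paste(base$tree_id[bad], collapse = ", ")))
      }
      warn(sprintf("Floored non-positive %s for %d tree(s) at %g mm.",
                   label, sum(bad), floor))
      x[bad] <- floor
    }
    x
  }
  base$pre_mm <- apply_floor(base$pre_mm, "pre-disturbance mean growth")
  base$post_mm <- apply_floor(base$post_mm, "post-disturbance mean growth")
  for (e in scheme$event_years) {
    col <- paste0("d_", e)
    base[[col]] <- apply_floor(base[[col]], sprintf("growth in event year %d", e))
    base[[paste0("resistance_", e)]] <- base[[col]] / base$pre_mm
    base[[paste0("recovery_", e)]] <- base$post_mm / base[[col]]
  }
  base$resilience <- base$post_mm / base$pre_mm

  meta_cols <- intersect(c("provenance_id", "region", "block"), names(chronos))
  if (length(meta_cols) > 0) {
    meta <- chronos |> distinct(.data$tree_id, dplyr::pick(dplyr::all_of(meta_cols)))
    base <- meta |> inner_join(base, by = "tree_id")
  }
  attr(base, "event_scheme") <- scheme
  base
}

#' Percent growth loss implied by a resistance index
#'
#' Resistance is the retained fraction of pre-drought growth, so the percent
#' growth loss during the event is `100 * (1 - resistance)`: a resistance of
#' 0.69 means a 31% loss.
#'
#' @param resistance Resistance index (vectorized).
#' @return Percent growth loss.
#' @export
growth_loss <- function(resistance) 100 * (1 - resistance)

#' Regional summary of drought indices via mixed-model BLUEs
#'
#' Fits, for each index column, the drought-design mixed model (region fixed,
#' block random — appropriate for the one-tree-per-provenance-per-block core
#' sampling) and returns regional best linear unbiased estimates with
#' standard errors and Tukey-adjusted letter groups. See [fit_lmm_blues()].
#'
#' @param resilience Per-tree index tibble from [compute_resilience()] (must
#'   carry `region` and `block`).
#' @param indices Index columns to summarise; default: every
#'   `resistance_*`/`recovery_*` column plus `resilience`.
#' @param alpha Family-wise level for the letter display.
#' @return A tibble: `index`, `region`, `estimate`, `se`, `letters`.
#' @export
regional_resilience_table <- function(resilience, indices = NULL, alpha = 0.05) {
  check_columns(resilience, c("tree_id", "region", "block"), "resilience")
  if (is.null(indices)) {
    indices <- c(grep("^(resistance|recovery)_", names(resilience), value = TRUE),
                 intersect("resilience", names(resilience)))
  }
  if (length(indices) == 0) abort("No index columns found.")
  purrr::map_dfr(indices, function(ix) {
    fit <- fit_lmm_blues(resilience, response = ix, preset = "drought", alpha = alpha)
    tidy(fit) |> mutate(index = ix, .before = 1)
  })
}
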