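#' Read a Tucson/RWL decadal ring-width file
#'
#' Parses the fixed "decadal" layout used by tree-ring databases: each line
#' carries a series (core) identifier, the calendar year of the first value on
#' the line, and up to ten ring widths, one per year. A series ends with a
#' terminator value whose magnitude also encodes the measurement unit:
#' `999` marks series stored in 0.01 mm, `-9999` marks series stored in
#' 0.001 mm. Widths are returned in millimetres. The missing-ring code `0`
#' is kept as a width of 0 mm and flagged in the `missing_ring` column.
#'
#' @param path Path to an RWL file.
#' @param core_suffix Regular expression stripped from the core id to obtain
#'   the tree id. The default removes one trailing letter, the usual convention
#'   for cores taken from opposite sides of a stem (e.g. `"P07T3A"` and
#'   `"P07T3B"` both belong to tree `"P07T3"`). Use `NULL` to copy the core id.
#' @return A tibble with columns `core_id`, `tree_id`, `year`, `width_mm`,
#'   `missing_ring`, one row per measured ring, ordered by core and year.
#' @seealso [write_rwl()], [read_rings_csv()]
#' @export
read_rwl <- function(path, core_suffix = "[A-Za-z]$") {
  if (!file.exists(path)) abort(sprintf("RWL file not found: '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !grepl("^#", lines)
  lines <- lines[keep]
  line_no <- which(keep)

  out <- vector("list", length(lines))
  closed <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) < 3) {
      abort(sprintf("Malformed decade line %d in '%s': fewer than 3 fields.", line_no[i], path))
    }
    id <- tok[1]
    year0 <- suppressWarnings(as.integer(tok[2]))
    vals <- suppressWarnings(as.integer(tok[-(1:2)]))
    if (is.na(year0) || anyNA(vals)) {
      abort(sprintf("Malformed decade line %d in '%s': non-numeric year or value.", line_no[i], path))
    }
    if (id %in% closed) {
      abort(sprintf("Line %d in '%s': series '%s' continues after its terminator.", line_no[i], path, id))
    }
    term <- match(TRUE, vals == 999L | vals == -9999L)
    unit <- NA_real_
    if (!is.na(term)) {
      unit <- if (vals[term] == 999L) 0.01 else 0.001
      vals <- vals[seq_len(term - 1L)]
      closed <- c(closed, id)
    }
    if (any(vals < 0L)) {
      abort(sprintf("Malformed decade line %d in '%s': negative ring width.", line_no[i], path))
    }
    out[[i]] <- tibble(
      core_id = id,
      year = year0 + seq_along(vals) - 1L,
      raw = vals,
      unit = unit
    )
  }
  rings <- dplyr::bind_rows(out)
  if (nrow(rings) == 0) abort(sprintf("No ring measurements found in '%s'.", path))

  open <- setdiff(unique(rings$core_id), closed)
  if (length(open) > 0) {
    abort(sprintf("Series without terminator (999/-9999) in '%s': %s.",
                  path, paste(open, collapse = ", ")))
  }
  # a terminator appears once per series; propagate its unit to all its rows
  rings <- rings |>
    group_by(.data$core_id) |>
    mutate(unit = max(.data$unit, na.rm = TRUE)) |>
    ungroup()

  dup <- rings |> count(.data$core_id, .data$year) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate (core, year) in '%s': %s.", path,
                  paste(sprintf("%s/%d", dup$core_id, dup$year), collapse = ", ")))
  }

  rings |>
    mutate(
      tree_id = if (is.null(core_suffix)) .data$core_id else sub(core_suffix, "", .data$core_id),
      width_mm = .data$raw * .data$unit,
      missing_ring = .data$raw == 0L
    ) |>
    arrange(.data$core_id, .data$year) |>
    select("core_id", "tree_id", "year", "width_mm", "missing_ring")
}

#' Write ring-width series to a Tucson/RWL decadal file
#'
#' @param rings Tibble with columns `core_id`, `year`, `width_mm`.
#' @param path Output path.
#' @param units Storage precision: `"0.01mm"` (terminator 999) or
#'   `"0.001mm"` (terminator -9999).
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rings, path, units = c("0.01mm", "0.001mm")) {
  check_columns(rings, c("core_id", "year", "width_mm"), "rings")
  units <- match.arg(units)
  scale <- if (units == "0.01mm") 100 else 1000
  terminator <- if (units == "0.01mm") "999" else "-9999"

  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(rings$core_id)) {
    s <- rings |> filter(.data$core_id == id) |> arrange(.data$year)
    if (any(diff(s$year) <= 0)) abort(sprintf("Series '%s': years must be strictly increasing.", id))
    vals <- formatC(as.integer(round(s$width_mm * scale)), width = 6)
    yr <- s$year
    first_of_line <- (yr %% 10) == 0
    first_of_line[1] <- TRUE
    starts <- which(first_of_line)
    for (k in seq_along(starts)) {
      idx <- starts[k]:(if (k < length(starts)) starts[k + 1] - 1 else length(yr))
      fields <- vals[idx]
      if (k == length(starts)) fields <- c(fields, formatC(terminator, width = 6))
      writeLines(sprintf("%-8s%6d%s", id, yr[starts[k]], paste(fields, collapse = "")), con)
    }
  }
  invisible(path)
}

#' Read and write ring widths in long CSV form
#'
#' The long CSV layout (`core_id, tree_id, year, width_mm`) is the package's
#' canonical interchange format; RWL is supported for compatibility with
#' tree-ring databases.
#'
#' @param path CSV path.
#' @return A tibble with columns `core_id`, `tree_id`, `year`, `width_mm`.
#' @export
read_rings_csv <- function(path) {
  rings <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(rings, c("core_id", "tree_id", "year", "width_mm"), "rings csv")
  if (any(!is.finite(rings$width_mm)) || any(rings$width_mm < 0)) {
    abort(sprintf("'%s': ring widths must be finite and non-negative.", path))
  }
  rings |> mutate(year = as.integer(.data$year)) |> arrange(.data$core_id, .data$year)
}

#' @rdname read_rings_csv
#' @param rings Tibble with columns `core_id`, `tree_id`, `year`, `width_mm`.
#' @export
write_rings_csv <- function(rings, path) {
  check_columns(rings, c("core_id", "tree_id", "year", "width_mm"), "rings")
  readr::write_csv(rings[, c("core_id", "tree_id", "year", "width_mm")], path)
  invisible(path)
}

#' Read a trial design table
#'
#' The design table maps each tree to its provenance (seed source), region,
#' block and plot, and carries the field measurements: total height (cm),
#' diameter at breast height (mm) and survival (0/1).
#'
#' @param path CSV with columns `tree_id, provenance_id, region, block, plot,
#'   height_cm, dbh_mm, survival`.
#' @return A tibble, `block` coerced to integer, `survival` to 0/1.
#' @export
read_design_csv <- function(path) {
  design <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(design,
                c("tree_id", "provenance_id", "region", "block", "plot",
                  "height_cm", "dbh_mm", "survival"),
                "design csv")
  bad <- setdiff(na.omit(unique(design$survival)), c(0, 1))
  if (length(bad) > 0) abort(sprintf("'%s': survival must be 0/1.", path))
  design |> mutate(block = as.integer(.data$block))
}

#' Assemble per-tree chronologies from core measurements
#'
#' Cores of the same tree are combined by the arithmetic mean of the cores
#' present in each year (typically two, one per stem side), and the series is
#' truncated to the analysis window. The per-tree mean and standard deviation
#' of ring width over the window are attached; they are the anchors for the
#' later normalization and its reversal, so a tree with zero variance over the
#' window is an error.
#'
#' @param rings Tibble of core measurements (`core_id, tree_id, year,
#'   width_mm`), e.g. from [read_rwl()] or [read_rings_csv()].
#' @param design Trial design tibble (see [read_design_csv()]); every sampled
#'   tree must have a design row.
#' @param window Inclusive analysis window as `c(first, last)` calendar years.
#' @return A tibble with one row per tree and year: `tree_id`,
#'   `provenance_id`, `region`, `block`, `year`, `width_mm` (mean over cores),
#'   `n_cores`, `raw_mean_mm`, `raw_sd_mm` (window statistics, constant within
#'   tree).
#' @export
build_tree_chronologies <- function(rings, design, window = c(1988L, 2017L)) {
  check_columns(rings, c("core_id", "tree_id", "year", "width_mm"), "rings")
  check_columns(design, c("tree_id", "provenance_id", "region", "block"), "design")
  window <- check_window(window)

  rings <- rings |> filter(is.finite(.data$width_mm))
  unknown <- setdiff(unique(rings$tree_id), design$tree_id)
  if (length(unknown) > 0) {
    abort(sprintf("Trees with cores but no design row: %s.",
                  paste(sort(unknown), collapse = ", ")))
  }

  chronos <- rings |>
    filter(.data$year >= window[1], .data$year <= window[2]) |>
    group_by(.data$tree_id, .data$year) |>
    summarise(width_mm = mean(.data$width_mm), n_cores = dplyr::n(), .groups = "drop") |>
    group_by(.data$tree_id) |>
    mutate(raw_mean_mm = mean(.data$width_mm), raw_sd_mm = sd(.data$width_mm)) |>
    ungroup()

  flat <- chronos |>
    distinct(.data$tree_id, .data$raw_sd_mm) |>
    filter(!is.finite(.data$raw_sd_mm) | .data$raw_sd_mm <= 0)
  if (nrow(flat) > 0) {
    # not fatal here: a flat window only matters once normalization is asked for
    warn(sprintf(
      "Zero-variance (or single-year) chronology over %d-%d for tree%s %s: normalization will fail.",
      window[1], window[2], if (nrow(flat) > 1) "s" else "",
      paste(sort(flat$tree_id), collapse = ", ")
    ))
  }

  design |>
    select("tree_id", "provenance_id", "region", "block") |>
    inner_join(chronos, by = "tree_id") |>
    arrange(.data$tree_id, .data$year)
}
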