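# ggplot2 methods for the package's result objects

#' Plot regional mean chronologies
#'
#' Regional mean growth per year with a standard-error ribbon; the usual way
#' to eyeball drought years and between-region level differences.
#'
#' @param chronos Chronology tibble with `region`, `year` and a value column.
#' @param value Column to plot (default `"detrended_mm"` if present, else
#'   `"width_mm"`).
#' @param events Optional event years drawn as dashed vertical lines.
#' @return A ggplot.
#' @export
plot_regional_chronologies <- function(chronos, value = NULL, events = NULL) {
  value <- value %||% if ("detrended_mm" %in% names(chronos)) "detrended_mm" else "width_mm"
  check_columns(chronos, c("region", "year", value), "chronos")
  summ <- chronos |>
    group_by(.data$region, .data$year) |>
    summarise(m = mean(.data[[value]]), se = sd(.data[[value]]) / sqrt(dplyr::n()),
              .groups = "drop")
  p <- ggplot(summ, aes(x = .data$year, y = .data$m,
                        colour = .data$region, fill = .data$region)) +
    geom_ribbon(aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
                alpha = 0.2, colour = NA) +
    geom_line() +
    labs(x = "Year", y = sprintf("%s (regional mean ± SE)", value),
         colour = "Region", fill = "Region") +
    theme_minimal()
  if (!is.null(events)) {
    p <- p + geom_vline(xintercept = events, linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a daily anomaly series as a signed area
#'
#' The filled area between the series and zero integrates the size and
#' duration of climate anomalies; drier/warmer-than-normal spells show as
#' one-signed areas.
#'
#' @param anomalies Tibble from [anomaly_series()].
#' @return A ggplot.
#' @export
plot_anomaly <- function(anomalies) {
  check_columns(anomalies, c("date", "anomaly"), "anomalies")
  ggplot(anomalies, aes(x = as.Date(.data$date), y = .data$anomaly)) +
    geom_area(aes(fill = .data$anomaly > 0), show.legend = FALSE) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac")) +
    labs(x = NULL, y = "Anomaly vs. day-of-year normal") +
    theme_minimal()
}

#' @method autoplot crossdating_report
#' @export
autoplot.crossdating_report <- function(object, ...) {
  ggplot(object$trees, aes(x = .data$r)) +
    geom_histogram(bins = 30, fill = "grey35") +
    geom_vline(xintercept = object$r_bar, colour = "#b2182b") +
    labs(x = "Interseries correlation",
         y = "Trees",
         title = sprintf("Mean r = %.3f, EPS = %.3f (n = %d)",
                         object$r_bar, object$eps, object$n_series)) +
    theme_minimal()
}

#' @method autoplot region_blues
#' @export
autoplot.region_blues <- function(object, ...) {
  d <- object$estimates |>
    mutate(region = stats::reorder(.data$region, .data$estimate))
  ggplot(d, aes(x = .data$region, y = .data$estimate)) +
    geom_pointrange(aes(ymin = .data$estimate - .data$se,
                        ymax = .data$estimate + .data$se)) +
    geom_text(aes(label = .data$letters, y = .data$estimate + 1.3 * .data$se),
              vjust = -0.4, size = 3.2) +
    labs(x = NULL, y = sprintf("%s (BLUE ± SE)", object$response)) +
    coord_flip() +
    theme_minimal()
}

#' @method autoplot association_matrix
#' @export
autoplot.association_matrix <- function(object, ...) {
  d <- object$table
  ggplot(d, aes(x = .data$climate_var, y = .data$trait, fill = .data$rho)) +
    geom_tile() +
    geom_text(aes(label = ifelse(.data$significant, "*", "")), size = 5) +
    scale_fill_gradient2(low = "#2166ac", high = "#b2182b", limits = c(-1, 1),
                         na.value = "grey80") +
    labs(x = "Climate of origin", y = "Trait",
         fill = "Spearman ρ",
         caption = sprintf("* Holm-adjusted p < %.2f (%s family)",
                           object$alpha, object$family)) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @method autoplot climate_pca
#' @export
autoplot.climate_pca <- function(object, ...) {
  fr <- object$var_frac$variance_fraction
  sc <- object$scores
  # scale the variable-correlation vectors to the score cloud
  r <- max(abs(c(sc$Comp.1, sc$Comp.2))) * 0.9
  arrows <- object$loadings |>
    mutate(x = .data$Comp.1 * r, y = .data$Comp.2 * r)
  p <- ggplot(sc, aes(x = .data$Comp.1, y = .data$Comp.2))
  if ("region" %in% names(sc)) p <- p + geom_point(aes(colour = .data$region))
  else p <- p + geom_point()
  p +
    geom_segment(data = arrows, aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
                 arrow = grid::arrow(length = grid::unit(2, "mm")), colour = "grey40") +
    geom_text(data = arrows, aes(x = 1.07 * .data$x, y = 1.07 * .data$y,
                                 label = .data$variable), size = 3) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * fr[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * fr[2])) +
    theme_minimal()
}
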