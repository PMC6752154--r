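# shared fixtures, built in code

# a minimal design table for n trees in one or more regions
tiny_design <- function(tree_ids, provenance = "P1", region = "R1", block = 1L) {
  tibble::tibble(
    tree_id = tree_ids,
    provenance_id = rep_len(provenance, length(tree_ids)),
    region = rep_len(region, length(tree_ids)),
    block = rep_len(as.integer(block), length(tree_ids)),
    plot = paste0("pl-", rep_len(provenance, length(tree_ids)), "-",
                  rep_len(block, length(tree_ids))),
    height_cm = 800, dbh_mm = 100, survival = 1L
  )
}

# a chronology tibble for one tree directly from a width vector
tiny_chrono <- function(widths, years = seq_along(widths) + 1987L, tree_id = "T1",
                        region = "R1", block = 1L, provenance = "P1") {
  tibble::tibble(
    tree_id = tree_id, provenance_id = provenance, region = region,
    block = as.integer(block), year = as.integer(years), width_mm = widths,
    n_cores = 1L, raw_mean_mm = mean(widths), raw_sd_mm = stats::sd(widths)
  )
}

# a common_spline that is identically zero over the given years
null_spline <- function(years = 1988:2017) {
  z0 <- tibble::tibble(tree_id = "flat", year = years, z = 0)
  fit_common_spline(z0, stiffness = 0.7)
}

# small, fast generator config for tests
test_config <- function(seed = 1L, ...) {
  generator_config(seed = seed, ...)
}

# a config whose drought multipliers are all 1 (generator null)
no_drought_config <- function(seed = 1L, ...) {
  cfg <- generator_config(seed = seed, ...)
  cfg$regions$resistance_1999 <- 1
  cfg$regions$resistance_2002 <- 1
  cfg
}

# a balanced multi-region design with exact region means and no noise
noiseless_design <- function(region_means = c(A = 10, B = 20, C = 35),
                             n_blocks = 4L, n_prov = 2L, n_per_plot = 3L) {
  d <- tidyr::expand_grid(
    region = names(region_means),
    prov = seq_len(n_prov),
    block = seq_len(n_blocks),
    tree = seq_len(n_per_plot)
  ) |>
    dplyr::mutate(
      provenance_id = paste0(region, prov),
      plot = paste0(provenance_id, "-b", block),
      tree_id = paste0(plot, "-t", tree),
      y = unname(region_means[region]),
      height_cm = y, dbh_mm = y, survival = 1L
    )
  d
}
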