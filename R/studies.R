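# Replicated simulation experiments validating the pipeline against the
# generator's known truth. These are the package's built-in calibration
# studies: each returns per-replicate results plus a one-row summary.

#' Variance-component recovery study
#'
#' Simulates trait data at the trial's design size with known variance
#' components, refits the growth-preset mixed model by REML, and summarises
#' the relative bias of each recovered component across replicates.
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed; replicate `i` uses `seed * 1000 + i` offsets.
#' @param trait_vc True components `c(prov, block, plot, resid)` on the
#'   response scale (variances).
#' @return List with `estimates` (per-replicate tibble) and `summary`
#'   (per-component mean estimate, truth, percent bias).
#' @export
vc_recovery_study <- function(n_rep = 200, seed = 1,
                              trait_vc = c(prov = 0.5, block = 0.3,
                                           plot = 0.2, resid = 1)) {
  est <- purrr::map_dfr(seq_len(n_rep), function(i) {
    cfg <- generator_config(
      seed = sub_seed(seed, i),
      trait_vc = list(height = trait_vc, dbh = trait_vc)
    )
    d <- simulate_traits(cfg)
    fit <- suppressWarnings(fit_lmm_blues(d, "height_cm", preset = "growth"))
    vc <- varcomp(fit)
    tibble(rep = i,
           prov = vc$variance[vc$term == "prov_in_region"],
           block = vc$variance[vc$term == "block"],
           plot = vc$variance[vc$term == "plot_in_block"],
           resid = vc$variance[vc$term == "Residual"])
  })
  truth <- trait_vc[c("prov", "block", "plot", "resid")]
  means <- colMeans(est[, names(truth)])
  summary <- tibble(
    component = names(truth),
    truth = unname(truth),
    estimate = unname(means)
  ) |>
    mutate(bias_pct = 100 * (.data$estimate - .data$truth) / .data$truth)
  list(estimates = est, summary = summary)
}

#' Survival-probability recovery study
#'
#' Simulates the trial's survival data (region-level Bernoulli rates from the
#' published regional estimates), fits the binomial GLMM, and reports how
#' often each region's estimated survival probability falls within two
#' reported standard errors of the generating truth.
#'
#' @inheritParams vc_recovery_study
#' @return List with `results` (region x replicate) and `summary`
#'   (`coverage`: fraction within 2 SE; `mean_abs_err`).
#' @export
survival_recovery_study <- function(n_rep = 200, seed = 1) {
  results <- purrr::map_dfr(seq_len(n_rep), function(i) {
    cfg <- generator_config(seed = sub_seed(seed, i))
    d <- simulate_traits(cfg)
    fit <- suppressWarnings(fit_glmm_survival(d))
    est <- tidy(fit)
    truth <- generator_truth(d)$region_survival[est$region]
    tibble(rep = i, region = est$region, estimate = est$estimate,
           se = est$se, truth = unname(truth))
  })
  summary <- tibble(
    coverage = mean(abs(results$estimate - results$truth) < 2 * results$se),
    mean_abs_err = mean(abs(results$estimate - results$truth))
  )
  list(results = results, summary = summary)
}

#' End-to-end drought-resistance recovery study
#'
#' The full pipeline experiment: simulate cores with known regional resistance
#' multipliers (single-year shocks, no recovery lag, so the event-year
#' multiplier is the constructed truth), assemble chronologies, detrend with
#' the common spline, compute Lloret indices, fit the drought-preset mixed
#' model, and compare the regional resistance BLUEs with the injected truth.
#'
#' @inheritParams vc_recovery_study
#' @param event_year Which event's resistance to evaluate.
#' @param floor Small positive growth floor (mm) forwarded to
#'   [compute_resilience()] so that rare non-positive detrended event-year
#'   values do not abort a replicate.
#' @return List with `results` (region x replicate: estimate, se, truth) and
#'   `summary` (`coverage` within 2 SE, `mean_bias`).
#' @export
resistance_recovery_study <- function(n_rep = 200, seed = 1, event_year = 1999L,
                                      floor = 0.05) {
  results <- purrr::map_dfr(seq_len(n_rep), function(i) {
    cfg <- generator_config(
      seed = sub_seed(seed, i),
      drought = list(event_years = c(1999L, 2002L), recovery_lag = 0L,
                     lag_decay = 0.5)
    )
    design <- simulate_traits(cfg)
    rings <- simulate_chronologies(cfg, design)
    det <- detrend_chronologies(build_tree_chronologies(rings, design))
    res <- suppressWarnings(compute_resilience(det, floor = floor))
    col <- paste0("resistance_", event_year)
    tab <- regional_resilience_table(res, indices = col)
    truth <- generator_truth(rings)$resistance[tab$region, col]
    tibble(rep = i, region = tab$region, estimate = tab$estimate,
           se = tab$se, truth = unname(truth))
  })
  summary <- tibble(
    coverage = mean(abs(results$estimate - results$truth) < 2 * results$se),
    mean_bias = mean(results$estimate - results$truth)
  )
  list(results = results, summary = summary)
}

#' Family-wise error study for the association screen
#'
#' Repeatedly draws provenance traits and climate normals with *no*
#' association (independent permutation null) and records how often the
#' Holm-adjusted Spearman screen declares any pair significant. Under valid
#' family-wise control the rate must not exceed the nominal level.
#'
#' @inheritParams vc_recovery_study
#' @param n_prov Number of provenances per replicate.
#' @param n_traits,n_climate Number of trait and climate columns.
#' @param alpha Nominal family-wise level.
#' @return List with `any_significant` (logical per replicate) and `summary`
#'   (`fwer`: fraction of replicates with at least one rejection).
#' @export
fwer_study <- function(n_rep = 500, seed = 1, n_prov = 33,
                       n_traits = 8, n_climate = 13, alpha = 0.05) {
  any_sig <- vapply(seq_len(n_rep), function(i) {
    with_seed(sub_seed(seed, i), {
      traits <- as_tibble(matrix(rnorm(n_prov * n_traits), n_prov,
                                 dimnames = list(NULL, paste0("t", seq_len(n_traits)))))
      climate <- as_tibble(matrix(rnorm(n_prov * n_climate), n_prov,
                                  dimnames = list(NULL, paste0("c", seq_len(n_climate)))))
      traits$provenance_id <- climate$provenance_id <- seq_len(n_prov)
      am <- spearman_holm(traits, climate, alpha = alpha)
      any(tidy(am)$significant)
    })
  }, logical(1))
  list(any_significant = any_sig, summary = tibble(fwer = mean(any_sig)))
}
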