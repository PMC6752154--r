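test_that("balanced noiseless data gives BLUEs equal to group means with zero SE", {
  d <- noiseless_design(c(A = 10, B = 20, C = 35))
  fit <- suppressWarnings(fit_lmm_blues(d, "y", preset = "growth"))
  est <- tidy(fit)
  expect_equal(est$estimate[match(c("A", "B", "C"), est$region)], c(10, 20, 35),
               tolerance = 1e-8)
  expect_equal(est$se, rep(0, 3), tolerance = 1e-6)
  expect_equal(sum(varcomp(fit)$variance), 0, tolerance = 1e-8)
  # all-different groups get all-different letters
  expect_equal(sort(est$letters), c("a", "b", "c"))

  fit2 <- suppressWarnings(fit_lmm_blues(d, "y", preset = "drought"))
  expect_equal(sort(tidy(fit2)$estimate), c(10, 20, 35), tolerance = 1e-8)
})

test_that("REML recovers known variance components without gross bias", {
  # light sanity check at the trial scale; the 200-replicate bias experiment
  # is part of the acceptance suite
  cfg <- test_config(seed = 43,
                     trait_vc = list(height = c(prov = 0.5, block = 0.3,
                                                plot = 0.2, resid = 1),
                                     dbh = c(prov = 64, block = 36, plot = 16,
                                             resid = 225)))
  vc_hat <- purrr::map_dfr(1:10, function(i) {
    cfg$seed <- 43L + i
    d <- simulate_traits(cfg)
    fit <- suppressWarnings(fit_lmm_blues(d, "height_cm", preset = "growth"))
    tidyr::pivot_wider(varcomp(fit)[, c("term", "variance")],
                       names_from = term, values_from = variance)
  })
  means <- colMeans(vc_hat)
  expect_lt(abs(means[["prov_in_region"]] - 0.5), 0.25)
  expect_lt(abs(means[["plot_in_block"]] - 0.2), 0.15)
  expect_lt(abs(means[["Residual"]] - 1.0), 0.2)
})

test_that("a single block clamps the block variance to zero with a warning", {
  d <- noiseless_design(c(A = 10, B = 20), n_blocks = 1L) |>
    dplyr::mutate(y = y + stats::rnorm(dplyr::n(), 0, 0.5))
  expect_warning(fit <- fit_lmm_blues(d, "y", preset = "drought"),
                 "inestimable")
  expect_equal(varcomp(fit)$variance[varcomp(fit)$term == "block"], 0)
  expect_equal(nrow(tidy(fit)), 2L)
})

test_that("regions absent from the design are rejected", {
  d <- noiseless_design(c(A = 10))
  expect_error(suppressWarnings(fit_lmm_blues(d, "y", preset = "growth")),
               "2 regions")
})

test_that("the survival GLMM recovers region probabilities and flags separation", {
  cfg <- test_config(seed = 47)
  d <- simulate_traits(cfg)
  fit <- suppressWarnings(fit_glmm_survival(d))
  est <- tidy(fit)
  truth <- generator_truth(d)$region_survival[est$region]
  expect_true(all(abs(est$estimate - truth) < pmax(2 * est$se, 0.06)))

  # all-survivors: estimates at the boundary, separation flagged
  d1 <- dplyr::mutate(d, survival = 1L)
  expect_warning(fit1 <- fit_glmm_survival(d1), "separation")
  est1 <- tidy(fit1)
  expect_true(all(est1$estimate > 0.999))
  expect_true(all(est1$separation))
})

test_that("Tukey letters separate exactly the significantly different groups", {
  # identical means: a single shared letter
  expect_equal(tukey_letters(c(a = 5, b = 5, c = 5), diag(0.2, 3), df = 20),
               rep("a", 3))
  # two groups ten SEs apart: distinct letters
  expect_equal(sort(tukey_letters(c(x = 0, y = 10), diag(1, 2), df = 30)),
               c("a", "b"))
  # three well-separated clusters mirroring the published height pattern
  est <- c(BC = 546, MC = 700, MM = 767, BP = 908, BS = 957, TM = 966)
  v <- diag(25^2, 6)
  lt <- tukey_letters(est, v, df = 100)
  expect_equal(unname(lt), c("c", "b", "b", "a", "a", "a"))
  expect_error(tukey_letters(c(a = 1, b = 2), matrix(NA_real_, 2, 2)), "NA")
})

test_that("Tukey letters agree with the multcomp reference on a random fit", {
  withr::local_seed(53)
  d <- tibble::tibble(
    g = factor(rep(LETTERS[1:5], each = 12)),
    y = rnorm(60, rep(c(0, 0.4, 0.5, 2.5, 2.6), each = 12))
  )
  fit <- stats::lm(y ~ 0 + g, data = d)
  mine <- tukey_letters(coef(fit), vcov(fit), df = fit$df.residual)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  ref <- multcomp::cld(glht)$mcletters$Letters
  # same partition: groups share a letter in one display iff they do in the other
  share <- function(lt) outer(lt, lt, function(a, b) {
    mapply(function(x, y) any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]]), a, b)
  })
  expect_equal(unname(share(mine)), unname(share(as.character(ref))))
})

test_that("Spearman screening matches a rank-based oracle and flags monotone pairs", {
  withr::local_seed(59)
  n <- 20
  traits <- tibble::tibble(provenance_id = paste0("P", 1:n),
                           t1 = rnorm(n), t2 = rnorm(n))
  climate <- tibble::tibble(provenance_id = paste0("P", 1:n),
                            c1 = traits$t1^3 + 0.001 * rnorm(n),  # monotone in t1
                            c2 = rnorm(n))
  am <- spearman_holm(traits, climate)
  tab <- tidy(am)
  r11 <- dplyr::filter(tab, trait == "t1", climate_var == "c1")
  expect_gt(r11$rho, 0.99)
  expect_true(r11$significant)

  # oracle: Spearman rho is the Pearson correlation of average ranks
  oracle <- cor(rank(traits$t2), rank(climate$c2))
  r22 <- dplyr::filter(tab, trait == "t2", climate_var == "c2")
  expect_equal(r22$rho, oracle, tolerance = 1e-12)

  # Holm: adjusted never below raw, monotone in raw-p order, <= Bonferroni
  ok <- !is.na(tab$p)
  expect_true(all(tab$p_holm[ok] >= tab$p[ok]))
  o <- order(tab$p[ok])
  expect_true(all(diff(tab$p_holm[ok][o]) >= -1e-15))
  expect_true(all(tab$p_holm[ok] <= pmin(1, tab$p[ok] * sum(ok)) + 1e-15))
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  withr::local_seed(61)
  n <- 15
  traits <- tibble::tibble(provenance_id = 1:n, t = rnorm(n))
  c1 <- tibble::tibble(provenance_id = 1:n, c = rnorm(n))
  c2 <- dplyr::mutate(c1, c = exp(3 * c))
  t2 <- dplyr::mutate(traits, t = atan(t) - 5)
  expect_equal(tidy(spearman_holm(traits, c1))$rho,
               tidy(spearman_holm(t2, c2))$rho, tolerance = 1e-12)
})

test_that("constant columns are flagged, not fatal", {
  traits <- tibble::tibble(provenance_id = 1:8, t = rnorm(8), flat = 1)
  climate <- tibble::tibble(provenance_id = 1:8, c = rnorm(8))
  expect_warning(am <- spearman_holm(traits, climate), "undefined")
  tab <- tidy(am)
  expect_true(is.na(dplyr::filter(tab, trait == "flat")$rho))
  expect_false(dplyr::filter(tab, trait == "flat")$significant)
})

test_that("climate PCA decomposes the correlation matrix", {
  cfg <- test_config(seed = 67)
  clim <- simulate_provenance_climate(cfg) |> dplyr::select(-region)
  pca <- climate_pca(clim)
  vf <- glance(pca)$variance_fraction
  expect_equal(sum(vf), 1, tolerance = 1e-12)
  expect_true(all(diff(vf) <= 1e-12))

  # loadings are variable-component correlations
  sc <- augment(pca)
  ld <- tidy(pca)
  v <- "mat"
  expect_equal(cor(clim[[v]], sc$Comp.1),
               ld$Comp.1[ld$variable == v], tolerance = 1e-6)

  # affine rescaling of any variable leaves the correlation PCA unchanged
  clim2 <- dplyr::mutate(clim, map = map / 25.4 + 3)
  vf2 <- glance(climate_pca(clim2))$variance_fraction
  expect_equal(vf, vf2, tolerance = 1e-10)

  # two perfectly correlated variables: one component explains everything
  two <- tibble::tibble(provenance_id = 1:10, a = rnorm(10))
  two$b <- 2 * two$a - 1
  expect_equal(glance(climate_pca(two))$variance_fraction[1], 1, tolerance = 1e-12)

  expect_error(climate_pca(dplyr::mutate(clim, flat = 5)), "flat")
})
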