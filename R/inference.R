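# Regional estimation for the randomized complete block provenance trial.
#
# Two model presets encode the two sampling intensities of the trial:
#  * "growth"  (height/DBH; 25 trees per provenance in 5-tree row plots):
#      y ~ region + (1 | provenance in region) + (1 | block) + (1 | plot in block)
#  * "drought" (core-sampled indices; 1 tree per provenance per block):
#      y ~ region + (1 | block)
# Regions are fixed; everything else random. Fitting is REML via lme4, and the
# regional BLUEs are the fixed-effect region means (the model is parameterized
# without an intercept, so fixef() returns mu + R_i directly) with model-based
# standard errors from the REML covariance.

lmm_formula <- function(response, preset, data) {
  random <- switch(preset,
    growth = c("prov_in_region", "block", "plot_in_block"),
    drought = "block",
    abort(sprintf("Unknown preset '%s'.", preset))
  )
  # a grouping factor with a single observed level carries no estimable
  # variance: drop the term (its component is reported as 0) rather than fail
  estimable <- vapply(random, function(g) dplyr::n_distinct(data[[g]]) > 1, logical(1))
  if (any(!estimable)) {
    warn(sprintf("Variance of %s inestimable (single level); clamped to 0.",
                 paste(random[!estimable], collapse = ", ")))
  }
  random <- random[estimable]
  list(
    formula = stats::reformulate(
      c("0", "region", sprintf("(1 | %s)", random)),
      response = sprintf("`%s`", response)
    ),
    dropped = switch(preset, growth = c("prov_in_region", "block", "plot_in_block"),
                     drought = "block")[!estimable],
    has_random = length(random) > 0
  )
}

prepare_model_frame <- function(data, response, preset) {
  need <- c("region", "block", response)
  if (preset == "growth") need <- c(need, "provenance_id", "plot")
  check_columns(data, need, "data")
  d <- data |>
    filter(!is.na(.data[[response]])) |>
    mutate(
      region = factor(.data$region, levels = unique(.data$region)),
      block = factor(.data$block)
    )
  if (nlevels(d$region) < 2) abort("At least 2 regions are required.")
  if (preset == "growth") {
    d <- d |> mutate(
      prov_in_region = factor(paste(.data$region, .data$provenance_id, sep = ":")),
      plot_in_block = factor(paste(.data$block, .data$plot, sep = ":"))
    )
  }
  # a region absent from every block makes the fixed-effect design singular
  present <- d |> distinct(.data$region, .data$block)
  if (any(table(present$region) == 0)) abort("Each region must occur in at least one block.")
  d
}

# containment-style residual degrees of freedom: n minus the rank of the
# combined fixed + random design matrix. Letter displays are sensitive to the
# df convention; this one reduces to the classical RCBD residual df.
containment_df <- function(fit) {
  x <- lme4::getME(fit, "X")
  z <- as.matrix(Matrix::t(lme4::getME(fit, "Zt")))
  max(1L, nrow(x) - qr(cbind(x, z))$rank)
}

#' Regional BLUEs from a linear mixed model
#'
#' Fits the trial's mixed model by REML and returns best linear unbiased
#' estimates of the regional means with model-based standard errors and a
#' Tukey-adjusted compact letter display. Two presets match the two sampling
#' designs: `"growth"` (region fixed; provenance-within-region, block and
#' plot-within-block random; for height/DBH measured on all plot trees) and
#' `"drought"` (region fixed, block random; for drought indices measured on
#' one cored tree per provenance and block).
#'
#' On exactly noise-free input the REML covariance degenerates; the estimates
#' are then still the group means and their standard errors are reported as 0.
#' Variance components estimated at the boundary are reported as 0 (lme4
#' constrains them to be non-negative).
#'
#' @param data Tibble with `region`, `block`, the response column, and for the
#'   growth preset also `provenance_id` and `plot`.
#' @param response Name of the response column.
#' @param preset `"growth"` or `"drought"`.
#' @param alpha Family-wise error level for the letter display.
#' @return An object of class `region_blues`. `tidy()` gives the per-region
#'   table (`region`, `estimate`, `se`, `letters`); `glance()` the fit summary;
#'   `varcomp()` the variance components.
#' @export
fit_lmm_blues <- function(data, response, preset = c("growth", "drought"), alpha = 0.05) {
  preset <- match.arg(preset)
  d <- prepare_model_frame(data, response, preset)
  fm <- lmm_formula(response, preset, d)
  fit <- withCallingHandlers(
    if (fm$has_random) lme4::lmer(fm$formula, data = d, REML = TRUE)
    else stats::lm(fm$formula, data = d),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      if (grepl("Hessian|converge|singular", conditionMessage(w), ignore.case = TRUE)) {
        invokeRestart("muffleWarning")
      }
    }
  )
  est <- if (fm$has_random) lme4::fixef(fit) else coef(fit)
  v <- tryCatch(suppressWarnings(as.matrix(vcov(fit))), error = function(e) NULL)
  if (is.null(v) || anyNA(v)) {
    # degenerate (noise-free) fit: all variability explained, SEs are zero
    v <- matrix(0, length(est), length(est))
  }
  regions <- levels(d$region)
  names(est) <- regions
  df <- if (fm$has_random) containment_df(fit) else fit$df.residual
  letters <- tukey_letters(est, v, df = df, alpha = alpha)

  if (fm$has_random) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- tibble(term = vc$grp, variance = pmax(vc$vcov, 0), sd = pmax(vc$sdcor, 0))
  } else {
    varcomp <- tibble(term = "Residual", variance = stats::sigma(fit)^2,
                      sd = stats::sigma(fit))
  }
  if (length(fm$dropped) > 0) {
    varcomp <- dplyr::bind_rows(
      tibble(term = fm$dropped, variance = 0, sd = 0), varcomp)
  }

  structure(
    list(
      estimates = tibble(region = regions, estimate = unname(est),
                         se = unname(sqrt(pmax(diag(v), 0))), letters = letters),
      vcov = v, varcomp = varcomp, fit = fit, response = response,
      preset = preset, df = df, alpha = alpha, scale = "response",
      n = nrow(d)
    ),
    class = "region_blues"
  )
}

#' Regional survival estimates from a binomial GLMM
#'
#' Fits a logistic mixed model (`survival ~ region + (1 | provenance in
#' region) + (1 | block)`, logit link, Laplace approximation) and reports
#' per-region survival probabilities: the inverse-link of the region fixed
#' effects, with delta-method standard errors. The Tukey letter display is
#' computed on the link scale, where the normal approximation holds, using
#' an infinite-df studentized range (z-based), the usual convention for GLMMs.
#'
#' Complete separation (a region entirely alive or dead) pushes the link-scale
#' estimate to the boundary; such regions are flagged in the `separation`
#' column and their estimates reported as-is with the (divergent) model SE —
#' no silent penalization is applied.
#'
#' @param data Tibble with `region`, `provenance_id`, `block`, `survival` (0/1).
#' @param alpha Family-wise error level for the letter display.
#' @return A `region_blues` object on the probability scale; `tidy()` includes
#'   a `separation` flag.
#' @export
fit_glmm_survival <- function(data, alpha = 0.05) {
  check_columns(data, c("region", "provenance_id", "block", "survival"), "data")
  if (!all(data$survival %in% c(0, 1))) abort("`survival` must be 0/1.")
  d <- data |>
    mutate(
      region = factor(.data$region, levels = unique(.data$region)),
      block = factor(.data$block),
      prov_in_region = factor(paste(.data$region, .data$provenance_id, sep = ":"))
    )
  if (nlevels(d$region) < 2) abort("At least 2 regions are required.")
  regions <- levels(d$region)
  if (dplyr::n_distinct(d$survival) == 1) {
    # every tree alive (or dead): complete separation in every region; report
    # the boundary directly (the likelihood has no interior optimum)
    warn(sprintf("Possible complete separation for region(s): %s (boundary estimate, SE unreliable).",
                 paste(regions, collapse = ", ")))
    p_bound <- if (d$survival[1] == 1) 1 - 1e-12 else 1e-12
    eta <- setNames(rep(qlogis(p_bound), length(regions)), regions)
    return(structure(
      list(
        estimates = tibble(region = regions, estimate = plogis(unname(eta)),
                           se = Inf, letters = rep("a", length(regions)),
                           separation = TRUE),
        link = tibble(region = regions, estimate = unname(eta), se = Inf),
        vcov = matrix(0, length(eta), length(eta)),
        varcomp = tibble(term = c("prov_in_region", "block"), variance = 0, sd = 0),
        fit = NULL, response = "survival", preset = "glmm", df = Inf,
        alpha = alpha, scale = "probability", n = nrow(d)
      ),
      class = "region_blues"
    ))
  }
  fit <- withCallingHandlers(
    lme4::glmer(survival ~ 0 + region + (1 | prov_in_region) + (1 | block),
                data = d, family = stats::binomial()),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      if (grepl("Hessian|converge|singular|scaled gradient|pwrssUpdate",
                conditionMessage(w), ignore.case = TRUE)) {
        invokeRestart("muffleWarning")
      }
    }
  )
  eta <- lme4::fixef(fit)
  v <- tryCatch(suppressWarnings(as.matrix(vcov(fit))), error = function(e) NULL)
  if (is.null(v) || anyNA(v)) v <- matrix(0, length(eta), length(eta))
  regions <- levels(d$region)
  names(eta) <- regions

  separation <- abs(eta) > 8  # |logit| > 8: probability within 3e-4 of 0/1
  if (any(separation)) {
    warn(sprintf("Possible complete separation for region(s): %s (boundary estimate, SE unreliable).",
                 paste(regions[separation], collapse = ", ")))
  }
  p <- plogis(eta)
  se_link <- sqrt(pmax(diag(v), 0))
  se_p <- se_link * p * (1 - p)  # delta method
  letters <- tukey_letters(eta, v, df = Inf, alpha = alpha)

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble(term = vc$grp, variance = pmax(vc$vcov, 0), sd = pmax(vc$sdcor, 0))

  structure(
    list(
      estimates = tibble(region = regions, estimate = unname(p),
                         se = unname(se_p), letters = letters,
                         separation = unname(separation)),
      link = tibble(region = regions, estimate = unname(eta), se = se_link),
      vcov = v, varcomp = varcomp, fit = fit, response = "survival",
      preset = "glmm", df = Inf, alpha = alpha, scale = "probability",
      n = nrow(d)
    ),
    class = "region_blues"
  )
}

#' @export
print.region_blues <- function(x, ...) {
  cat(sprintf("Regional BLUEs for '%s' (%s preset, n = %d, %s scale)\n",
              x$response, x$preset, x$n, x$scale))
  print(as.data.frame(x$estimates), row.names = FALSE)
  invisible(x)
}

#' Tidiers for regional mixed-model estimates
#'
#' @param x A `region_blues` object.
#' @param ... Unused.
#' @return `tidy()`: one row per region with `estimate`, `se`, `letters`;
#'   `glance()`: one-row fit summary; `varcomp()`: variance components.
#' @method tidy region_blues
#' @export
tidy.region_blues <- function(x, ...) x$estimates

#' @rdname tidy.region_blues
#' @method glance region_blues
#' @export
glance.region_blues <- function(x, ...) {
  tibble(
    response = x$response, preset = x$preset, n = x$n,
    n_regions = nrow(x$estimates), df = x$df,
    sigma = if (inherits(x$fit, "lmerMod")) stats::sigma(x$fit) else NA_real_,
    logLik = as.numeric(stats::logLik(x$fit))
  )
}

#' @rdname tidy.region_blues
#' @export
varcomp <- function(x) {
  if (!inherits(x, "region_blues")) abort("`x` must be a `region_blues`.")
  x$varcomp
}

#' Tukey-adjusted compact letter display
#'
#' All pairwise differences are tested with the studentized-range criterion at
#' family-wise level `alpha`: groups `i`, `j` differ when
#' `|m_i - m_j| / se_ij > q(1 - alpha, k, df) / sqrt(2)` with `se_ij` from the
#' estimate covariance. Letters are then assigned with the insert-and-absorb
#' algorithm, so groups sharing a letter are not significantly different.
#' When the covariance is exactly zero (noise-free fits) groups are separated
#' whenever their estimates differ at all.
#'
#' @param estimates Named numeric vector of group estimates.
#' @param vcov Covariance matrix of the estimates (no `NA`s).
#' @param df Degrees of freedom of the studentized range; `Inf` for the
#'   normal-approximation (GLMM) case.
#' @param alpha Family-wise error level.
#' @return Character vector of letter groups, parallel to `estimates`, with
#'   letters ordered by decreasing estimate.
#' @export
tukey_letters <- function(estimates, vcov, df = Inf, alpha = 0.05) {
  k <- length(estimates)
  if (k < 2) abort("Need at least 2 groups.")
  vcov <- as.matrix(vcov)
  if (anyNA(vcov) || nrow(vcov) != k || ncol(vcov) != k) {
    abort("`vcov` must be a k x k covariance matrix without NAs.")
  }
  crit <- qtukey(1 - alpha, k, max(df, 1)) / sqrt(2)

  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se2 <- vcov[i, i] + vcov[j, j] - 2 * vcov[i, j]
      diff <- abs(estimates[i] - estimates[j])
      sig[i, j] <- sig[j, i] <-
        if (se2 <= 1e-24) diff > 1e-10 * max(1, abs(estimates[i]), abs(estimates[j]))
        else diff / sqrt(se2) > crit
    }
  }

  # insert-and-absorb on logical membership columns
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      hit <- vapply(cols, function(cl) cl[i] && cl[j], logical(1))
      if (!any(hit)) next
      new_cols <- list()
      for (idx in seq_along(cols)) {
        cl <- cols[[idx]]
        if (cl[i] && cl[j]) {
          a <- cl; a[i] <- FALSE
          b <- cl; b[j] <- FALSE
          new_cols <- c(new_cols, list(a, b))
        } else {
          new_cols <- c(new_cols, list(cl))
        }
      }
      # absorb: drop columns whose members are a subset of another column's
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_cols[[b]][new_cols[[a]]]) &&
              !(all(new_cols[[a]] == new_cols[[b]]) && a < b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- unique(new_cols[keep])
    }
  }
  # order letters by the best (largest) estimate among each column's members
  ord <- order(vapply(cols, function(cl) -max(estimates[cl]), numeric(1)))
  cols <- cols[ord]
  vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(cl) cl[g], logical(1)))], collapse = "")
  }, character(1))
}

#' Spearman correlation screen with Holm adjustment
#'
#' Rank-based (Spearman) correlations between every trait column and every
#' climate column across provenances, with p-values from [stats::cor.test()]
#' (exact for ten or fewer pairs without ties, t-approximation otherwise) and
#' the family-wise Holm step-down adjustment over the whole trait-by-climate
#' matrix (the default and more conservative choice) or within each trait.
#'
#' @param traits Tibble of provenance-level trait means; first joined to
#'   `climate` on `by`.
#' @param climate Tibble of provenance climate normals.
#' @param by Join column (default `"provenance_id"`).
#' @param trait_cols,climate_cols Column selections; default: all numeric
#'   columns other than `by`.
#' @param family `"matrix"` (Holm over all pairs jointly) or `"per_trait"`.
#' @param alpha Significance level applied to adjusted p-values.
#' @return An `association_matrix`; `tidy()` gives `trait`, `climate_var`,
#'   `n`, `rho`, `p`, `p_holm`, `significant`.
#' @export
spearman_holm <- function(traits, climate, by = "provenance_id",
                          trait_cols = NULL, climate_cols = NULL,
                          family = c("matrix", "per_trait"), alpha = 0.05) {
  family <- match.arg(family)
  check_columns(traits, by, "traits")
  check_columns(climate, by, "climate")
  numeric_cols <- function(d) names(d)[vapply(d, is.numeric, logical(1))]
  trait_cols <- trait_cols %||% setdiff(numeric_cols(traits), by)
  climate_cols <- climate_cols %||% setdiff(numeric_cols(climate), by)
  if (length(trait_cols) == 0 || length(climate_cols) == 0) {
    abort("No numeric trait or climate columns to correlate.")
  }
  merged <- inner_join(traits, climate, by = by, suffix = c("", ".clim"))
  if (nrow(merged) < 5) abort("Need at least 5 paired provenances.")

  grid <- tidyr::expand_grid(trait = trait_cols, climate_var = climate_cols)
  res <- purrr::pmap_dfr(grid, function(trait, climate_var) {
    x <- merged[[trait]]; y <- merged[[climate_var]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 5 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble(trait = trait, climate_var = climate_var,
                    n = n, rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", exact = n <= 10)
    )
    tibble(trait = trait, climate_var = climate_var,
           n = n, rho = unname(ct$estimate), p = ct$p.value)
  })
  if (anyNA(res$rho)) {
    warn(sprintf("%d pair(s) undefined (constant column or < 5 pairs); excluded from adjustment.",
                 sum(is.na(res$rho))))
  }
  if (family == "matrix") {
    res$p_holm <- NA_real_
    ok <- !is.na(res$p)
    res$p_holm[ok] <- p.adjust(res$p[ok], method = "holm")
  } else {
    res <- res |>
      group_by(.data$trait) |>
      mutate(p_holm = ifelse(is.na(.data$p), NA_real_,
                             p.adjust(.data$p, method = "holm"))) |>
      ungroup()
  }
  res$significant <- !is.na(res$p_holm) & res$p_holm < alpha
  structure(list(table = res, family = family, alpha = alpha),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("Spearman/Holm association matrix: %d tests (%s family), %d significant at %.2f\n",
              sum(!is.na(x$table$p)), x$family, sum(x$table$significant), x$alpha))
  invisible(x)
}

#' Tidiers for association matrices
#'
#' @param x An `association_matrix`.
#' @param ... Unused.
#' @return `tidy()`: the long pair table; `glance()`: one-row summary.
#' @method tidy association_matrix
#' @export
tidy.association_matrix <- function(x, ...) x$table

#' @rdname tidy.association_matrix
#' @method glance association_matrix
#' @export
glance.association_matrix <- function(x, ...) {
  tibble(n_tests = sum(!is.na(x$table$p)),
         n_significant = sum(x$table$significant),
         family = x$family, alpha = x$alpha)
}

#' Principal component analysis of provenance climate normals
#'
#' Eigen-decomposition of the *correlation* matrix of the climate variables
#' (via [stats::princomp()]), so variables on different scales contribute
#' equally. Returns provenance scores, per-component variance fractions, and
#' loadings expressed as variable-component correlations — the vectors of the
#' classical climate-ordination biplot.
#'
#' @param climate Tibble of provenance climate normals.
#' @param id_col Identifier column (default `"provenance_id"`); all other
#'   numeric columns enter the ordination.
#' @param vars Optional explicit set of variable columns.
#' @return A `climate_pca` object; `tidy()` gives loadings (as correlations),
#'   `glance()` variance fractions, `augment()` provenance scores.
#' @export
climate_pca <- function(climate, id_col = "provenance_id", vars = NULL) {
  check_columns(climate, id_col, "climate")
  vars <- vars %||% setdiff(names(climate)[vapply(climate, is.numeric, logical(1))], id_col)
  if (length(vars) < 2) abort("Need at least 2 climate variables.")
  m <- as.matrix(climate[, vars])
  if (nrow(m) < 3) abort("Need at least 3 provenances.")
  constant <- vars[apply(m, 2, function(col) sd(col) == 0 || anyNA(col))]
  if (length(constant) > 0) {
    abort(sprintf("Constant or incomplete climate variable(s): %s.",
                  paste(constant, collapse = ", ")))
  }
  pc <- princomp(m, cor = TRUE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  # with cor = TRUE, cor(variable, component) = eigenvector * component sd
  load_cor <- sweep(unclass(pc$loadings), 2, pc$sdev, `*`)
  scores <- as_tibble(unclass(pc$scores)) |>
    mutate(!!id_col := climate[[id_col]], .before = 1)
  structure(
    list(
      scores = scores,
      loadings = as_tibble(load_cor, rownames = "variable"),
      var_frac = tibble(component = colnames(pc$scores),
                        variance_fraction = unname(var_frac)),
      sdev = pc$sdev, vars = vars, id_col = id_col
    ),
    class = "climate_pca"
  )
}

#' @export
print.climate_pca <- function(x, ...) {
  cat(sprintf("Climate PCA (correlation matrix): %d variables, %d provenances; PC1+PC2 = %.1f%% of variance\n",
              length(x$vars), nrow(x$scores),
              100 * sum(x$var_frac$variance_fraction[1:2])))
  invisible(x)
}

#' Tidiers for climate PCA
#'
#' @param x A `climate_pca`.
#' @param ... Unused.
#' @return `tidy()`: loadings as variable-component correlations;
#'   `glance()`: variance fractions; `augment()`: provenance scores.
#' @method tidy climate_pca
#' @export
tidy.climate_pca <- function(x, ...) x$loadings

#' @rdname tidy.climate_pca
#' @method glance climate_pca
#' @export
glance.climate_pca <- function(x, ...) x$var_frac

#' @rdname tidy.climate_pca
#' @method augment climate_pca
#' @export
augment.climate_pca <- function(x, ...) x$scores
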