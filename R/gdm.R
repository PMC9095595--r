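#' Monotone I-spline basis
#'
#' Order-2 I-splines (integrated M-splines): `n_splines` monotone
#' nondecreasing basis functions with knots at the 0th/50th/100th percentiles
#' of the observed values (more interior knots are added at evenly spaced
#' percentiles when `n_splines > 3`). Each basis function is 0 at the minimum
#' and 1 at the maximum of the training range; evaluation outside the range is
#' clamped. Implemented through the standard identity expressing an I-spline
#' as a tail sum of one-order-higher B-splines.
#'
#' @param x Numeric values at which to evaluate the basis.
#' @param n_splines Number of basis functions (default 3).
#' @param knots Optional knot vector (min, interior..., max); computed from
#'   `x` quantiles when NULL.
#' @return Matrix `length(x) x n_splines`, values in `[0, 1]`, with the knot
#'   vector in `attr(, "knots")`.
#' @export
ispline_basis <- function(x, n_splines = 3, knots = NULL) {
  order_k <- 2L
  if (is.null(knots)) {
    stop_if(length(unique(x)) < 3, "need >= 3 distinct x values")
    probs <- seq(0, 1, length.out = n_splines)
    knots <- as.numeric(stats::quantile(x, probs, names = FALSE))
    stop_if(knots[1] == knots[length(knots)], "constant x: no spline range")
    # quantile ties would give coincident interior knots; nudge them apart
    for (i in 2:length(knots)) {
      if (knots[i] <= knots[i - 1]) {
        knots[i] <- knots[i - 1] +
          1e-8 * (knots[length(knots)] - knots[1])
      }
    }
  }
  stop_if(length(knots) != n_splines, "need n_splines knots (min..max)")
  bnd <- range(knots)
  xc <- pmin(pmax(x, bnd[1]), bnd[2])
  aug <- c(rep(bnd[1], order_k + 1), knots[-c(1, length(knots))],
           rep(bnd[2], order_k + 1))
  # B-splines of order k+1 = 3 on the augmented knots; n_b = n_splines + 1
  B <- splines::splineDesign(aug, xc, ord = order_k + 1, outer.ok = TRUE)
  n_b <- ncol(B)
  out <- matrix(0, length(xc), n_splines)
  for (i in seq_len(n_splines)) {
    out[, i] <- rowSums(B[, (i + 1):n_b, drop = FALSE])
  }
  # guard against tiny negative round-off and enforce the boundary values
  out <- pmin(pmax(out, 0), 1)
  out[xc >= bnd[2], ] <- 1
  attr(out, "knots") <- knots
  out
}

#' Site-pair table for dissimilarity regression
#'
#' One row per unordered site pair: the response dissimilarity, both sites'
#' predictor values and both sites' coordinates.
#'
#' @param dissim Square symmetric dissimilarity matrix (values in `[0, 1]`)
#'   with site dimnames, or a `dist`.
#' @param sites Data frame with `site`, predictor columns, `lon`, `lat`.
#' @param predictors Character vector of predictor column names.
#' @return Data frame with columns `site1`, `site2`, `response`,
#'   `<p>_1`/`<p>_2` per predictor, `lon_1`, `lat_1`, `lon_2`, `lat_2`.
#' @export
site_pair_table <- function(dissim, sites,
                            predictors = c("temperature", "precipitation")) {
  if (inherits(dissim, "dist")) dissim <- as.matrix(dissim)
  labs <- sites$site
  stop_if(!all(labs %in% rownames(dissim)), "dissimilarity matrix must be ",
          "labelled by site")
  out <- list()
  for (i in seq_len(length(labs) - 1)) {
    for (j in (i + 1):length(labs)) {
      y <- dissim[labs[i], labs[j]]
      stop_if(is.na(y) || y < 0 || y > 1,
              "response dissimilarity must be in [0, 1]")
      rec <- data.frame(site1 = labs[i], site2 = labs[j], response = y,
                        row.names = NULL)
      for (p in predictors) {
        rec[[paste0(p, "_1")]] <- sites[[p]][i]
        rec[[paste0(p, "_2")]] <- sites[[p]][j]
      }
      rec$lon_1 <- sites$lon[i]; rec$lat_1 <- sites$lat[i]
      rec$lon_2 <- sites$lon[j]; rec$lat_2 <- sites$lat[j]
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

# Design matrix of |I(x_i) - I(x_j)| spline differences per predictor, plus
# splined great-circle distance for geography. Knots are taken from the
# supplied fit (prediction) or computed from the table (fitting).
gdm_design <- function(table, predictors, geo, n_splines, knots = NULL) {
  cols <- list()
  kn <- list()
  for (p in predictors) {
    x1 <- table[[paste0(p, "_1")]]
    x2 <- table[[paste0(p, "_2")]]
    k <- if (!is.null(knots)) knots[[p]] else {
      xs <- c(x1, x2)
      as.numeric(stats::quantile(xs, seq(0, 1, length.out = n_splines),
                                 names = FALSE))
    }
    if (any(diff(k) <= 0)) {
      k <- k + seq(0, 1e-8 * max(abs(k) + 1), length.out = length(k))
    }
    b1 <- ispline_basis(x1, n_splines, knots = k)
    b2 <- ispline_basis(x2, n_splines, knots = k)
    m <- abs(b1 - b2)
    colnames(m) <- paste0(p, "_I", seq_len(n_splines))
    cols[[p]] <- m
    kn[[p]] <- k
  }
  if (geo) {
    d <- great_circle_km(as.matrix(table[c("lon_1", "lat_1")]),
                         as.matrix(table[c("lon_2", "lat_2")]))
    k <- if (!is.null(knots)) knots[["geography"]] else {
      as.numeric(stats::quantile(d, seq(0, 1, length.out = n_splines),
                                 names = FALSE))
    }
    if (any(diff(k) <= 0)) {
      k <- k + seq(0, 1e-8 * max(abs(k) + 1), length.out = length(k))
    }
    m <- ispline_basis(d, n_splines, knots = k)
    colnames(m) <- paste0("geography_I", seq_len(n_splines))
    cols[["geography"]] <- m
    kn[["geography"]] <- k
  }
  list(X = do.call(cbind, cols), knots = kn)
}

# GDM (binomial-type) deviance of dissimilarities y against fitted mu.
gdm_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

# Nonnegative IRLS for the negative-exponential link mu = 1 - exp(-eta),
# eta = theta0 + X theta, all theta >= 0. Returns coefficients and deviance.
gdm_irls <- function(X, y, max_iter = 100, tol = 1e-8) {
  Xi <- cbind(intercept = 1, X)
  mu <- pmin(pmax((y + mean(y)) / 2, 1e-4), 1 - 1e-4)
  dev <- gdm_deviance(y, mu)
  theta <- rep(0, ncol(Xi))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- -log(1 - mu)
    dmu <- 1 - mu                       # d mu / d eta
    vmu <- pmax(mu * (1 - mu), 1e-9)
    z <- eta + (y - mu) / dmu
    w <- dmu^2 / vmu
    sw <- sqrt(w)
    fit <- pracma::lsqnonneg(Xi * sw, z * sw)
    theta_new <- fit$x
    eta_new <- as.numeric(Xi %*% theta_new)
    mu_new <- 1 - exp(-eta_new)
    dev_new <- gdm_deviance(y, mu_new)
    step_ok <- is.finite(dev_new)
    if (step_ok && abs(dev - dev_new) < tol) {
      theta <- theta_new; mu <- mu_new; dev <- dev_new
      converged <- TRUE
      break
    }
    if (step_ok && dev_new <= dev + 1e-12) {
      theta <- theta_new; mu <- mu_new; dev <- dev_new
    } else if (step_ok) {
      # damped step: move halfway in coefficient space
      theta_half <- (theta + theta_new) / 2
      mu_half <- 1 - exp(-as.numeric(Xi %*% theta_half))
      dev_half <- gdm_deviance(y, mu_half)
      if (dev_half < dev) {
        theta <- theta_half; mu <- mu_half; dev <- dev_half
      } else {
        converged <- TRUE   # no further improvement possible
        break
      }
    } else break
  }
  list(theta = setNames(theta, colnames(Xi)), fitted = mu, deviance = dev,
       converged = converged)
}

#' Fit a generalized dissimilarity model
#'
#' Monotone regression of pairwise dissimilarities on site-level predictors:
#' `d_ij = 1 - exp(-eta_ij)` with
#' `eta_ij = beta0 + sum_p sum_k alpha_pk |I_pk(x_pi) - I_pk(x_pj)|`,
#' all coefficients nonnegative (monotone transforms). Geography enters as
#' great-circle distance passed through its own I-splines. Fitted by
#' iteratively reweighted least squares with nonnegativity-constrained
#' solves; deviance is the binomial-type GDM deviance with fitted values
#' clamped to `[1e-9, 1 - 1e-9]`; convergence when the deviance change falls
#' below `1e-8` (at most 100 iterations; non-convergence is flagged).
#'
#' @param dissim Square dissimilarity matrix (or `dist`) in `[0, 1]`.
#' @param sites Data frame with `site`, predictor columns, `lon`, `lat`.
#' @param predictors Site-level predictor columns (default temperature and
#'   precipitation).
#' @param geo Include the geographic-distance predictor (default TRUE).
#' @param n_splines I-splines per predictor (default 3, knots at
#'   min/median/max).
#' @return A `gdm_fit`: intercept, per-predictor spline coefficients, knots,
#'   null and model deviance, `deviance_explained` (%), fitted values,
#'   convergence flag, and the site-pair table used.
#' @export
fit_gdm <- function(dissim, sites,
                    predictors = c("temperature", "precipitation"),
                    geo = TRUE, n_splines = 3) {
  table <- site_pair_table(dissim, sites, predictors)
  stop_if(nrow(table) < 6, "need >= 6 site pairs, got ", nrow(table))
  des <- gdm_design(table, predictors, geo, n_splines)
  y <- table$response
  fit <- gdm_irls(des$X, y)
  null_fit <- gdm_irls(matrix(0, length(y), 0), y)
  dev_expl <- 100 * (1 - fit$deviance / null_fit$deviance)
  structure(list(
    intercept = fit$theta[["intercept"]],
    coefficients = fit$theta[-1],
    predictors = c(predictors, if (geo) "geography"),
    knots = des$knots, n_splines = n_splines, geo = geo,
    null_deviance = null_fit$deviance, deviance = fit$deviance,
    deviance_explained = dev_expl, fitted = fit$fitted,
    converged = fit$converged, sites = sites, table = table,
    predictor_cols = predictors), class = "gdm_fit")
}

#' @export
print.gdm_fit <- function(x, ...) {
  cat(sprintf("gdm_fit: %d pairs, deviance explained %.1f%%%s\n",
              nrow(x$table), x$deviance_explained,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' Predicted dissimilarities from a fitted GDM
#'
#' @param object A `gdm_fit`.
#' @param newdata Optional site-pair table (default: training table).
#' @param ... Unused.
#' @return Predicted dissimilarities in `[0, 1)`.
#' @export
predict.gdm_fit <- function(object, newdata = NULL, ...) {
  table <- newdata %||% object$table
  des <- gdm_design(table, object$predictor_cols, object$geo,
                    object$n_splines, knots = object$knots)
  eta <- object$intercept + as.numeric(des$X %*% object$coefficients)
  1 - exp(-eta)
}

#' Permutation importance and significance of a fitted GDM
#'
#' Importance of a predictor: its site-level values are permuted across
#' sites (coordinates jointly for geography), the site-pair table rebuilt,
#' the model refit, and the percent change in deviance explained recorded;
#' the importance is the mean over permutations. Full-model significance:
#' all predictors permuted together, p = proportion of permutations whose
#' deviance explained is >= the observed one.
#'
#' @param fit A `gdm_fit`.
#' @param n_perm Number of permutations (study default 1000).
#' @param seed Integer seed (required).
#' @return List with `importance` (named %, mean over permutations),
#'   `p_value`, `observed_deviance_explained`, `null_deviance_explained`
#'   (vector over all-predictor permutations).
#' @export
gdm_importance_and_significance <- function(fit, n_perm = 1000, seed) {
  stop_if(missing(seed), "an explicit seed is required")
  stop_if(!inherits(fit, "gdm_fit"), "need a gdm_fit")
  sites <- fit$sites
  preds <- fit$predictor_cols
  dissim <- dissim_from_table(fit$table, sites$site)
  refit_dev <- function(sites_perm) {
    f <- fit_gdm(dissim, sites_perm, predictors = preds, geo = fit$geo,
                 n_splines = fit$n_splines)
    f$deviance_explained
  }
  perm_sites <- function(s, what, perm) {
    if (what == "geography") {
      s$lon <- s$lon[perm]; s$lat <- s$lat[perm]
    } else {
      s[[what]] <- s[[what]][perm]
    }
    s
  }
  obs <- fit$deviance_explained
  withr::with_seed(seed, {
    importance <- setNames(numeric(length(fit$predictors)), fit$predictors)
    for (p in fit$predictors) {
      drops <- vapply(seq_len(n_perm), function(i) {
        perm <- sample.int(nrow(sites))
        dev_p <- refit_dev(perm_sites(sites, p, perm))
        100 * (obs - dev_p) / max(obs, .Machine$double.eps)
      }, 0)
      importance[p] <- mean(drops)
    }
    null_dev <- vapply(seq_len(n_perm), function(i) {
      s <- sites
      for (p in fit$predictors) s <- perm_sites(s, p, sample.int(nrow(sites)))
      refit_dev(s)
    }, 0)
    p_value <- mean(null_dev >= obs)
    list(importance = importance, p_value = p_value,
         observed_deviance_explained = obs,
         null_deviance_explained = null_dev)
  })
}

# Rebuild the square response matrix from a site-pair table.
dissim_from_table <- function(table, sites) {
  m <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  for (k in seq_len(nrow(table))) {
    m[table$site1[k], table$site2[k]] <- table$response[k]
    m[table$site2[k], table$site1[k]] <- table$response[k]
  }
  m
}

#' GDM over a tree sample of pairwise beta matrices
#'
#' Fits a GDM per tree for one beta-diversity component and aggregates the
#' deviances, deviance explained, permutation importances and the p-value
#' ratio (proportion of trees with p < 0.05).
#'
#' @param beta_df Pairwise output of [beta_over_sample()].
#' @param component `"sor"`, `"sim"` or `"sne"`.
#' @param sites Site predictor table (see [fit_gdm()]).
#' @param n_perm Permutations per tree for importance/significance.
#' @param seed Integer seed.
#' @param mcc Include the `"MCC"` rows as a separately reported fit.
#' @return List with `summary` (one-row data frame of means and SDs),
#'   `per_tree` (data frame), `mcc` (row or NULL).
#' @export
gdm_over_sample <- function(beta_df, component, sites, n_perm = 100, seed,
                            mcc = TRUE) {
  stop_if(missing(seed), "an explicit seed is required")
  ids <- setdiff(unique(beta_df$tree_id), "MCC")
  one <- function(id, sd_i) {
    m <- beta_matrix(beta_df, id, component, sites$site)
    f <- fit_gdm(m, sites)
    imp <- gdm_importance_and_significance(f, n_perm = n_perm, seed = sd_i)
    data.frame(tree_id = id, deviance = f$deviance,
               deviance_explained = f$deviance_explained,
               p_value = imp$p_value,
               imp_geography = imp$importance[["geography"]],
               imp_temperature = imp$importance[["temperature"]],
               imp_precipitation = imp$importance[["precipitation"]],
               converged = f$converged, row.names = NULL)
  }
  per_tree <- do.call(rbind, lapply(seq_along(ids), function(i) {
    one(ids[i], derive_seed(seed, i))
  }))
  mcc_row <- NULL
  if (mcc && "MCC" %in% beta_df$tree_id) {
    mcc_row <- one("MCC", derive_seed(seed, 0))
  }
  summary <- data.frame(
    component = component,
    deviance_mean = mean(per_tree$deviance),
    deviance_sd = stats::sd(per_tree$deviance),
    deviance_explained_mean = mean(per_tree$deviance_explained),
    deviance_explained_sd = stats::sd(per_tree$deviance_explained),
    p_value_ratio = pvalue_ratio(per_tree$p_value),
    imp_geography_mean = mean(per_tree$imp_geography),
    imp_geography_sd = stats::sd(per_tree$imp_geography),
    imp_temperature_mean = mean(per_tree$imp_temperature),
    imp_temperature_sd = stats::sd(per_tree$imp_temperature),
    imp_precipitation_mean = mean(per_tree$imp_precipitation),
    imp_precipitation_sd = stats::sd(per_tree$imp_precipitation),
    row.names = NULL)
  list(summary = summary, per_tree = per_tree, mcc = mcc_row)
}

#' Fitted I-spline transform curves for plotting
#'
#' @param fit A `gdm_fit`.
#' @param n_points Points per predictor curve.
#' @return Data frame: predictor, x, f (partial monotone transform).
#' @export
gdm_spline_curves <- function(fit, n_points = 200) {
  out <- list()
  for (p in fit$predictors) {
    k <- fit$knots[[p]]
    x <- seq(min(k), max(k), length.out = n_points)
    B <- ispline_basis(x, fit$n_splines, knots = k)
    al <- fit$coefficients[paste0(p, "_I", seq_len(fit$n_splines))]
    out[[p]] <- data.frame(predictor = p, x = x,
                           f = as.numeric(B %*% al), row.names = NULL)
  }
  do.call(rbind, out)
}
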