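# Gaussian-likelihood BIC used for model comparison: n*ln(RSS/n) + k*ln(n),
# with k counting regression coefficients plus the error variance. Only
# differences in BIC matter downstream.
gaussian_bic <- function(fit) {
  rss <- sum(stats::residuals(fit)^2)
  n <- length(stats::residuals(fit))
  k <- length(stats::coef(fit)) + 1
  n * log(rss / n) + k * log(n)
}

fit_one_spec <- function(formula, dat) {
  fit <- stats::lm(formula, data = dat)
  stop_if(anyNA(stats::coef(fit)), "rank-deficient design; collinear terms: ",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                collapse = ", "))
  res <- stats::residuals(fit)
  shapiro_p <- if (length(unique(round(res, 12))) > 2) {
    stats::shapiro.test(res)$p.value
  } else NA_real_
  list(coefficients = stats::coef(fit),
       r2 = summary(fit)$r.squared,
       bic = gaussian_bic(fit),
       shapiro_p = shapiro_p,
       normal_ok = is.na(shapiro_p) || shapiro_p >= 0.05,
       n = length(res))
}

#' Fit the three candidate climate models for one tree's SES values
#'
#' Ordinary least squares of the per-site SES values on the site-level
#' temperature and precipitation PC1 scores: a null (intercept-only) model,
#' an additive model, and a full model with the interaction. Residual
#' normality is screened by Shapiro-Wilk at alpha = 0.05; downstream
#' aggregation retains only fits that pass.
#'
#' @param ses_values Named numeric vector of SES values (names = sites);
#'   missing values are dropped.
#' @param temperature,precipitation Named numeric site-level predictor scores.
#' @return List of three fits (`null`, `additive`, `full`), each with
#'   `coefficients`, `r2`, `bic`, `shapiro_p`, `normal_ok`, `n`.
#' @export
fit_candidates <- function(ses_values, temperature, precipitation) {
  sites <- names(ses_values)
  stop_if(is.null(sites), "ses_values must be named by site")
  dat <- data.frame(ses = as.numeric(ses_values),
                    temp = as.numeric(temperature[sites]),
                    prec = as.numeric(precipitation[sites]))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  stop_if(nrow(dat) < 4, "need >= 4 complete site rows, got ", nrow(dat))
  list(null = fit_one_spec(ses ~ 1, dat),
       additive = fit_one_spec(ses ~ temp + prec, dat),
       full = fit_one_spec(ses ~ temp * prec, dat))
}

#' BIC model selection with the delta-BIC < 2 rule
#'
#' @param fits Named list of fits carrying a `bic` element (e.g. the output
#'   of [fit_candidates()]), or a named numeric vector of BIC values.
#' @return List with `delta_bic` (named), `best` (name of the lowest-BIC
#'   model; ties broken by input order) and `equally_probable` (names with
#'   delta-BIC < 2).
#' @export
select_by_bic <- function(fits) {
  bics <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) f$bic, 0)
  stop_if(length(bics) < 1, "need at least one fit")
  delta <- bics - min(bics)
  list(delta_bic = delta,
       best = names(delta)[which.min(delta)],
       equally_probable = names(delta)[delta < 2])
}

#' Regress SES values on climate across a tree sample
#'
#' Runs [fit_candidates()] for every tree of a [run_alpha()] result (one
#' metric at a time) and returns the per-tree fits plus the MCC fit.
#'
#' @param alpha_df Output of [run_alpha()].
#' @param metric `"pd"`, `"mpd"` or `"mntd"`.
#' @param temperature,precipitation Named site-level predictor scores.
#' @return List with `per_tree` (list of candidate-fit triples), `mcc`
#'   (triple or NULL).
#' @export
fit_candidates_over_trees <- function(alpha_df, metric, temperature,
                                      precipitation) {
  g <- alpha_df[alpha_df$metric == metric, ]
  ids <- setdiff(unique(g$tree_id), "MCC")
  per_tree <- lapply(ids, function(id) {
    gi <- g[g$tree_id == id, ]
    fit_candidates(setNames(gi$ses, gi$site), temperature, precipitation)
  })
  names(per_tree) <- ids
  mcc <- NULL
  if ("MCC" %in% g$tree_id) {
    gm <- g[g$tree_id == "MCC", ]
    mcc <- fit_candidates(setNames(gm$ses, gm$site), temperature,
                          precipitation)
  }
  list(per_tree = per_tree, mcc = mcc)
}

#' Across-tree model comparison summary
#'
#' For each candidate specification: mean and SD (over the trees whose fit
#' met the residual-normality screen) of R-squared, delta-BIC and each slope
#' coefficient, the number of retained trees, and the MCC-tree values.
#'
#' @param fits Output of [fit_candidates_over_trees()].
#' @return Data frame, one row per model specification.
#' @export
summarize_over_trees <- function(fits) {
  specs <- c("null", "additive", "full")
  per_tree <- fits$per_tree
  # delta-BIC within each tree's candidate set
  deltas <- lapply(per_tree, function(tr) select_by_bic(tr)$delta_bic)
  out <- lapply(specs, function(sp) {
    keep <- vapply(per_tree, function(tr) isTRUE(tr[[sp]]$normal_ok), TRUE)
    r2 <- vapply(per_tree[keep], function(tr) tr[[sp]]$r2, 0)
    db <- vapply(deltas[keep], function(d) d[[sp]], 0)
    coefs <- do.call(rbind, lapply(per_tree[keep], function(tr) {
      tr[[sp]]$coefficients
    }))
    row <- data.frame(model = sp, n_trees_retained = sum(keep),
                      r2_mean = mean(r2), r2_sd = stats::sd(r2),
                      delta_bic_mean = mean(db), delta_bic_sd = stats::sd(db),
                      row.names = NULL)
    if (!is.null(coefs) && ncol(coefs) > 1) {
      for (cn in setdiff(colnames(coefs), "(Intercept)")) {
        row[[paste0("beta_", gsub(":", "_x_", cn), "_mean")]] <-
          mean(coefs[, cn])
        row[[paste0("beta_", gsub(":", "_x_", cn), "_sd")]] <-
          stats::sd(coefs[, cn])
      }
    }
    if (!is.null(fits$mcc)) {
      row$r2_mcc <- fits$mcc[[sp]]$r2
      row$delta_bic_mcc <- select_by_bic(fits$mcc)$delta_bic[[sp]]
    }
    row
  })
  merged <- Reduce(function(a, b) merge(a, b, all = TRUE, sort = FALSE), out)
  merged[match(specs, merged$model), ]
}

#' Proportion of significant permutation tests across trees
#'
#' @param p_values Numeric vector of per-tree p-values.
#' @param alpha Significance level (default 0.05).
#' @return Proportion of trees with `p < alpha`.
#' @export
pvalue_ratio <- function(p_values, alpha = 0.05) {
  stop_if(length(p_values) == 0, "no p-values supplied")
  mean(p_values < alpha, na.rm = TRUE)
}
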