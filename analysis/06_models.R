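# Stage 6 -- inference.
# (a) For each alpha metric, the per-tree SES values are regressed on the
# temperature and precipitation PC1 scores under three candidate models
# (null / additive / full-with-interaction), screened for residual
# normality, and compared by BIC (delta-BIC < 2 = equally probable).
# (b) Pairwise dissimilarities (sor, sim, sne) are modelled per tree by a
# generalized dissimilarity model with monotone I-splines over temperature,
# precipitation and great-circle distance; permutation importance and
# full-model significance are aggregated into the p-value ratio.

source("analysis/00_config.R")

comm <- read_community_matrix(file.path(DATA, "community.csv"))
alpha <- utils::read.csv(file.path(OUT, "alpha_ses_long.csv"),
                         colClasses = c(tree_id = "character"))
pw <- utils::read.csv(file.path(OUT, "beta_pairwise_long.csv"),
                      colClasses = c(tree_id = "character"))
sites <- utils::read.csv(file.path(OUT, "site_predictors.csv"))
temp <- setNames(sites$temperature, sites$site)
prec <- setNames(sites$precipitation, sites$site)

cat("BIC model comparison (mean over normality-passing trees):\n")
for (met in c("pd", "mpd", "mntd")) {
  fits <- fit_candidates_over_trees(alpha, met, temp, prec)
  tab <- summarize_over_trees(fits)
  wcsv(tab, sprintf("model_comparison_%s.csv", met))
  best <- tab$model[which.min(tab$delta_bic_mean)]
  cat(sprintf("  SES.%s: best = %s (R2 = %.2f, %d trees retained)\n",
              toupper(met), best, tab$r2_mean[tab$model == best],
              tab$n_trees_retained[tab$model == best]))
}

cat("Generalized dissimilarity models (per-tree, aggregated):\n")
gdm_rows <- list()
for (comp in c("sor", "sim", "sne")) {
  g <- gdm_over_sample(pw, comp, sites, n_perm = N_PERM,
                       seed = derive_seed(SEED, 3))
  gdm_rows[[comp]] <- g$summary
  wcsv(g$per_tree, sprintf("gdm_per_tree_%s.csv", comp))
  imp <- c(geography = g$summary$imp_geography_mean,
           temperature = g$summary$imp_temperature_mean,
           precipitation = g$summary$imp_precipitation_mean)
  cat(sprintf(
    "  %s: deviance explained %.1f%%, p-value ratio %.2f, top predictor %s\n",
    comp, g$summary$deviance_explained_mean, g$summary$p_value_ratio,
    names(imp)[which.max(imp)]))
}
wcsv(do.call(rbind, gdm_rows), "gdm_summary.csv")

# fitted spline transforms of the MCC-tree sor model, for plotting
mcc_m <- beta_matrix(pw, "MCC", "sor", sites$site)
wcsv(gdm_spline_curves(fit_gdm(mcc_m, sites)), "gdm_spline_curves_sor.csv")
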