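# Stage 5 -- climate and geography predictors.
# Deduplicates sampling points by raster pixel, averages the 19 bioclim-style
# variables per site, reduces the temperature- and precipitation-related
# subsets to their first principal components, and tabulates inter-site
# great-circle distances.

source("analysis/00_config.R")

points <- utils::read.csv(file.path(DATA, "climate_points.csv"))
comm <- read_community_matrix(file.path(DATA, "community.csv"))
elev <- setNames(comm$elevation, comm$sites)

preds <- site_predictors(points, elevation = elev)
wcsv(preds$sites, "site_predictors.csv")
dists <- geographic_distances(
  preds$sites,
  temperature = setNames(preds$sites$temperature, preds$sites$site),
  precipitation = setNames(preds$sites$precipitation, preds$sites$site))
wcsv(dists, "site_distances.csv")

cat(sprintf("Retained %d of %d points after pixel deduplication.\n",
            preds$n_points_retained, nrow(points)))
cat(sprintf("PC1 explains %.1f%% of the temperature subset, %.1f%% of the\n",
            100 * preds$pca_temperature$var_explained,
            100 * preds$pca_precipitation$var_explained))
cat("precipitation subset.\n")
cat(sprintf("Elevation vs temperature PC1: Pearson %.3f, Spearman %.3f.\n",
            preds$diagnostics$pearson[1], preds$diagnostics$spearman[1]))
cat(sprintf("Adjacent-site distances span %.1f-%.1f km.\n",
            min(dists$geo_km[abs(match(dists$site2, preds$sites$site) -
                                   match(dists$site1, preds$sites$site)) == 1]),
            max(dists$geo_km[abs(match(dists$site2, preds$sites$site) -
                                   match(dists$site1, preds$sites$site)) == 1])))
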