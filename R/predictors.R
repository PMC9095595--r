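#' Default bioclim-style variable subsets
#'
#' Conventional split of the 19 bioclim summary variables into the
#' temperature-related (bio1-bio11) and precipitation-related (bio12-bio19)
#' subsets.
#'
#' @return List with `temperature` and `precipitation` character vectors.
#' @export
bioclim_subsets <- function() {
  list(temperature = paste0("bio", 1:11),
       precipitation = paste0("bio", 12:19))
}

#' Deduplicate sampling points by raster pixel
#'
#' Keeps exactly one point (the first in input order) per occupied pixel of a
#' regular lon/lat grid, so spatially pseudo-replicated climate extractions do
#' not enter the site means twice.
#'
#' @param points Data frame with `site`, `lon`, `lat` and climate columns.
#' @param resolution Grid resolution in decimal degrees (default 3 arc-second,
#'   1/1200 degree).
#' @param origin Grid origin `c(lon, lat)`, default `c(0, 0)`.
#' @return The retained subset of `points`.
#' @export
dedup_by_pixel <- function(points, resolution = 1 / 1200, origin = c(0, 0)) {
  stop_if(!all(c("site", "lon", "lat") %in% names(points)),
          "points need columns site, lon, lat")
  stop_if(anyNA(points$lon) || anyNA(points$lat),
          "missing coordinates in points table")
  px <- floor((points$lon - origin[1]) / resolution)
  py <- floor((points$lat - origin[2]) / resolution)
  keep <- !duplicated(paste(px, py))
  points[keep, , drop = FALSE]
}

#' Per-site means of climate variables
#'
#' @param points Deduplicated points table (`site` column plus variables).
#' @param vars Variable columns to average; default all numeric columns except
#'   lon/lat.
#' @return Data frame, one row per site (input site order), site means per
#'   variable plus `lon`/`lat` centroids when present.
#' @export
site_climate_means <- function(points, vars = NULL) {
  stop_if(!"site" %in% names(points), "points need a 'site' column")
  if (is.null(vars)) {
    vars <- setdiff(names(points)[vapply(points, is.numeric, TRUE)],
                    c("lon", "lat"))
  }
  sites <- unique(points$site)
  out <- do.call(rbind, lapply(sites, function(s) {
    g <- points[points$site == s, , drop = FALSE]
    stop_if(nrow(g) == 0, "site with zero points: ", s)
    row <- as.data.frame(lapply(g[vars], mean))
    row$site <- s
    if (all(c("lon", "lat") %in% names(g))) {
      row$lon <- mean(g$lon); row$lat <- mean(g$lat)
    }
    row
  }))
  out[c("site", setdiff(names(out), "site"))]
}

#' First principal component of a standardized variable subset
#'
#' Variables are z-scored (mean 0, SD 1); constant variables are dropped with
#' a warning; the leading eigenvector of the correlation structure gives the
#' site scores. The sign is fixed so that PC1 correlates positively with the
#' mean of the standardized subset variables.
#'
#' @param site_table Data frame with a `site` column and the variables.
#' @param variable_subset Character vector of variable column names.
#' @return List with `scores` (named by site), `loadings` (unit norm),
#'   `var_explained` (proportion in `[0, 1]`), `dropped`.
#' @export
pca_first_axis <- function(site_table, variable_subset) {
  stop_if(nrow(site_table) < 2, "PCA needs >= 2 sites")
  miss <- setdiff(variable_subset, names(site_table))
  stop_if(length(miss) > 0, "missing variables: ", paste(miss, collapse = ", "))
  x <- as.matrix(site_table[variable_subset])
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping constant variable(s): ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  stop_if(ncol(x) < 2, "need >= 2 non-constant variables")
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  ref <- rowMeans(z)
  if (stats::sd(ref) == 0) ref <- z[, 1]   # mutually cancelling variables
  if (stats::cor(scores, ref) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  list(scores = setNames(scores, site_table$site),
       loadings = loadings,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
       dropped = dropped)
}

#' Great-circle distance between two lon/lat points
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param p1,p2 Numeric `c(lon, lat)` in decimal degrees (or two-column
#'   matrices).
#' @return Distance in kilometres.
#' @export
great_circle_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371000) / 1000
}

#' Inter-site distance set
#'
#' Geographic great-circle distances between site centroids plus absolute
#' differences of the temperature and precipitation PC1 scores.
#'
#' @param centroids Data frame with `site`, `lon`, `lat`.
#' @param temperature,precipitation Optional named score vectors (site names).
#' @return Data frame of unordered site pairs with `geo_km` and, when scores
#'   are given, `d_temperature`, `d_precipitation`.
#' @export
geographic_distances <- function(centroids, temperature = NULL,
                                 precipitation = NULL) {
  stop_if(anyNA(centroids$lon) || anyNA(centroids$lat),
          "missing centroid coordinates")
  n <- nrow(centroids)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rec <- data.frame(
        site1 = centroids$site[i], site2 = centroids$site[j],
        geo_km = great_circle_km(c(centroids$lon[i], centroids$lat[i]),
                                 c(centroids$lon[j], centroids$lat[j])),
        row.names = NULL)
      if (!is.null(temperature)) {
        rec$d_temperature <-
          abs(temperature[[centroids$site[i]]] -
              temperature[[centroids$site[j]]])
      }
      if (!is.null(precipitation)) {
        rec$d_precipitation <-
          abs(precipitation[[centroids$site[i]]] -
              precipitation[[centroids$site[j]]])
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Build the site-level predictor table from climate points
#'
#' Pipeline: deduplicate points by pixel, average per site, run separate PCAs
#' on the temperature- and precipitation-related subsets, and collect site
#' centroids. Alternatively (`pca_on = "points"`) the PCA is run on the
#' deduplicated points and the scores averaged per site.
#'
#' @param points Climate points table (`site`, `lon`, `lat`, variables).
#' @param subsets List with `temperature` and `precipitation` variable names
#'   (default [bioclim_subsets()]).
#' @param resolution,origin Pixel grid, see [dedup_by_pixel()].
#' @param pca_on `"site_means"` (default) or `"points"`.
#' @param elevation Optional named elevation vector for diagnostics.
#' @return List with `sites` (data frame: site, temperature, precipitation,
#'   lon, lat), `pca_temperature`, `pca_precipitation`, `n_points_retained`,
#'   and `diagnostics` (elevation correlations, Pearson and Spearman, when
#'   elevations are given).
#' @export
site_predictors <- function(points, subsets = bioclim_subsets(),
                            resolution = 1 / 1200, origin = c(0, 0),
                            pca_on = c("site_means", "points"),
                            elevation = NULL) {
  pca_on <- match.arg(pca_on)
  overlap <- intersect(subsets$temperature, subsets$precipitation)
  stop_if(length(overlap) > 0, "subsets must partition the variable list; ",
          "overlap: ", paste(overlap, collapse = ", "))
  pts <- dedup_by_pixel(points, resolution, origin)
  means <- site_climate_means(pts)
  if (pca_on == "site_means") {
    pca_t <- pca_first_axis(means, subsets$temperature)
    pca_p <- pca_first_axis(means, subsets$precipitation)
    score_t <- pca_t$scores
    score_p <- pca_p$scores
  } else {
    pca_t <- pca_first_axis(pts, subsets$temperature)
    pca_p <- pca_first_axis(pts, subsets$precipitation)
    score_t <- tapply(pca_t$scores, pts$site, mean)[means$site]
    score_p <- tapply(pca_p$scores, pts$site, mean)[means$site]
  }
  sites <- data.frame(site = means$site,
                      temperature = as.numeric(score_t),
                      precipitation = as.numeric(score_p),
                      lon = means$lon, lat = means$lat, row.names = NULL)
  diagnostics <- NULL
  if (!is.null(elevation)) {
    el <- elevation[sites$site]
    diagnostics <- data.frame(
      predictor = c("temperature", "precipitation"),
      pearson = c(stats::cor(el, sites$temperature),
                  stats::cor(el, sites$precipitation)),
      spearman = c(stats::cor(el, sites$temperature, method = "spearman"),
                   stats::cor(el, sites$precipitation, method = "spearman")))
  }
  list(sites = sites, pca_temperature = pca_t, pca_precipitation = pca_p,
       n_points_retained = nrow(pts), diagnostics = diagnostics)
}
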