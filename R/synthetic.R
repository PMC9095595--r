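#' Default synthetic study configuration
#'
#' The defaults emulate the study design the package targets: 7 ordered sites
#' spanning 0-3000 m, ~150 species in ~50 genera, a monotone temperature
#' lapse, a hump-shaped precipitation profile, Brownian-evolved thermal
#' niches (phylogenetic niche conservatism) and declining richness with
#' elevation.
#'
#' @param seed Integer seed driving every stochastic stage (required).
#' @param assembly `"filtering"`, `"competition"` or `"neutral"`.
#' @param ... Overrides for any default field.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed, assembly = c("filtering", "competition",
                                               "neutral"), ...) {
  stop_if(missing(seed), "an explicit seed is required")
  assembly <- match.arg(assembly)
  cfg <- list(
    n_sites = 7,
    elevation = seq(0, 3000, length.out = 7),
    n_genera = 50,
    n_species = 150,
    birth = 0.1,                 # backbone birth rate (per lineage per My)
    death = 0,                   # backbone extinction rate
    backbone_depth = 120,        # crown age of the backbone (My)
    crown_fraction = 0.5,
    sigma2 = 0.4,                # Brownian rate of thermal optima (degC^2/My)
    root_optimum = 17,           # ancestral thermal optimum (degC)
    sea_level_temp = 25,         # mean annual temperature at 0 m (degC)
    lapse = 5.5 / 1000,          # temperature lapse (degC per m)
    precip_base = 1100,          # mm/yr away from the hump
    precip_hump = 1700,          # extra mm/yr at the hump peak
    precip_peak_elev = 1500,     # elevation of the precipitation hump (m)
    precip_width = 900,          # hump width (m)
    assembly = assembly,
    tau = 2,                     # filter width (degC)
    delta = 60,                  # limiting-similarity radius (My, patristic)
    richness = round(seq(45, 8, length.out = 7)),
    n_points_per_site = 20,
    seed = as.integer(seed))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  stop_if(length(unknown) > 0, "unknown config fields: ",
          paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stop_if(cfg$birth <= 0, "birth rate must be > 0")
  stop_if(cfg$n_species < cfg$n_genera, "need n_species >= n_genera")
  structure(cfg, class = "scenario_config")
}

#' Simulate an ultrametric backbone genus tree
#'
#' Birth-death tree conditioned on the number of extant genera
#' (via [ape::rphylo()]), rescaled to a fixed crown depth.
#'
#' @param n_genera Number of genus tips.
#' @param birth,death Speciation and extinction rates (> 0 / >= 0).
#' @param depth Crown depth the tree is rescaled to (My).
#' @param seed Integer seed.
#' @return Ultrametric [ape::phylo] with tips `g01, g02, ...`.
#' @export
simulate_backbone <- function(n_genera, birth = 0.1, death = 0, depth = 120,
                              seed) {
  stop_if(missing(seed), "an explicit seed is required")
  stop_if(n_genera < 2, "need >= 2 genera")
  withr::with_seed(seed, {
    tr <- ape::rphylo(n_genera, birth = birth, death = death)
    tr$edge.length <- tr$edge.length * (depth / max(tip_depths(tr)))
    tr$tip.label <- sprintf("g%02d", seq_len(n_genera))
    tr
  })
}

#' Assign species to genera
#'
#' Every genus receives at least one species; the remaining species are
#' spread multinomially (uniform probabilities).
#'
#' @param backbone Genus-level tree (tips = genus labels).
#' @param n_species Total species count (>= number of genera).
#' @param seed Integer seed.
#' @return Data frame `species`, `genus`.
#' @export
simulate_assignment <- function(backbone, n_species, seed) {
  stop_if(missing(seed), "an explicit seed is required")
  genera <- backbone$tip.label
  stop_if(n_species < length(genera), "need n_species >= n_genera")
  withr::with_seed(seed, {
    extra <- as.integer(stats::rmultinom(1, n_species - length(genera),
                                         rep(1, length(genera))))
    counts <- 1L + extra
    data.frame(
      species = unlist(lapply(seq_along(genera), function(i) {
        sprintf("%s_sp%02d", genera[i], seq_len(counts[i]))
      })),
      genus = rep(genera, counts), row.names = NULL)
  })
}

#' Evolve species thermal optima by Brownian motion
#'
#' Brownian motion with rate `sigma2` along the branches of a species-level
#' tree, so closer relatives carry more similar optima (phylogenetic niche
#' conservatism).
#'
#' @param tree Species-level [ape::phylo].
#' @param sigma2 Brownian rate (degC^2 per branch-length unit).
#' @param root_value Ancestral optimum (degC).
#' @param seed Integer seed.
#' @return Named numeric vector of tip optima.
#' @export
evolve_thermal_optima <- function(tree, sigma2 = 0.4, root_value = 17, seed) {
  stop_if(missing(seed), "an explicit seed is required")
  stop_if(sigma2 < 0, "sigma2 must be >= 0")
  withr::with_seed(seed, {
    x <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2),
                         root.value = root_value)
    setNames(as.numeric(x), names(x))
  })
}

#' Site-level climate gradient (19 bioclim-style variables)
#'
#' Temperature-related variables (bio1-bio11) are affine transforms of the
#' site temperature given by the lapse rate, with small site-level noise
#' (redrawn, deterministically under the seed, if it would break strict
#' monotonicity along elevation). Precipitation-related variables
#' (bio12-bio19) follow a Gaussian hump over elevation plus a seasonality
#' term. Noise is shared within each subset so PCA finds a dominant first
#' axis.
#'
#' @param config A `scenario_config`.
#' @return Data frame: site, elevation, site_temp (degC), site_precip
#'   (mm/yr), bio1..bio19.
#' @export
make_gradient <- function(config) {
  cfg <- config
  elev <- cfg$elevation
  n <- length(elev)
  temp <- cfg$sea_level_temp - cfg$lapse * elev
  precip <- cfg$precip_base +
    cfg$precip_hump * exp(-((elev - cfg$precip_peak_elev) /
                              cfg$precip_width)^2)
  seasonality <- 80 - 15 * (elev / 1000)   # drier-season contrast, declining
  withr::with_seed(derive_seed(cfg$seed, 11), {
    sites <- sprintf("s%04d", round(elev))
    out <- data.frame(site = sites, elevation = elev, site_temp = temp,
                      site_precip = precip, row.names = NULL)
    for (j in 1:11) {
      a <- stats::runif(1, -3, 3)
      b <- stats::runif(1, 0.6, 1.4)
      repeat {
        v <- a + b * temp + stats::rnorm(n, 0, 0.3)
        if (all(diff(v) < 0)) break    # strictly decreasing with elevation
      }
      out[[paste0("bio", j)]] <- v
    }
    for (j in 12:19) {
      base <- if (j %% 2 == 0) precip else precip / 4 + seasonality * 3
      b <- stats::runif(1, 0.6, 1.4)
      out[[paste0("bio", j)]] <- b * base +
        stats::rnorm(n, 0, 0.02 * mean(base))
    }
    out
  })
}

#' Per-point climate table around the site values
#'
#' Places site centroids along the mountain slope (unequal adjacent
#' distances, as in real transects) and jitters `n_points_per_site` sampling
#' points around each centroid, with point-level climate noise around the
#' site values.
#'
#' @param gradient Output of [make_gradient()].
#' @param config A `scenario_config`.
#' @return Data frame: site, lon, lat, bio1..bio19.
#' @export
make_climate_points <- function(gradient, config) {
  cfg <- config
  n <- nrow(gradient)
  withr::with_seed(derive_seed(cfg$seed, 12), {
    # cumulative, uneven spacing up the slope (km), converted to degrees
    step_km <- stats::runif(n - 1, 2, 12)
    along <- c(0, cumsum(step_km))
    lon <- -97.15 + along / (111.32 * cos(19.5 * pi / 180)) * 0.8
    lat <- 19.45 + along / 111.19 * 0.2
    vars <- paste0("bio", 1:19)
    out <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- cfg$n_points_per_site
      pt <- data.frame(
        site = gradient$site[i],
        lon = lon[i] + stats::runif(k, -0.004, 0.004),
        lat = lat[i] + stats::runif(k, -0.004, 0.004))
      for (v in vars) {
        pt[[v]] <- gradient[[v]][i] +
          stats::rnorm(k, 0, 0.02 * max(abs(gradient[[v]])))
      }
      pt
    }))
    out
  })
}

#' Assemble communities along the gradient
#'
#' Three assembly rules acting on the species' thermal optima and the site
#' temperatures:
#' * `filtering`: species enter with probability
#'   `exp(-(optimum - site_temp)^2 / (2 tau^2))`, then the community is
#'   topped-up/thinned to the target richness by inclusion probability;
#' * `competition`: candidates admitted in random order only if their
#'   patristic distance to every resident exceeds `delta`; a shortfall
#'   against the target richness is recorded, not fatal;
#' * `neutral`: a uniform random draw of the target richness.
#'
#' @param optima Named species thermal optima (degC).
#' @param site_temps Named site temperatures (degC).
#' @param rule Assembly rule.
#' @param config A `scenario_config` (supplies tau, delta, richness).
#' @param tree Species-level tree (required for `competition`).
#' @param seed Integer seed.
#' @return Binary sites x species matrix (all species columns retained);
#'   attribute `shortfall` records unmet richness per site.
#' @export
assemble_communities <- function(optima, site_temps,
                                 rule = c("filtering", "competition",
                                          "neutral"),
                                 config, tree = NULL, seed) {
  rule <- match.arg(rule)
  stop_if(missing(seed), "an explicit seed is required")
  species <- names(optima)
  sites <- names(site_temps)
  target <- rep_len(config$richness, length(sites))
  m <- matrix(0L, length(sites), length(species),
              dimnames = list(sites, species))
  D <- if (rule == "competition") {
    stop_if(is.null(tree), "competition rule needs the species tree")
    patristic(tree)[species, species]
  }
  shortfall <- setNames(integer(length(sites)), sites)
  withr::with_seed(seed, {
    for (i in seq_along(sites)) {
      k <- target[i]
      if (rule == "neutral") {
        chosen <- sample(species, k)
      } else if (rule == "filtering") {
        p <- pmax(exp(-(optima - site_temps[i])^2 / (2 * config$tau^2)),
                  1e-300)
        inc <- stats::rbinom(length(p), 1, p) == 1
        # top-up/thin to the target richness by inclusion probability,
        # sampled (not ranked) so the tau -> Inf limit is uniform
        if (sum(inc) > k) {
          chosen <- sample(species[inc], k, prob = p[inc])
        } else if (sum(inc) < k) {
          add <- sample(species[!inc], k - sum(inc), prob = p[!inc])
          chosen <- c(species[inc], add)
        } else chosen <- species[inc]
      } else {
        chosen <- character(0)
        for (s in sample(species)) {
          if (length(chosen) == k) break
          if (length(chosen) == 0 || all(D[s, chosen] > config$delta)) {
            chosen <- c(chosen, s)
          }
        }
        if (length(chosen) < k) {
          shortfall[i] <- k - length(chosen)
          message(sprintf(
            "competition: site %s reached %d of %d species (delta = %g)",
            sites[i], length(chosen), k, config$delta))
        }
      }
      m[i, chosen] <- 1L
    }
  })
  attr(m, "shortfall") <- shortfall
  m
}

#' End-to-end synthetic fixture bundle
#'
#' Generates a mutually consistent backbone tree, species assignment, tree
#' sample, true species tree with Brownian thermal optima, climate gradient
#' and points, and an assembled community matrix, with a manifest recording
#' the seed and all parameters. Byte-stable given the config.
#'
#' @param config A `scenario_config`.
#' @param n_trees Size of the phylogenetic-uncertainty tree sample.
#' @return A `fixture_bundle` list: config, backbone, assignment, sample,
#'   true_tree, optima, gradient, points, community (a `community_matrix`),
#'   manifest.
#' @export
make_fixture <- function(config, n_trees = 25) {
  cfg <- config
  backbone <- simulate_backbone(cfg$n_genera, cfg$birth, cfg$death,
                                cfg$backbone_depth,
                                seed = derive_seed(cfg$seed, 1))
  assignment <- simulate_assignment(backbone, cfg$n_species,
                                    seed = derive_seed(cfg$seed, 2))
  true_tree <- resolve_genus_to_species(backbone, assignment,
                                        cfg$crown_fraction,
                                        seed = derive_seed(cfg$seed, 3))
  optima <- evolve_thermal_optima(true_tree, cfg$sigma2, cfg$root_optimum,
                                  seed = derive_seed(cfg$seed, 4))
  gradient <- make_gradient(cfg)
  points <- make_climate_points(gradient, cfg)
  site_temps <- setNames(gradient$site_temp, gradient$site)
  inc <- assemble_communities(optima, site_temps, cfg$assembly, cfg,
                              tree = true_tree,
                              seed = derive_seed(cfg$seed, 5))
  community <- suppressWarnings(community_matrix(inc, gradient$elevation))
  sample <- simulate_tree_sample(backbone, assignment, n_trees,
                                 cfg$crown_fraction,
                                 base_seed = derive_seed(cfg$seed, 6))
  manifest <- c(unclass(cfg), list(n_trees = n_trees,
                                   n_species_observed =
                                     length(community$species)))
  structure(list(config = cfg, backbone = backbone, assignment = assignment,
                 sample = sample, true_tree = true_tree, optima = optima,
                 gradient = gradient, points = points, community = community,
                 manifest = manifest),
            class = "fixture_bundle")
}

#' Write a fixture bundle to disk
#'
#' Emits exactly the formats the pipeline reads: newick for the backbone,
#' true tree and tree sample (one per line), CSVs for the assignment, climate
#' points and community matrix, and a JSON manifest.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(bundle$backbone, file.path(dir, "backbone.nwk"))
  write_newick(bundle$true_tree, file.path(dir, "true_tree.nwk"))
  write_tree_sample(bundle$sample, file.path(dir, "tree_sample.nwk"))
  utils::write.csv(bundle$assignment, file.path(dir, "assignment.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$points, file.path(dir, "climate_points.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(species = names(bundle$optima),
                              optimum = as.numeric(bundle$optima)),
                   file.path(dir, "thermal_optima.csv"), row.names = FALSE)
  write_community_matrix(bundle$community, file.path(dir, "community.csv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
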