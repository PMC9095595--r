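test_that("backbone simulation: tip count, ultrametricity, determinism", {
  b1 <- simulate_backbone(12, birth = 0.1, death = 0, depth = 100, seed = 5)
  expect_equal(length(b1$tip.label), 12)
  expect_true(elevphylo:::is_ultrametric_tol(b1))
  expect_equal(max(elevphylo:::tip_depths(b1)), 100, tolerance = 1e-8)
  b2 <- simulate_backbone(12, birth = 0.1, death = 0, depth = 100, seed = 5)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  cherry <- simulate_backbone(2, birth = 0.2, seed = 1)
  expect_equal(length(cherry$tip.label), 2)
})

test_that("species assignment covers every genus exactly once per species", {
  bb <- simulate_backbone(10, seed = 2)
  asn <- simulate_assignment(bb, 40, seed = 3)
  expect_equal(nrow(asn), 40)
  expect_setequal(unique(asn$genus), bb$tip.label)
  expect_equal(anyDuplicated(asn$species), 0)
  expect_error(simulate_assignment(bb, 5, seed = 1), "n_species")
})

test_that("Brownian thermal optima behave like Brownian motion", {
  bb <- simulate_backbone(30, seed = 4, depth = 50)
  # zero rate: every optimum equals the root value
  o0 <- evolve_thermal_optima(bb, sigma2 = 0, root_value = 17, seed = 1)
  expect_equal(unname(o0), rep(17, 30))
  # tip variance scales with depth x sigma2 over replicates
  reps <- vapply(1:60, function(s) {
    var(evolve_thermal_optima(bb, sigma2 = 0.4, root_value = 0, seed = s))
  }, 0)
  # E[var over tips] < sigma2 * depth (shared history removes variance);
  # it must be positive and of that order
  expect_gt(mean(reps), 0.05 * 0.4 * 50)
  expect_lt(mean(reps), 1.5 * 0.4 * 50)
  # phylogenetic signal: trait distance correlates with patristic distance
  o <- evolve_thermal_optima(bb, sigma2 = 0.4, root_value = 0, seed = 9)
  D <- patristic(bb)[names(o), names(o)]
  td <- abs(outer(o, o, "-"))
  expect_gt(cor(D[upper.tri(D)], td[upper.tri(td)], method = "spearman"), 0)
})

test_that("climate gradient has the designed monotone/hump structure", {
  cfg <- scenario_config(seed = 6)
  g <- make_gradient(cfg)
  expect_equal(nrow(g), 7)
  for (j in 1:11) expect_true(all(diff(g[[paste0("bio", j)]]) < 0))
  # hump-shaped precipitation: interior maximum
  expect_gt(which.max(g$site_precip), 1)
  expect_lt(which.max(g$site_precip), 7)
  # dominant first axis on defaults
  p <- pca_first_axis(g, paste0("bio", 1:11))
  expect_gt(p$var_explained, 0.6)
  # consistent sign convention: warm lowlands score high on PC1
  expect_gt(cor(p$scores, g$site_temp), 0.9)
})

test_that("assembly rules: limits, richness targets, and shortfall logging", {
  cfg <- scenario_config(seed = 7)
  bundle <- small_fixture(seed = 7, n_trees = 1)
  temps <- setNames(bundle$gradient$site_temp, bundle$gradient$site)
  # neutral: exact target richness
  mn <- assemble_communities(bundle$optima, temps, "neutral", cfg,
                             seed = 1)
  expect_equal(unname(rowSums(mn)), cfg$richness)
  # filtering: exact target richness via top-up/thin
  mf <- assemble_communities(bundle$optima, temps, "filtering", cfg,
                             seed = 2)
  expect_equal(unname(rowSums(mf)), cfg$richness)
  # tau -> Inf reduces filtering to neutral-like uniform inclusion
  cfg_inf <- scenario_config(seed = 7, tau = 1e9)
  m_inf <- assemble_communities(bundle$optima, temps, "filtering", cfg_inf,
                                seed = 3)
  sel <- colnames(m_inf)[m_inf[1, ] == 1]
  opt_rank <- rank(abs(bundle$optima - temps[1]))[sel]
  # selected species are not biased toward close thermal matches
  expect_gt(mean(opt_rank), 0.3 * length(bundle$optima))
  # delta = 0 reduces competition to neutral richness attainment
  cfg0 <- scenario_config(seed = 7, delta = 0)
  m0 <- assemble_communities(bundle$optima, temps, "competition", cfg0,
                             tree = bundle$true_tree, seed = 4)
  expect_equal(unname(rowSums(m0)), cfg0$richness)
  # infeasible delta logs a shortfall instead of failing
  cfg_big <- scenario_config(seed = 7, delta = 1e6)
  expect_message(
    mb <- assemble_communities(bundle$optima, temps, "competition", cfg_big,
                               tree = bundle$true_tree, seed = 5),
    "reached")
  expect_true(all(attr(mb, "shortfall") > 0))
  # competition respects the limiting-similarity radius
  D <- patristic(bundle$true_tree)
  cfgc <- scenario_config(seed = 7)
  mc <- assemble_communities(bundle$optima, temps, "competition", cfgc,
                             tree = bundle$true_tree, seed = 6)
  for (i in 1:2) {
    res <- colnames(mc)[mc[i, ] == 1]
    d <- D[res, res]; diag(d) <- Inf
    expect_gt(min(d), cfgc$delta)
  }
})

test_that("fixtures are byte-stable given the seed and pass validators", {
  cfg <- scenario_config(seed = 8)
  b1 <- make_fixture(cfg, n_trees = 2)
  b2 <- make_fixture(cfg, n_trees = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(b1, d1)
  write_fixture(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # bundle round-trips through the module readers
  comm <- read_community_matrix(file.path(d1, "community.csv"))
  expect_identical(comm$incidence, b1$community$incidence)
  samp <- read_tree_sample(file.path(d1, "tree_sample.nwk"))
  expect_equal(samp$size, 2)
  expect_setequal(samp$trees[[1]]$tip.label, b1$assignment$species)
  bb <- read_newick(file.path(d1, "backbone.nwk"))
  expect_true(elevphylo:::is_ultrametric_tol(bb))
  # default config: 7 sites, all nonempty
  expect_equal(length(b1$community$sites), 7)
  expect_true(all(rowSums(b1$community$incidence) > 0))
})

test_that("assembly scenarios order SES.MPD as filtering < neutral < competition", {
  ses_mpd_mean <- function(assembly, seed) {
    b <- small_fixture(seed = seed, assembly = assembly, n_trees = 1)
    a <- run_alpha(b$sample, b$community, n_null = 59, n_iterations = 300,
                   seed = derive_seed(seed, 99))
    mean(a$ses[a$metric == "mpd"], na.rm = TRUE)
  }
  seeds <- 301:305
  filt <- vapply(seeds, function(s) ses_mpd_mean("filtering", s), 0)
  neut <- vapply(seeds, function(s) ses_mpd_mean("neutral", s), 0)
  comp <- vapply(seeds, function(s) suppressMessages(
    ses_mpd_mean("competition", s)), 0)
  expect_lt(mean(filt), 0)
  expect_gt(mean(comp), 0)
  expect_lt(mean(filt), mean(neut))
  expect_lt(mean(neut), mean(comp))
})

test_that("filtering gradients are turnover-dominated for distant pairs", {
  b <- small_fixture(seed = 11, assembly = "filtering", n_trees = 1,
                     sigma2 = 0.4)
  pw <- beta_over_sample(b$true_tree, b$community, mode = "pairwise")
  far <- pw[pw$site_pair %in% c("s0000-s2500", "s0000-s3000",
                                "s0500-s3000"), ]
  expect_gt(mean(far$sim > far$sne), 0.5)
})
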