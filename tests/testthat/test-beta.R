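test_that("branch partition matches hand computations", {
  tr <- balanced4()
  p <- branch_partition(tr, c("A", "B"), c("C", "D"))
  expect_equal(p, list(a = 0, b = 3, c = 3))
  p2 <- branch_partition(tr, c("A", "B"), c("A", "B", "C", "D"))
  expect_equal(p2, list(a = 3, b = 0, c = 3))
  p3 <- branch_partition(tr, c("A", "B"), c("A", "B"))
  expect_equal(p3$b + p3$c, 0)
  expect_equal(p3$a, faith_pd(tr, c("A", "B")))
  expect_error(branch_partition(tr, character(0), "A"), "empty")
})

test_that("partition is consistent with Faith's PD (a+b and a+c)", {
  bundle <- small_fixture()
  tree <- bundle$true_tree
  inc <- bundle$community$incidence
  cache <- elevphylo:::phylo_cache(tree)
  for (i in 1:3) {
    c1 <- colnames(inc)[inc[i, ] == 1]
    c2 <- colnames(inc)[inc[i + 1, ] == 1]
    p <- branch_partition(cache, c1, c2)
    expect_equal(p$a + p$b, faith_pd(cache, c1), tolerance = 1e-12)
    expect_equal(p$a + p$c, faith_pd(cache, c2), tolerance = 1e-12)
  }
})

test_that("phylosor decomposition formulas and identities", {
  expect_equal(phylosor_pair(list(a = 5, b = 0, c = 0)),
               list(sor = 0, sim = 0, sne = 0))
  d <- phylosor_pair(list(a = 0, b = 3, c = 3))
  expect_equal(d, list(sor = 1, sim = 1, sne = 0))
  n <- phylosor_pair(list(a = 3, b = 0, c = 3))
  expect_equal(n$sor, 1 / 3)
  expect_equal(n$sim, 0)
  expect_equal(n$sne, 1 / 3)
  # sor = sim + sne exactly; symmetry in b <-> c
  withr::with_seed(4, {
    for (i in 1:50) {
      a <- runif(1, 0, 5); b <- runif(1, 0, 5); cc <- runif(1, 0, 5)
      d1 <- phylosor_pair(list(a = a, b = b, c = cc))
      d2 <- phylosor_pair(list(a = a, b = cc, c = b))
      expect_equal(d1$sor, d1$sim + d1$sne, tolerance = 1e-12)
      expect_equal(d1$sor, d2$sor, tolerance = 1e-12)
      expect_equal(d1$sim, d2$sim, tolerance = 1e-12)
      expect_true(d1$sim <= d1$sor && d1$sor <= 1 && d1$sim >= 0)
    }
  })
})

test_that("star-tree phylosor equals classic Sorensen/Simpson set measures", {
  # unit-branch star tree: branch partition reduces to set cardinalities
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  c1 <- c("A", "B", "C", "D")
  c2 <- c("C", "D", "E")
  shared <- length(intersect(c1, c2))
  b <- length(setdiff(c1, c2)); cc <- length(setdiff(c2, c1))
  d <- phylosor_pair(branch_partition(tr, c1, c2))
  expect_equal(d$sor, (b + cc) / (2 * shared + b + cc), tolerance = 1e-12)
  expect_equal(d$sim, min(b, cc) / (shared + min(b, cc)), tolerance = 1e-12)
})

test_that("multisite decomposition: degenerate and two-site reductions", {
  bundle <- small_fixture()
  tree <- bundle$true_tree
  inc <- bundle$community$incidence
  # identical sites -> all zero
  same <- suppressWarnings(community_matrix(
    matrix(rep(inc[1, ], 3), 3, ncol(inc), byrow = TRUE,
           dimnames = list(c("x", "y", "z"), colnames(inc))),
    c(0, 1, 2)))
  dec0 <- phylosor_multisite(tree, same)
  expect_equal(dec0, list(sor = 0, sim = 0, sne = 0))
  # two sites -> equals pairwise
  two <- suppressWarnings(
    community_matrix(inc[1:2, ], bundle$community$elevation[1:2]))
  decm <- phylosor_multisite(tree, two)
  c1 <- colnames(inc)[inc[1, ] == 1]
  c2 <- colnames(inc)[inc[2, ] == 1]
  decp <- phylosor_pair(branch_partition(tree, c1, c2))
  expect_equal(decm$sor, decp$sor, tolerance = 1e-12)
  expect_equal(decm$sim, decp$sim, tolerance = 1e-12)
  expect_equal(decm$sne, decp$sne, tolerance = 1e-12)
})

test_that("multisite decomposition matches a brute-force formula oracle", {
  # 3 sites on a 6-tip tree, everything enumerated via the picante PD oracle
  tr <- ape::read.tree(
    text = "(((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,(E:2,F:2):1);")
  inc <- matrix(c(1, 1, 1, 0, 0, 0,
                  0, 1, 1, 1, 0, 0,
                  0, 0, 0, 1, 1, 1), 3, 6, byrow = TRUE,
                dimnames = list(c("low", "mid", "high"), tr$tip.label))
  cm <- community_matrix(inc, c(0, 1, 2))
  dec <- phylosor_multisite(tr, cm)

  comms <- lapply(seq_len(nrow(inc)), function(i) {
    colnames(inc)[inc[i, ] == 1]
  })
  S <- vapply(comms, function(cc) pd_oracle(tr, cc), 0)
  S_T <- pd_oracle(tr, colnames(inc))
  pairs <- combn(3, 2)
  mins <- maxs <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- partition_oracle(tr, comms[[i]], comms[[j]])
    mins[k] <- min(p$b, p$c); maxs[k] <- max(p$b, p$c)
  }
  core <- sum(S) - S_T
  sim_o <- sum(mins) / (core + sum(mins))
  sor_o <- (sum(mins) + sum(maxs)) / (2 * core + sum(mins) + sum(maxs))
  expect_equal(dec$sim, sim_o, tolerance = 1e-12)
  expect_equal(dec$sor, sor_o, tolerance = 1e-12)
  expect_equal(dec$sne, sor_o - sim_o, tolerance = 1e-12)
})

test_that("adjacent series and beta ratio follow the elevation order", {
  bundle <- small_fixture()
  adj <- adjacent_series(bundle$true_tree, bundle$community)
  expect_equal(nrow(adj), 6)
  expect_identical(adj$site_low, bundle$community$sites[1:6])
  expect_identical(adj$site_high, bundle$community$sites[2:7])
  expect_equal(adj$beta_ratio, adj$sim / adj$sor)
  expect_identical(adj$turnover_dominated, adj$beta_ratio > 0.5)
  # ratio bounds
  expect_equal(beta_ratio(list(sor = 0.4, sim = 0)), 0)
  expect_equal(beta_ratio(list(sor = 0.4, sim = 0.4)), 1)
  expect_message(br <- beta_ratio(list(sor = 0, sim = 0)), "undefined")
  expect_true(is.na(br))
})

test_that("beta_over_sample emits the expected pair counts and MCC rows", {
  bundle <- small_fixture(n_trees = 2)
  pw <- beta_over_sample(bundle$sample, bundle$community, mode = "pairwise",
                         mcc = bundle$true_tree)
  expect_equal(sum(pw$tree_id == "1"), choose(7, 2))
  expect_equal(sum(pw$tree_id == "MCC"), choose(7, 2))
  expect_equal(pw$sor, pw$sim + pw$sne, tolerance = 1e-12)
  ms <- beta_over_sample(bundle$sample, bundle$community, mode = "multisite")
  expect_equal(nrow(ms), 2)
  # identical trees -> zero SD
  samp <- elevphylo:::as_tree_sample(rep(bundle$sample$trees[1], 3))
  ms2 <- beta_over_sample(samp, bundle$community, mode = "multisite")
  expect_equal(sd(ms2$sor), 0)
  # square matrix reconstruction is symmetric with zero diagonal
  m <- beta_matrix(pw, "1", "sor", bundle$community$sites)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
})
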