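test_that("newick read/write round-trips topology and branch lengths", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tmp)
  tr <- read_newick(tmp)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(unname(patristic(tr)["A", "C"]), 4)

  bundle <- small_fixture()
  tr2 <- bundle$sample$trees[[1]]
  out <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr2, out)
  back <- read_newick(out)
  expect_equal(patristic(back)[rownames(patristic(tr2)),
                               colnames(patristic(tr2))],
               patristic(tr2), tolerance = 1e-9)
})

test_that("malformed newick is rejected with the offending position", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2", tmp)
  expect_error(read_newick(tmp), "position 16")
  writeLines("((A:1,B:1):1,C:2)", tmp)
  expect_error(read_newick(tmp), "missing terminal ';'")
  writeLines("((A:1,B:1):1,C);", tmp)
  expect_error(read_newick(tmp), "branch lengths")
})

test_that("genus resolution follows the crown-depth rule and preserves depth", {
  bb <- toy_backbone()
  asn <- toy_assignment()
  tr <- resolve_genus_to_species(bb, asn, crown_fraction = 0.5, seed = 11)
  expect_setequal(tr$tip.label, asn$species)
  # ultrametric with the backbone's total depth for every tip
  depths <- elevphylo:::tip_depths(tr)
  expect_equal(depths, rep(15, 7), tolerance = 1e-8)
  # monotypic genus renamed in place, branch unchanged
  d <- patristic(tr)
  expect_equal(unname(d["s2a", "s1a"]), unname(patristic(bb)["g2", "g1"]))
  # two-species genus g3 (terminal 12, crown_fraction .5) -> cherry of depth 6
  expect_equal(unname(d["s3a", "s3b"]), 12)
  # between-genus patristic equals backbone patristic for every seed
  for (s in 2:6) {
    tri <- resolve_genus_to_species(bb, asn, crown_fraction = 0.5, seed = s)
    di <- patristic(tri)
    expect_equal(unname(di["s1a", "s4a"]), unname(patristic(bb)["g1", "g4"]))
    expect_true(elevphylo:::is_ultrametric_tol(tri))
  }
  # species mapped to an unknown genus are reported
  bad <- rbind(asn, data.frame(species = "sXa", genus = "gX"))
  expect_error(resolve_genus_to_species(bb, bad, seed = 1), "gX")
})

test_that("crown fraction controls within-genus crown depth", {
  bb <- toy_backbone()
  asn <- data.frame(species = c("x1", "x2"), genus = c("g1", "g1"))
  tr <- resolve_genus_to_species(bb, asn, crown_fraction = 0.25, seed = 3)
  # cherry tips 2.5 below the graft; stem 7.5
  expect_equal(unname(patristic(tr)["x1", "x2"]), 5)
  expect_true(elevphylo:::is_ultrametric_tol(tr))
})

test_that("tree sampling is deterministic given the base seed", {
  bb <- toy_backbone()
  asn <- toy_assignment()
  s1 <- simulate_tree_sample(bb, asn, n_trees = 4, base_seed = 99)
  s2 <- simulate_tree_sample(bb, asn, n_trees = 4, base_seed = 99)
  expect_identical(
    vapply(s1$trees, function(t) ape::write.tree(t), ""),
    vapply(s2$trees, function(t) ape::write.tree(t), ""))
  expect_equal(s1$size, 4)
  tips <- sort(s1$trees[[1]]$tip.label)
  for (tr in s1$trees) expect_identical(sort(tr$tip.label), tips)
  expect_error(simulate_tree_sample(bb, asn, n_trees = 0, base_seed = 1),
               "n_trees")
})

test_that("monotypic-only backbones resolve to a unique relabeled tree", {
  bb <- toy_backbone()
  asn <- data.frame(species = paste0("m", 1:4), genus = paste0("g", 1:4))
  s <- simulate_tree_sample(bb, asn, n_trees = 5, base_seed = 1)
  nwk <- vapply(s$trees, function(t) ape::write.tree(t), "")
  expect_length(unique(nwk), 1L)
  expect_equal(unname(patristic(s$trees[[1]])["m1", "m2"]),
               unname(patristic(bb)["g1", "g2"]))
})

test_that("mcc_tree maximizes summed log clade frequency", {
  # topology X ((A,B),(C,D)) nine times, Y ((A,C),(B,D)) once:
  # X clades {AB}, {CD} have freq .9; Y clades {AC}, {BD} freq .1; root 1.
  x <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  y <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  samp <- elevphylo:::as_tree_sample(c(rep(list(x), 9), list(y)))
  m <- mcc_tree(samp)
  expect_equal(attr(m, "index"), 1L)
  expect_equal(attr(m, "credibility"), 2 * log(0.9), tolerance = 1e-12)
  expect_setequal(m$tip.label, x$tip.label)

  # degenerate sample of identical trees: credibility 0
  samp2 <- elevphylo:::as_tree_sample(rep(list(x), 5))
  expect_equal(attr(mcc_tree(samp2), "credibility"), 0)

  # exhaustive check: credibility of returned tree >= all members
  bundle <- small_fixture(n_trees = 8)
  freq <- clade_frequencies(bundle$sample)
  cred <- vapply(bundle$sample$trees, function(tr) {
    sum(log(freq[elevphylo:::clade_keys(tr)]))
  }, 0)
  expect_equal(attr(mcc_tree(bundle$sample), "credibility"), max(cred))
})

test_that("mcc_tree agrees with the reference maximum clade credibility", {
  skip_if_not_installed("phangorn")
  bundle <- small_fixture(seed = 7, n_trees = 10)
  trees <- bundle$sample$trees
  class(trees) <- "multiPhylo"
  ref <- phangorn::maxCladeCred(trees)
  mine <- mcc_tree(bundle$sample)
  expect_true(ape::all.equal.phylo(mine, ref, use.edge.length = FALSE))
})

test_that("clade frequencies are proper frequencies with root at 1", {
  bundle <- small_fixture(n_trees = 6)
  freq <- clade_frequencies(bundle$sample)
  expect_true(all(freq > 0 & freq <= 1))
  root_key <- paste(sort(bundle$sample$trees[[1]]$tip.label),
                    collapse = "\r")
  expect_equal(unname(freq[root_key]), 1)
})
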