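test_that("faith_pd matches hand computations and is monotone", {
  tr <- balanced4()
  expect_equal(faith_pd(tr, c("A", "B", "C", "D")), 6)  # whole tree
  expect_equal(faith_pd(tr, c("A", "B")), 3)            # A + B + stem
  expect_equal(faith_pd(tr, "A"), 2)                    # root-to-tip path
  expect_error(faith_pd(tr, character(0)), "empty")
  expect_error(faith_pd(tr, c("A", "Z")), "Z")
  # monotone under community growth
  bundle <- small_fixture()
  tree <- bundle$true_tree
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- sample(tree$tip.label, 5)
      b <- union(a, sample(tree$tip.label, 10))
      expect_lte(faith_pd(tree, a), faith_pd(tree, b))
    }
  })
})

test_that("mpd and mntd match hand computations and each other's bound", {
  tr <- balanced4()
  expect_equal(mpd(tr, c("A", "B", "C")), 10 / 3)
  expect_equal(mntd(tr, c("A", "B", "C")), 8 / 3)
  expect_equal(mpd(tr, c("A", "C")), mntd(tr, c("A", "C")))
  expect_equal(mpd(tr, c("A", "C")), 4)
  expect_error(mpd(tr, "A"), "undefined for singletons")
  expect_error(mntd(tr, "A"), "undefined for singletons")
  # mpd >= mntd over many random communities
  bundle <- small_fixture()
  tree <- bundle$true_tree
  withr::with_seed(8, {
    for (i in 1:200) {
      comm <- sample(tree$tip.label, sample(2:12, 1))
      expect_gte(mpd(tree, comm), mntd(tree, comm))
    }
  })
})

test_that("alpha metrics agree with picante on random communities", {
  skip_if_not_installed("picante")
  bundle <- small_fixture()
  tree <- bundle$true_tree
  inc <- bundle$community$incidence
  ref_pd <- picante::pd(inc, tree, include.root = TRUE)
  ref_mpd <- picante::mpd(inc, stats::cophenetic(tree))
  ref_mntd <- picante::mntd(inc, stats::cophenetic(tree))
  cache <- elevphylo:::phylo_cache(tree)
  mine <- elevphylo:::alpha_metrics_matrix(cache, inc)
  expect_equal(mine$pd, ref_pd$PD, tolerance = 1e-10)
  expect_equal(mine$mpd, ref_mpd, tolerance = 1e-10)
  expect_equal(mine$mntd, ref_mntd, tolerance = 1e-10)
})

test_that("independent swap preserves margins exactly for every seed", {
  m <- random_incidence(6, 40, seed = 2)
  for (s in 1:10) {
    sw <- independent_swap(m, n_iterations = 500, seed = s)
    expect_identical(rowSums(sw), rowSums(m))
    expect_identical(colSums(sw), colSums(m))
    expect_true(all(sw %in% c(0L, 1L)))
  }
})

test_that("the unique checkerboard of a 2x2 identity is swapped", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  sw <- independent_swap(m, n_iterations = 1, seed = 4)
  expect_identical(unname(sw), matrix(c(0L, 1L, 1L, 0L), 2, 2))
})

test_that("a matrix with no checkerboard returns unchanged with a warning", {
  m <- matrix(1L, 3, 3, dimnames = list(paste0("r", 1:3), paste0("c", 1:3)))
  expect_warning(sw <- independent_swap(m, n_iterations = 5, seed = 1),
                 "swap")
  expect_identical(unname(sw), unname(m))
})

test_that("the swap chain reaches every margin-preserving matrix", {
  # 3x3 with margins (1,1,1)/(1,1,1): the margin-fixed class is the 6
  # permutation matrices; enumerate by brute force and check reachability.
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  class_mats <- lapply(perms, function(p) {
    m <- matrix(0L, 3, 3); m[cbind(1:3, p)] <- 1L; m
  })
  key <- function(m) paste(m, collapse = "")
  start <- class_mats[[1]]
  dimnames(start) <- list(paste0("r", 1:3), paste0("c", 1:3))
  seen <- character(0)
  for (s in 1:300) {
    sw <- independent_swap(start, n_iterations = 1 + s %% 7, seed = s)
    seen <- union(seen, key(unname(sw)))
  }
  expect_setequal(seen, vapply(class_mats, key, ""))
})

test_that("compiled swap kernel matches the pure-R reference bitwise", {
  m <- random_incidence(7, 30, seed = 3)
  for (s in c(1, 17, 123)) {
    expect_identical(independent_swap(m, 200, seed = s),
                     elevphylo:::independent_swap_r(m, 200, seed = s))
  }
})

test_that("ses arithmetic and the 1.96 significance rule", {
  r <- ses(12, c(10, 10, 14, 14))
  expect_equal(r$ses, 0)
  expect_false(r$significant)
  expect_equal(r$null_sd, sd(c(10, 10, 14, 14)))
  r2 <- ses(5, c(2, 3, 4))   # mean 3, sample sd 1
  expect_equal(r2$ses, 2)
  expect_true(r2$significant)
  expect_error(ses(1, c(3, 3, 3)), "degenerate")
})

test_that("run_alpha emits SES per site/metric/tree with consistent flags", {
  bundle <- small_fixture(n_trees = 2)
  a <- run_alpha(bundle$sample, bundle$community, n_null = 29,
                 n_iterations = 200, seed = 6, mcc = bundle$true_tree)
  expect_setequal(unique(a$tree_id), c("1", "2", "MCC"))
  expect_setequal(unique(a$metric), c("pd", "mpd", "mntd"))
  ok <- !is.na(a$ses)
  expect_equal(a$ses[ok], (a$observed[ok] - a$null_mean[ok]) / a$null_sd[ok])
  expect_equal(a$significant[ok], abs(a$ses[ok]) > 1.96)
  # species absent from the trees are named
  bad <- bundle$community
  bad$incidence <- cbind(bad$incidence, ghost_species = 1L)
  bad$species <- colnames(bad$incidence)
  expect_error(run_alpha(bundle$sample, bad, n_null = 5, seed = 1),
               "ghost_species")
})

test_that("identical sample trees give zero across-tree SES spread", {
  bundle <- small_fixture(n_trees = 1)
  samp <- elevphylo:::as_tree_sample(rep(bundle$sample$trees, 3))
  a <- run_alpha(samp, bundle$community, n_null = 19, n_iterations = 200,
                 seed = 9)
  s <- summarize_alpha(a)
  expect_true(all(s$ses_sd[!is.na(s$ses_sd)] < 1e-12))
})

test_that("filtering fixtures are phylogenetically clustered at stressed sites", {
  bundle <- small_fixture(seed = 202, assembly = "filtering", n_trees = 1)
  a <- run_alpha(bundle$sample, bundle$community, n_null = 99,
                 n_iterations = 500, seed = 13)
  m <- a[a$metric == "mpd" & !is.na(a$ses), ]
  expect_lt(mean(m$ses), 0)
})
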