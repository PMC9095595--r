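# Shared in-code fixtures for the test suite. Everything is generated
# programmatically under fixed seeds; nothing is read from disk.

# The 4-tip balanced tree used for the hand-computed metric examples.
balanced4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# Small backbone + assignment for resolution tests.
toy_backbone <- function() {
  ape::read.tree(text = "((g1:10,g2:10):5,(g3:12,g4:12):3);")
}

toy_assignment <- function() {
  data.frame(
    species = c("s1a", "s1b", "s1c", "s2a", "s3a", "s3b", "s4a"),
    genus   = c("g1", "g1", "g1", "g2", "g3", "g3", "g4"))
}

# Random binary community matrix with guaranteed nonempty rows/columns.
random_incidence <- function(n_sites, n_species, p = 0.35, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      m <- matrix(rbinom(n_sites * n_species, 1, p), n_sites, n_species,
                  dimnames = list(sprintf("site%d", seq_len(n_sites)),
                                  sprintf("sp%02d", seq_len(n_species))))
      if (all(rowSums(m) >= 2) && all(colSums(m) >= 1)) return(m)
    }
  })
}

small_fixture <- function(seed = 101, assembly = "filtering", n_trees = 3,
                          ...) {
  make_fixture(scenario_config(seed = seed, assembly = assembly, ...),
               n_trees = n_trees)
}

# Brute-force Faith's PD oracle: classifies every edge by whether the set of
# tips descending from it intersects the community, using phangorn's clade
# enumeration (independent of the package's tip-edge bookkeeping).
pd_oracle <- function(tree, community) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  on_path <- vapply(desc, function(d) {
    any(tree$tip.label[d] %in% community)
  }, TRUE)
  sum(tree$edge.length[on_path])
}

# Brute-force pairwise branch partition from PD of unions (picante oracle).
partition_oracle <- function(tree, c1, c2) {
  comm <- matrix(0, 3, length(tree$tip.label),
                 dimnames = list(c("c1", "c2", "u"), tree$tip.label))
  comm["c1", c1] <- 1; comm["c2", c2] <- 1; comm["u", union(c1, c2)] <- 1
  pds <- picante::pd(comm, tree, include.root = TRUE)$PD
  list(a = pds[1] + pds[2] - pds[3], b = pds[3] - pds[2], c = pds[3] - pds[1])
}
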