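# Logical edge-inclusion vector of a community's root-inclusive spanning
# subtree (one entry per tree edge).
spanning_edges <- function(cache, community) {
  check_community(cache, community)
  colSums(cache$tipE[community, , drop = FALSE]) > 0
}

#' Shared and exclusive branch length between two communities
#'
#' Branches of the union spanning subtree (root paths included) are classified
#' by whether they lie on the root path of tips from both communities (`a`),
#' only the first (`b`), or only the second (`c`). Under this convention
#' `a + b` and `a + c` equal the two communities' Faith's PD.
#'
#' @inheritParams faith_pd
#' @param comm1,comm2 Character vectors of species labels (nonempty).
#' @return List with `a`, `b`, `c` (branch-length units).
#' @export
branch_partition <- function(tree, comm1, comm2) {
  cache <- if (is.list(tree) && !inherits(tree, "phylo")) tree else
    phylo_cache(tree)
  e1 <- spanning_edges(cache, comm1)
  e2 <- spanning_edges(cache, comm2)
  list(a = sum(cache$el[e1 & e2]),
       b = sum(cache$el[e1 & !e2]),
       c = sum(cache$el[!e1 & e2]))
}

#' PhyloSor dissimilarity partitioned into turnover and nestedness
#'
#' Soerensen-family phylogenetic decomposition: total dissimilarity
#' `sor = (b + c) / (2a + b + c)`, turnover `sim = min(b, c) / (a + min(b, c))`
#' and nestedness-resultant `sne = sor - sim`, computed from a branch-length
#' partition (`a` shared, `b`/`c` exclusive).
#'
#' @param partition Output of [branch_partition()].
#' @return List with `sor`, `sim`, `sne`, all in `[0, 1]` with
#'   `sor == sim + sne`.
#' @export
phylosor_pair <- function(partition) {
  a <- partition$a; b <- partition$b; cc <- partition$c
  stop_if(a + b <= 0 || a + cc <= 0,
          "both communities must have positive spanning branch length")
  sor <- (b + cc) / (2 * a + b + cc)
  sim <- if (a + min(b, cc) > 0) min(b, cc) / (a + min(b, cc)) else 0
  list(sor = sor, sim = sim, sne = sor - sim)
}

#' Multiple-site PhyloSor decomposition
#'
#' One overall dissimilarity for all sites jointly: with `S_i` the Faith's PD
#' of site i, `S_T` the PD of the pooled community and `b_ij` the branch
#' length exclusive to site i relative to site j,
#' `SIM = sum_min / (sum_i S_i - S_T + sum_min)` and
#' `SOR = (sum_min + sum_max) / (2 (sum_i S_i - S_T) + sum_min + sum_max)`
#' where `sum_min`/`sum_max` run over `min(b_ij, b_ji)` / `max(b_ij, b_ji)`
#' for all unordered pairs; `SNE = SOR - SIM`.
#'
#' @param tree An [ape::phylo] (or internal cache).
#' @param matrix A `community_matrix` with >= 2 nonempty sites.
#' @return List with `sor`, `sim`, `sne`.
#' @export
phylosor_multisite <- function(tree, matrix) {
  cache <- if (is.list(tree) && !inherits(tree, "phylo")) tree else
    phylo_cache(tree)
  stop_if(!inherits(matrix, "community_matrix"), "need a community_matrix")
  inc <- matrix$incidence
  stop_if(nrow(inc) < 2, "need >= 2 sites")
  stop_if(any(rowSums(inc) == 0), "empty site(s): ",
          paste(rownames(inc)[rowSums(inc) == 0], collapse = ", "))
  E <- (inc %*% cache$tipE[colnames(inc), , drop = FALSE]) > 0  # sites x edges
  S <- as.numeric(E %*% cache$el)
  S_T <- sum(cache$el[colSums(E) > 0])
  n <- nrow(inc)
  sum_min <- sum_max <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      b_ij <- sum(cache$el[E[i, ] & !E[j, ]])
      b_ji <- sum(cache$el[E[j, ] & !E[i, ]])
      sum_min <- sum_min + min(b_ij, b_ji)
      sum_max <- sum_max + max(b_ij, b_ji)
    }
  }
  core <- sum(S) - S_T
  sim <- if (core + sum_min > 0) sum_min / (core + sum_min) else 0
  sor_den <- 2 * core + sum_min + sum_max
  sor <- if (sor_den > 0) (sum_min + sum_max) / sor_den else 0
  list(sor = sor, sim = sim, sne = sor - sim)
}

#' Turnover-to-total ratio of a decomposition
#'
#' `beta_ratio = sim / sor`; values above 0.5 indicate turnover-dominated
#' dissimilarity, below 0.5 nestedness-dominated. Undefined (NA) when
#' `sor == 0`.
#'
#' @param dec A decomposition list with `sor` and `sim`.
#' @return A real in `[0, 1]`, or NA.
#' @export
beta_ratio <- function(dec) {
  if (dec$sor == 0) {
    message("beta_ratio undefined: total dissimilarity is zero")
    return(NA_real_)
  }
  dec$sim / dec$sor
}

#' Adjacent-site decomposition series along the gradient
#'
#' Applies [phylosor_pair()] to every consecutive (elevation-ordered) pair of
#' sites and annotates the turnover/nestedness dominance of each pair.
#'
#' @inheritParams phylosor_multisite
#' @return Data frame with one row per adjacent pair: site_low, site_high,
#'   sor, sim, sne, beta_ratio, turnover_dominated.
#' @export
adjacent_series <- function(tree, matrix) {
  cache <- if (is.list(tree) && !inherits(tree, "phylo")) tree else
    phylo_cache(tree)
  stop_if(!inherits(matrix, "community_matrix"), "need a community_matrix")
  inc <- matrix$incidence
  out <- lapply(seq_len(nrow(inc) - 1), function(i) {
    c1 <- colnames(inc)[inc[i, ] == 1]
    c2 <- colnames(inc)[inc[i + 1, ] == 1]
    dec <- phylosor_pair(branch_partition(cache, c1, c2))
    br <- suppressMessages(beta_ratio(dec))
    data.frame(site_low = rownames(inc)[i], site_high = rownames(inc)[i + 1],
               sor = dec$sor, sim = dec$sim, sne = dec$sne, beta_ratio = br,
               turnover_dominated = !is.na(br) & br > 0.5, row.names = NULL)
  })
  do.call(rbind, out)
}

# All unordered pairwise decompositions of a matrix on one tree.
pairwise_decompositions <- function(cache, matrix) {
  inc <- matrix$incidence
  n <- nrow(inc)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      c1 <- colnames(inc)[inc[i, ] == 1]
      c2 <- colnames(inc)[inc[j, ] == 1]
      dec <- phylosor_pair(branch_partition(cache, c1, c2))
      out[[length(out) + 1L]] <- data.frame(
        site1 = rownames(inc)[i], site2 = rownames(inc)[j],
        sor = dec$sor, sim = dec$sim, sne = dec$sne, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Phylogenetic beta diversity across a tree sample
#'
#' Applies the chosen decomposition mode to every tree of the sample (and the
#' MCC tree when given) and returns a long-format table.
#'
#' @param sample A `tree_sample` or single [ape::phylo].
#' @param matrix A `community_matrix`.
#' @param mode One of `"pairwise"`, `"adjacent"`, `"multisite"`.
#' @param mcc Optional MCC tree; its rows get `tree_id = "MCC"`.
#' @return Long data.frame: mode, site_pair (or `"ALL"`), tree_id, sor, sim,
#'   sne, beta_ratio.
#' @export
beta_over_sample <- function(sample, matrix,
                             mode = c("pairwise", "adjacent", "multisite"),
                             mcc = NULL) {
  mode <- match.arg(mode)
  if (inherits(sample, "phylo")) sample <- as_tree_sample(list(sample))
  eval_tree <- function(tree, id) {
    cache <- phylo_cache(tree)
    if (mode == "multisite") {
      dec <- phylosor_multisite(cache, matrix)
      data.frame(mode = mode, site_pair = "ALL", tree_id = id,
                 sor = dec$sor, sim = dec$sim, sne = dec$sne,
                 beta_ratio = suppressMessages(beta_ratio(dec)),
                 row.names = NULL)
    } else if (mode == "adjacent") {
      adj <- adjacent_series(cache, matrix)
      data.frame(mode = mode,
                 site_pair = paste(adj$site_low, adj$site_high, sep = "-"),
                 tree_id = id, sor = adj$sor, sim = adj$sim, sne = adj$sne,
                 beta_ratio = adj$beta_ratio, row.names = NULL)
    } else {
      pw <- pairwise_decompositions(cache, matrix)
      br <- ifelse(pw$sor > 0, pw$sim / pw$sor, NA_real_)
      data.frame(mode = mode,
                 site_pair = paste(pw$site1, pw$site2, sep = "-"),
                 tree_id = id, sor = pw$sor, sim = pw$sim, sne = pw$sne,
                 beta_ratio = br, row.names = NULL)
    }
  }
  res <- do.call(rbind, lapply(seq_len(sample$size), function(t) {
    eval_tree(sample$trees[[t]], as.character(t))
  }))
  if (!is.null(mcc)) res <- rbind(res, eval_tree(mcc, "MCC"))
  res
}

#' Across-tree summary of beta decompositions
#'
#' @param beta_df Output of [beta_over_sample()].
#' @return Per site pair: mean and SD of sor/sim/sne/beta_ratio across trees,
#'   plus MCC values when present.
#' @export
summarize_beta <- function(beta_df) {
  trees <- beta_df[beta_df$tree_id != "MCC", ]
  mcc <- beta_df[beta_df$tree_id == "MCC", ]
  agg <- do.call(rbind, lapply(split(trees, trees$site_pair), function(g) {
    data.frame(site_pair = g$site_pair[1],
               sor_mean = mean(g$sor), sor_sd = stats::sd(g$sor),
               sim_mean = mean(g$sim), sim_sd = stats::sd(g$sim),
               sne_mean = mean(g$sne), sne_sd = stats::sd(g$sne),
               beta_ratio_mean = mean(g$beta_ratio, na.rm = TRUE),
               row.names = NULL)
  }))
  if (nrow(mcc) > 0) {
    agg$sor_mcc <- mcc$sor[match(agg$site_pair, mcc$site_pair)]
    agg$sim_mcc <- mcc$sim[match(agg$site_pair, mcc$site_pair)]
    agg$sne_mcc <- mcc$sne[match(agg$site_pair, mcc$site_pair)]
  }
  rownames(agg) <- NULL
  agg[match(unique(beta_df$site_pair), agg$site_pair), ]
}

#' Square pairwise dissimilarity matrices from a pairwise beta table
#'
#' @param beta_df Output of [beta_over_sample()] in pairwise mode.
#' @param tree_id Which tree's rows to extract.
#' @param component `"sor"`, `"sim"` or `"sne"`.
#' @param sites Site order for the matrix rows/columns.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
beta_matrix <- function(beta_df, tree_id, component = c("sor", "sim", "sne"),
                        sites) {
  component <- match.arg(component)
  g <- beta_df[beta_df$tree_id == tree_id & beta_df$mode == "pairwise", ]
  stop_if(nrow(g) == 0, "no pairwise rows for tree_id ", tree_id)
  m <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  parts <- strsplit(g$site_pair, "-", fixed = TRUE)
  for (k in seq_len(nrow(g))) {
    i <- parts[[k]][1]; j <- parts[[k]][2]
    m[i, j] <- m[j, i] <- g[[component]][k]
  }
  m
}
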