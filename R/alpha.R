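# Per-tree cache of the quantities the alpha/beta metrics reuse: the patristic
# distance matrix and the tip x edge indicator (edge lies on the tip's root
# path). Recomputation gives identical values; the cache is a pure speed-up.
phylo_cache <- function(tree) {
  validate_phylo(tree)
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  parent_edge <- integer(n_tip + tree$Nnode)   # edge index leading into node
  parent_edge[tree$edge[, 2L]] <- seq_len(n_edge)
  parent_node <- integer(n_tip + tree$Nnode)
  parent_node[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- n_tip + 1L
  tipE <- matrix(0L, n_tip, n_edge,
                 dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(n_tip)) {
    node <- i
    while (node != root) {
      tipE[i, parent_edge[node]] <- 1L
      node <- parent_node[node]
    }
  }
  list(tree = tree, tips = tree$tip.label, tipE = tipE,
       el = tree$edge.length, D = patristic(tree))
}

check_community <- function(cache, community) {
  stop_if(length(community) == 0, "community is empty")
  unknown <- setdiff(community, cache$tips)
  stop_if(length(unknown) > 0, "species absent from the tree: ",
          paste(unknown, collapse = ", "))
  invisible(community)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree that connects the community's
#' species to the root of the tree (the path to the root is included).
#'
#' @param tree An [ape::phylo] (or a cache from the internal helper).
#' @param community Character vector of species labels present at the site.
#' @return Branch-length sum (same units as the tree).
#' @export
faith_pd <- function(tree, community) {
  cache <- if (is.list(tree) && !inherits(tree, "phylo")) tree else
    phylo_cache(tree)
  check_community(cache, community)
  used <- colSums(cache$tipE[community, , drop = FALSE]) > 0
  sum(cache$el[used])
}

#' Mean pairwise and mean nearest taxon distance
#'
#' `mpd()` averages the patristic distance over all unordered distinct pairs
#' of community members; `mntd()` averages, over members, the distance to the
#' nearest other member. Both are presence-based (unweighted) and undefined
#' for communities of fewer than two species.
#'
#' @inheritParams faith_pd
#' @return A nonnegative real.
#' @export
mpd <- function(tree, community) {
  cache <- if (is.list(tree) && !inherits(tree, "phylo")) tree else
    phylo_cache(tree)
  check_community(cache, community)
  stop_if(length(community) < 2,
          "mpd is undefined for singletons (need >= 2 species)")
  d <- cache$D[community, community]
  mean(d[upper.tri(d)])
}

#' @rdname mpd
#' @export
mntd <- function(tree, community) {
  cache <- if (is.list(tree) && !inherits(tree, "phylo")) tree else
    phylo_cache(tree)
  check_community(cache, community)
  stop_if(length(community) < 2,
          "mntd is undefined for singletons (need >= 2 species)")
  d <- cache$D[community, community]
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# Vectorized per-site metrics for an incidence matrix aligned to cache$tips.
# Sites with < 2 species get NA for mpd/mntd; empty sites get NA for pd.
alpha_metrics_matrix <- function(cache, incidence) {
  stopifnot(all(colnames(incidence) %in% cache$tips))
  inc <- incidence[, , drop = FALSE]
  sub <- cache$tipE[colnames(inc), , drop = FALSE]
  edge_used <- (inc %*% sub) > 0
  pd <- as.numeric(edge_used %*% cache$el)
  pd[rowSums(inc) == 0] <- NA_real_
  D <- cache$D[colnames(inc), colnames(inc)]
  mpd_v <- mntd_v <- rep(NA_real_, nrow(inc))
  for (i in seq_len(nrow(inc))) {
    sp <- which(inc[i, ] == 1)
    if (length(sp) >= 2) {
      d <- D[sp, sp]
      mpd_v[i] <- mean(d[upper.tri(d)])
      diag(d) <- Inf
      mntd_v[i] <- mean(apply(d, 1, min))
    }
  }
  data.frame(site = rownames(inc), pd = pd, mpd = mpd_v, mntd = mntd_v,
             row.names = NULL)
}

#' Independent-swap randomization
#'
#' Randomizes a binary incidence matrix by `n_iterations` successful 2x2
#' checkerboard swaps (submatrix `[[1,0],[0,1]] <-> [[0,1],[1,0]]`), chosen
#' uniformly among random row/column pairs. Site richness (row sums) and
#' species occupancy (column sums) are preserved exactly. A matrix with no
#' checkerboard is returned unchanged with a warning once the attempt budget
#' is exhausted.
#'
#' @param matrix A `community_matrix` or a binary matrix.
#' @param n_iterations Number of successful swaps (study default 1000).
#' @param seed Integer seed (required).
#' @return Same type as the input.
#' @export
independent_swap <- function(matrix, n_iterations = 1000, seed) {
  stop_if(missing(seed), "an explicit seed is required")
  is_cm <- inherits(matrix, "community_matrix")
  m <- if (is_cm) matrix$incidence else {
    stop_if(!is_binary(matrix), "matrix must be binary")
    m0 <- as.matrix(matrix); storage.mode(m0) <- "integer"; m0
  }
  out <- withr::with_seed(seed, {
    .indep_swap_cpp(m, as.integer(n_iterations),
                    max_tries = max(1e5, 200 * n_iterations))
  })
  dimnames(out) <- dimnames(m)
  if (is_cm) {
    res <- matrix
    res$incidence <- out
    res
  } else out
}

# Pure-R reference for the swap kernel; draws the identical RNG stream as the
# compiled version, so the two agree bitwise under the same seed (tested).
independent_swap_r <- function(m, n_iterations, seed) {
  storage.mode(m) <- "integer"
  withr::with_seed(seed, {
    nr <- nrow(m); nc <- ncol(m)
    done <- 0; tries <- 0
    max_tries <- max(1e5, 200 * n_iterations)
    while (done < n_iterations && tries < max_tries) {
      tries <- tries + 1
      r1 <- floor(stats::runif(1) * nr) + 1
      r2 <- floor(stats::runif(1) * (nr - 1)) + 1
      if (r2 >= r1) r2 <- r2 + 1
      c1 <- floor(stats::runif(1) * nc) + 1
      c2 <- floor(stats::runif(1) * (nc - 1)) + 1
      if (c2 >= c1) c2 <- c2 + 1
      sub <- m[c(r1, r2), c(c1, c2)]
      if (sum(sub) == 2 && sub[1, 1] == sub[2, 2]) {
        m[c(r1, r2), c(c1, c2)] <- 1L - sub
        done <- done + 1
      }
    }
    m
  })
}

#' Standardized effect size against a null distribution
#'
#' `ses = (observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation; two-sided significance at `|ses| > 1.96`.
#'
#' @param observed Observed metric value.
#' @param null_values Numeric vector of null-model values (>= 2 distinct).
#' @return List with `observed`, `null_mean`, `null_sd`, `ses`, `significant`.
#' @export
ses <- function(observed, null_values) {
  null_values <- null_values[!is.na(null_values)]
  stop_if(length(unique(null_values)) < 2,
          "degenerate null distribution (fewer than 2 distinct values)")
  ns <- stats::sd(null_values)
  stop_if(ns == 0, "degenerate null distribution (zero standard deviation)")
  z <- (observed - mean(null_values)) / ns
  list(observed = observed, null_mean = mean(null_values), null_sd = ns,
       ses = z, significant = abs(z) > 1.96)
}

#' Alpha phylogenetic diversity SES across a tree sample
#'
#' For every tree in the sample and every site: observed PD, MPD and MNTD; a
#' null distribution from `n_null` independent-swap randomizations of the
#' observed matrix (each null matrix a fresh chain of `n_iterations`
#' successful swaps); and the standardized effect sizes. The randomization
#' does not depend on the tree, so the `n_null` null matrices are generated
#' once and evaluated on every tree. If an MCC tree is supplied its values are
#' appended with `tree_id = "MCC"`.
#'
#' @param sample A `tree_sample`, or a single [ape::phylo].
#' @param matrix A `community_matrix`.
#' @param n_null Number of null matrices (study default 1000).
#' @param n_iterations Successful swaps per null matrix (study default 1000).
#' @param seed Integer seed for the null chains (required).
#' @param mcc Optional MCC tree ([ape::phylo]).
#' @return Long data.frame: site, metric, tree_id, observed, null_mean,
#'   null_sd, ses, significant. Sites with < 2 species have NA mpd/mntd SES.
#' @export
run_alpha <- function(sample, matrix, n_null = 1000, n_iterations = 1000,
                      seed, mcc = NULL) {
  stop_if(missing(seed), "an explicit seed is required")
  if (inherits(sample, "phylo")) sample <- as_tree_sample(list(sample))
  stop_if(!inherits(matrix, "community_matrix"), "need a community_matrix")
  tips <- sample$trees[[1]]$tip.label
  missing_sp <- setdiff(matrix$species, tips)
  stop_if(length(missing_sp) > 0, "matrix species absent from the trees: ",
          paste(missing_sp, collapse = ", "))
  inc <- matrix$incidence
  nulls <- lapply(seq_len(n_null), function(j) {
    independent_swap(inc, n_iterations, seed = derive_seed(seed, j))
  })

  eval_tree <- function(tree, id) {
    cache <- phylo_cache(tree)
    obs <- alpha_metrics_matrix(cache, inc)
    null_arr <- vapply(nulls, function(nm) {
      as.matrix(alpha_metrics_matrix(cache, nm)[, c("pd", "mpd", "mntd")])
    }, matrix(0, nrow(inc), 3))
    out <- list()
    for (k in seq_along(c("pd", "mpd", "mntd"))) {
      met <- c("pd", "mpd", "mntd")[k]
      for (i in seq_len(nrow(inc))) {
        o <- obs[[met]][i]
        nv <- null_arr[i, k, ]
        if (is.na(o) || all(is.na(nv))) {
          rec <- list(observed = o, null_mean = NA_real_, null_sd = NA_real_,
                      ses = NA_real_, significant = NA)
        } else {
          rec <- ses(o, nv)
        }
        out[[length(out) + 1L]] <- data.frame(
          site = rownames(inc)[i], metric = met, tree_id = id,
          observed = rec$observed, null_mean = rec$null_mean,
          null_sd = rec$null_sd, ses = rec$ses, significant = rec$significant,
          row.names = NULL)
      }
    }
    do.call(rbind, out)
  }

  res <- do.call(rbind, lapply(seq_len(sample$size), function(t) {
    eval_tree(sample$trees[[t]], as.character(t))
  }))
  if (!is.null(mcc)) res <- rbind(res, eval_tree(mcc, "MCC"))
  res
}

#' Across-tree summary of SES results
#'
#' @param alpha_df Output of [run_alpha()].
#' @return Data frame with per site and metric: mean and SD of SES across the
#'   sampled trees, and the MCC value when present.
#' @export
summarize_alpha <- function(alpha_df) {
  trees <- alpha_df[alpha_df$tree_id != "MCC", ]
  mcc <- alpha_df[alpha_df$tree_id == "MCC", ]
  agg <- do.call(rbind, lapply(split(
    trees, list(trees$site, trees$metric), drop = TRUE), function(g) {
      data.frame(site = g$site[1], metric = g$metric[1],
                 ses_mean = mean(g$ses), ses_sd = stats::sd(g$ses),
                 prop_significant = mean(g$significant), row.names = NULL)
    }))
  if (nrow(mcc) > 0) {
    key <- paste(agg$site, agg$metric)
    mkey <- paste(mcc$site, mcc$metric)
    agg$ses_mcc <- mcc$ses[match(key, mkey)]
    agg$significant_mcc <- mcc$significant[match(key, mkey)]
  }
  rownames(agg) <- NULL
  agg[order(agg$metric, match(agg$site, unique(alpha_df$site))), ]
}
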