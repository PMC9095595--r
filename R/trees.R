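#' Read a phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] with the validation the downstream
#' diversity calculations rely on: unique tip labels and nonnegative branch
#' lengths on every edge. Malformed newick (unbalanced parentheses, missing
#' terminal semicolon) is reported with the offending character position.
#'
#' @param path Path to a newick file containing a single tree.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick_text(txt)
}

parse_newick_text <- function(txt) {
  txt <- trimws(txt)
  stop_if(!nzchar(txt), "empty newick input")
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    stop_if(depth < 0L, sprintf(
      "malformed newick: unmatched ')' at position %d", i))
  }
  stop_if(depth != 0L, sprintf(
    "malformed newick: %d unclosed '(' at end of input (position %d)",
    depth, length(chars)))
  stop_if(!grepl(";\\s*$", txt), sprintf(
    "malformed newick: missing terminal ';' (position %d)", nchar(txt)))
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
  stop_if(is.null(tree), "malformed newick: parser failed on input")
  validate_phylo(tree)
  tree
}

validate_phylo <- function(tree) {
  stop_if(!inherits(tree, "phylo"), "not a phylogeny")
  stop_if(anyDuplicated(tree$tip.label) > 0, "duplicate tip labels: ",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  stop_if(is.null(tree$edge.length),
          "tree has no branch lengths; branch lengths are required")
  stop_if(anyNA(tree$edge.length), "tree has missing branch lengths")
  stop_if(any(tree$edge.length < 0), "tree has negative branch lengths")
  invisible(tree)
}

#' Write a phylogeny to newick
#'
#' Branch lengths are written with 15 significant digits so that a
#' write/read round trip preserves patristic distances to floating-point
#' accuracy.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @export
write_newick <- function(tree, path) {
  validate_phylo(tree)
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Read / write a multi-tree sample (one newick per line)
#'
#' @param path File with one newick string per line.
#' @return A `tree_sample` object (see [simulate_tree_sample()]).
#' @export
read_tree_sample <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parse_newick_text)
  as_tree_sample(trees)
}

#' @rdname read_tree_sample
#' @param sample A `tree_sample`.
#' @export
write_tree_sample <- function(sample, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tr in sample$trees) {
    writeLines(ape::write.tree(tr, digits = 15), con)
  }
  invisible(path)
}

as_tree_sample <- function(trees, seeds = NA_integer_) {
  stop_if(length(trees) < 1, "tree sample must contain at least one tree")
  tips <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    stop_if(!identical(sort(tr$tip.label), tips),
            "all trees in a sample must share the identical tip set")
  }
  structure(list(trees = trees,
                 seeds = rep_len(seeds, length(trees)),
                 size = length(trees)),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("tree_sample: %d trees, %d shared tips\n",
              x$size, length(x$trees[[1]]$tip.label)))
  invisible(x)
}

#' Read a species-to-genus assignment table
#'
#' @param path Two-column CSV with header `species,genus`.
#' @return A data.frame with columns `species` and `genus`.
#' @export
read_genus_assignment <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("species", "genus") %in% names(df)),
          "assignment CSV must have columns 'species' and 'genus'")
  validate_assignment(df)
  df[c("species", "genus")]
}

validate_assignment <- function(assignment) {
  stop_if(anyDuplicated(assignment$species) > 0,
          "each species must map to exactly one genus; duplicated: ",
          paste(unique(assignment$species[duplicated(assignment$species)]),
                collapse = ", "))
  invisible(assignment)
}

# -- Yule resolution of a genus backbone to species level ---------------------

# Simulate a Yule (pure-birth) crown group of n >= 2 tips and return it as a
# newick fragment "(...)" whose tips sit exactly `depth` below the crown node.
# Relative node heights are the pure-birth waiting-time order statistics;
# the birth rate cancels under rescaling to the target crown depth.
yule_crown_newick <- function(tip_labels, depth) {
  n <- length(tip_labels)
  stop_if(n < 2, "crown simulation needs >= 2 tips")
  # node bookkeeping: birth time, end time, children indices
  birth <- c(0, 0)
  end <- c(NA_real_, NA_real_)
  kids <- list(integer(0), integer(0))
  active <- c(1L, 2L)
  t_now <- 0
  while (length(active) < n) {
    k <- length(active)
    t_now <- t_now + stats::rexp(1, rate = k)
    split <- active[sample.int(k, 1L)]
    id1 <- length(birth) + 1L
    id2 <- length(birth) + 2L
    birth <- c(birth, t_now, t_now)
    end[split] <- t_now
    end <- c(end, NA_real_, NA_real_)
    kids[[split]] <- c(id1, id2)
    kids <- c(kids, list(integer(0), integer(0)))
    active <- c(setdiff(active, split), id1, id2)
  }
  t_total <- t_now + stats::rexp(1, rate = n)
  end[is.na(end)] <- t_total
  scale <- depth / t_total
  labels <- sample(tip_labels)
  tip_ids <- which(lengths(kids) == 0)
  lab_of <- setNames(labels, tip_ids)
  as_str <- function(id) {
    len <- (end[id] - birth[id]) * scale
    if (length(kids[[id]]) == 0) {
      sprintf("%s:%.15g", lab_of[[as.character(id)]], len)
    } else {
      sprintf("(%s,%s):%.15g", as_str(kids[[id]][1]), as_str(kids[[id]][2]),
              len)
    }
  }
  sprintf("(%s,%s)", as_str(1L), as_str(2L))
}

#' Resolve a genus-level backbone to a species-level tree
#'
#' Each backbone tip is a genus. A genus carrying a single species is renamed
#' in place. A genus with n >= 2 species is replaced by a random Yule
#' (pure-birth) crown group of its species, grafted so that the crown depth
#' equals `crown_fraction` times the genus terminal branch length; within-genus
#' node heights are the rescaled Yule waiting-time order statistics. The
#' output tree is ultrametric with the same total depth as the backbone.
#'
#' @param backbone Ultrametric genus-level [ape::phylo]; tips are genus labels.
#' @param assignment Data frame with columns `species`, `genus`.
#' @param crown_fraction Fraction of the genus terminal branch allotted to the
#'   within-genus crown group, in (0, 1). Default 0.5.
#' @param seed Integer seed; the resolution is deterministic given the seed.
#' @return A species-level [ape::phylo].
#' @export
resolve_genus_to_species <- function(backbone, assignment,
                                     crown_fraction = 0.5, seed) {
  validate_phylo(backbone)
  validate_assignment(assignment)
  stop_if(missing(seed), "an explicit seed is required")
  stop_if(crown_fraction <= 0 || crown_fraction >= 1,
          "crown_fraction must be in (0, 1)")
  stop_if(!is_ultrametric_tol(backbone), "backbone must be ultrametric")
  orphans <- setdiff(unique(assignment$genus), backbone$tip.label)
  stop_if(length(orphans) > 0,
          "species mapped to genera absent from the backbone: ",
          paste(orphans, collapse = ", "))
  spp_by_genus <- split(assignment$species, assignment$genus)

  withr::with_seed(seed, {
    n_tip <- length(backbone$tip.label)
    root <- n_tip + 1L
    children <- split(backbone$edge[, 2L], backbone$edge[, 1L])
    edge_len <- numeric(n_tip + backbone$Nnode)
    edge_len[backbone$edge[, 2L]] <- backbone$edge.length
    node_str <- function(id) {
      if (id <= n_tip) {
        genus <- backbone$tip.label[id]
        len <- edge_len[id]
        spp <- spp_by_genus[[genus]]
        if (is.null(spp)) {        # genus kept as-is (no species mapped)
          sprintf("%s:%.15g", genus, len)
        } else if (length(spp) == 1L) {
          sprintf("%s:%.15g", spp, len)
        } else {
          crown <- crown_fraction * len
          sprintf("%s:%.15g", yule_crown_newick(spp, crown), len - crown)
        }
      } else {
        inner <- paste(vapply(children[[as.character(id)]], node_str, ""),
                       collapse = ",")
        if (id == root) {
          sprintf("(%s);", inner)
        } else {
          sprintf("(%s):%.15g", inner, edge_len[id])
        }
      }
    }
    parse_newick_text(node_str(root))
  })
}

#' Simulate a sample of species-level trees from one backbone
#'
#' Repeats [resolve_genus_to_species()] `n_trees` times with per-tree seeds
#' `base_seed + i`, propagating the phylogenetic uncertainty of the unresolved
#' within-genus relationships.
#'
#' @inheritParams resolve_genus_to_species
#' @param n_trees Number of resolutions (study default 1000).
#' @param base_seed Integer seed from which per-tree seeds are derived.
#' @return A `tree_sample` object: list with `trees`, `seeds`, `size`.
#' @export
simulate_tree_sample <- function(backbone, assignment, n_trees = 1000,
                                 crown_fraction = 0.5, base_seed) {
  stop_if(n_trees < 1, "n_trees must be >= 1")
  stop_if(missing(base_seed), "an explicit base_seed is required")
  seeds <- vapply(seq_len(n_trees), function(i) derive_seed(base_seed, i), 1L)
  trees <- lapply(seeds, function(s) {
    resolve_genus_to_species(backbone, assignment, crown_fraction, seed = s)
  })
  out <- as_tree_sample(trees)
  out$seeds <- seeds
  out
}

# Canonical string keys for the clades (tip subsets) of a tree.
clade_keys <- function(tree, nontrivial_only = TRUE) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = "\r"), "")
  sizes <- lengths(pp)
  if (nontrivial_only) keys <- keys[sizes >= 2L]
  keys
}

#' Clade support frequencies across a tree sample
#'
#' @param sample A `tree_sample`.
#' @return Named numeric vector: for each clade observed in the sample (as a
#'   sorted tip-label key), the fraction of trees containing it.
#' @export
clade_frequencies <- function(sample) {
  stop_if(!inherits(sample, "tree_sample"), "need a tree_sample")
  all_keys <- unlist(lapply(sample$trees, clade_keys))
  tab <- table(all_keys) / sample$size
  setNames(as.numeric(tab), names(tab))
}

#' Maximum clade credibility tree of a sample
#'
#' Credibility of a tree is the sum over its non-trivial clades of the log of
#' that clade's frequency in the sample; the sample member maximizing it is
#' returned (ties broken by lowest tree index).
#'
#' @param sample A `tree_sample`.
#' @return The selected [ape::phylo], with attributes `credibility` (log scale)
#'   and `index` (position in the sample).
#' @export
mcc_tree <- function(sample) {
  stop_if(!inherits(sample, "tree_sample") || sample$size < 1,
          "need a nonempty tree_sample")
  freq <- clade_frequencies(sample)
  cred <- vapply(sample$trees, function(tr) {
    sum(log(freq[clade_keys(tr)]))
  }, 0)
  best <- which.max(cred)   # which.max returns the first maximum: lowest index
  out <- sample$trees[[best]]
  attr(out, "credibility") <- cred[best]
  attr(out, "index") <- best
  out
}

#' Patristic distance matrix of a tree
#'
#' @param tree An [ape::phylo].
#' @return Symmetric matrix of tip-to-tip path lengths, tips in
#'   `tree$tip.label` order.
#' @export
patristic <- function(tree) {
  validate_phylo(tree)
  stats::cophenetic(tree)[tree$tip.label, tree$tip.label]
}
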