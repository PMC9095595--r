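#' @useDynLib elevphylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile sd cor lm coef shapiro.test prcomp optimize
#'   setNames rbinom rexp runif complete.cases
#' @importFrom utils read.csv write.csv
NULL

#' Derived seed for the i-th replicate of a stochastic operation
#'
#' Stochastic stages derive per-replicate seeds as `base_seed + i`, folded
#' into the 32-bit integer range R's RNG accepts.
#'
#' @param base_seed Integer base seed.
#' @param i Replicate index.
#' @return An integer seed.
#' @export
derive_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) + as.numeric(i)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

is_binary <- function(m) all(m %in% c(0, 1))

#' Tolerance used for ultrametricity checks (relative).
#' @noRd
.ultra_tol <- 1e-8

# Root-to-tip depths of every tip, in tree branch-length units.
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- numeric(n_tip + tree$Nnode)
  root <- n_tip + 1L
  # edges are stored so a preorder pass works after sorting by parent depth;
  # ape guarantees parents appear before children in cladewise order
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    depth[tr$edge[k, 2L]] <- depth[tr$edge[k, 1L]] + tr$edge.length[k]
  }
  depth
}

tip_depths <- function(tree) {
  node_depths(tree)[seq_along(tree$tip.label)]
}

is_ultrametric_tol <- function(tree, tol = .ultra_tol) {
  d <- tip_depths(tree)
  (max(d) - min(d)) <= tol * max(max(d), .Machine$double.eps)
}
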