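#' Read a phylogeny from a Newick string or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is
#' the backbone of every comparative computation in the package, so the
#' invariants the downstream code relies on are enforced here: branch lengths
#' present on every edge, strictly positive (or optionally collapsed when
#' exactly zero), and unique tip labels.
#'
#' @param x A Newick string (anything containing `";"`) or a path to a file.
#' @param collapse_zero If `TRUE`, zero-length branches are collapsed into
#'   polytomies with [ape::di2multi()]; if `FALSE` (default) they are an error.
#' @return An object of class `phylo` (rooted; polytomies preserved).
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr)
read_newick <- function(x, collapse_zero = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  tr <- if (grepl(";", x, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = x),
             error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE))
  } else {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    ape::read.tree(x)
  }
  if (is.null(tr)) stop("Newick parse error: could not read a tree from input", call. = FALSE)
  validate_phylo(tr, collapse_zero = collapse_zero)
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

validate_phylo <- function(tree, collapse_zero = FALSE) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; time-calibrated branch lengths are required", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) stop("missing branch length on one or more edges", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed", call. = FALSE)
  if (any(tree$edge.length == 0)) {
    if (collapse_zero) {
      tree <- ape::di2multi(tree, tol = 0)
    } else {
      stop("zero-length branches present; use collapse_zero = TRUE to collapse them",
           call. = FALSE)
    }
  }
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique", call. = FALSE)
  tree
}

#' Tree height and ultrametricity
#'
#' `tree_height()` returns the maximum root-to-tip path length.
#' `is_ultrametric_tree()` checks whether all root-to-tip distances agree
#' within a relative tolerance (default `1e-6` times the height), the
#' criterion assumed by the OU covariance transform.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return `tree_height()`: a scalar in the tree's time units.
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' @rdname tree_height
#' @param tol Relative tolerance on root-to-tip distances.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(d)
}

# Root-to-node distance for every node (tips first, ape numbering).
node_depths <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  depth <- numeric(n_node)
  tr <- stats::reorder(tree) # cladewise: parents before children
  for (k in seq_len(nrow(tr$edge))) {
    depth[tr$edge[k, 2]] <- depth[tr$edge[k, 1]] + tr$edge.length[k]
  }
  depth
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip distances.
#' Under Brownian motion the trait covariance among tips is `sigma2 * vcv`.
#'
#' @param tree A `phylo` object.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  ape::vcv.phylo(tree)
}

#' Branch-length transformations of a phylogenetic covariance matrix
#'
#' Applies the covariance-level equivalent of the classical branch-length
#' transformations used in phylogenetic regression and trait-model fitting:
#'
#' * `"lambda"` (Pagel): off-diagonal entries multiplied by `lambda`,
#'   diagonal untouched. `lambda = 1` is Brownian motion, `lambda = 0` a
#'   star phylogeny.
#' * `"OU"` (single-optimum, fixed root, ultrametric tree of height T):
#'   entry (i, j) becomes `exp(-2 a (T - t_ij)) * (1 - exp(-2 a t_ij)) / (2 a)`
#'   where `t_ij` is the shared path length and `a` the attraction strength
#'   `alpha`. The overall rate `sigma2` multiplies this downstream.
#' * `"EB"` (early burst / ACDC with exponent `a <= 0`): entry becomes
#'   `(exp(a * t_ij) - 1) / a`, with the Brownian limit as `a -> 0`.
#'
#' @param C Covariance matrix from [phylo_vcv()] (possibly already scaled).
#' @param model One of `"lambda"`, `"OU"`, `"EB"`.
#' @param param The transformation parameter: `lambda` in \[0, 1\], `alpha > 0`
#'   or the EB exponent `a <= 0`.
#' @param tree_height Height T of the (ultrametric) tree; required for OU.
#' @param ultrametric Set `FALSE` to signal a non-ultrametric source tree;
#'   the OU transform then errors rather than silently mis-specifying.
#' @return The transformed covariance matrix.
#' @export
transform_covariance <- function(C, model = c("lambda", "OU", "EB"),
                                 param, tree_height = NULL, ultrametric = TRUE) {
  model <- match.arg(model)
  stopifnot(is.matrix(C), nrow(C) == ncol(C), is.numeric(param), length(param) == 1L)
  switch(model,
    lambda = {
      if (param < 0) stop("lambda must be in [0, 1]", call. = FALSE)
      if (param > 1) {
        if (param > 1 + 1e-8) warning("lambda > 1 clipped to 1")
        param <- 1
      }
      V <- C * param
      diag(V) <- diag(C)
      V
    },
    OU = {
      if (param <= 0) stop("alpha must be > 0 for the OU transform", call. = FALSE)
      if (!ultrametric) stop("OU transform requires an ultrametric tree", call. = FALSE)
      if (is.null(tree_height)) tree_height <- max(diag(C))
      a <- param
      (exp(-2 * a * (tree_height - C)) * (1 - exp(-2 * a * C))) / (2 * a)
    },
    EB = {
      if (param > 0) stop("EB exponent a must be <= 0", call. = FALSE)
      if (abs(param) < 1e-9) return(C) # Brownian limit; avoids 0/0 loss
      (exp(param * C) - 1) / param
    }
  )
}

#' Rescale a tree's branch lengths under Pagel's lambda
#'
#' Internal branches are multiplied by `lambda` and each terminal branch is
#' stretched so the tip keeps its original depth. The tip covariance of the
#' rescaled tree equals the lambda-transformed covariance of the original,
#' which is what ancestral-state estimation under a fitted lambda model needs.
#'
#' @param tree An ultrametric-or-not `phylo` object.
#' @param lambda Value in \[0, 1\].
#' @return A `phylo` object.
#' @export
rescale_tree_lambda <- function(tree, lambda) {
  stopifnot(lambda >= 0, lambda <= 1 + 1e-8)
  lambda <- min(lambda, 1)
  depth <- node_depths(tree)
  n_tip <- ape::Ntip(tree)
  tr <- tree
  is_tip_edge <- tr$edge[, 2] <= n_tip
  tr$edge.length <- tr$edge.length * lambda
  # restore original tip depths
  tip_depth_new <- depth[tr$edge[is_tip_edge, 2]] * lambda
  tr$edge.length[is_tip_edge] <- tr$edge.length[is_tip_edge] +
    (depth[tr$edge[is_tip_edge, 2]] - tip_depth_new)
  tr
}

# Depth of the MRCA of every pair of nodes (tips and internals), i.e. the
# joint BM covariance over all nodes. Used by ancestral-state conditioning.
joint_node_vcv <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  depth <- node_depths(tree)
  # ancestor sets via cladewise traversal
  parent <- integer(n_all)
  tr <- stats::reorder(tree)
  for (k in seq_len(nrow(tr$edge))) parent[tr$edge[k, 2]] <- tr$edge[k, 1]
  root <- n_tip + 1L
  anc_list <- vector("list", n_all)
  anc_list[[root]] <- root
  ord <- c(root, tr$edge[, 2]) # parents before children
  for (v in tr$edge[, 2]) anc_list[[v]] <- c(anc_list[[parent[v]]], v)
  V <- matrix(0, n_all, n_all)
  for (i in seq_len(n_all)) {
    ai <- anc_list[[i]]
    for (j in i:n_all) {
      common <- intersect(ai, anc_list[[j]])
      V[i, j] <- V[j, i] <- max(depth[common])
    }
  }
  V
}
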