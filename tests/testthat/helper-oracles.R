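# Independent oracles used across test files. These deliberately avoid the
# package's own computational paths: likelihoods by exhaustive enumeration
# over internal states, covariances by explicit path enumeration.

# Mk likelihood and marginal posteriors by brute-force enumeration over all
# internal-node state assignments (feasible for <= ~8 internal nodes).
enum_mk <- function(tree, states, q01, q10, root_prior = c(0.5, 0.5)) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  tr <- stats::reorder(tree)
  st <- states[tree$tip.label]
  internals <- (n_tip + 1L):n_all
  combs <- as.matrix(expand.grid(rep(list(0:1), length(internals))))
  pmat <- function(t) {
    s <- q01 + q10
    if (s == 0) return(diag(2))
    p0 <- q10 / s; p1 <- q01 / s; e <- exp(-s * t)
    matrix(c(p0 + p1 * e, p0 * (1 - e), p1 * (1 - e), p1 + p0 * e), 2)
  }
  P <- lapply(tr$edge.length, pmat)
  post <- matrix(0, length(internals), 2)
  tot <- 0
  for (r in seq_len(nrow(combs))) {
    full <- c(st, combs[r, ])
    lik <- root_prior[full[n_tip + 1L] + 1L]
    for (k in seq_len(nrow(tr$edge))) {
      lik <- lik * P[[k]][full[tr$edge[k, 1]] + 1L, full[tr$edge[k, 2]] + 1L]
    }
    tot <- tot + lik
    for (i in seq_along(internals)) {
      post[i, combs[r, i] + 1L] <- post[i, combs[r, i] + 1L] + lik
    }
  }
  list(lik = tot, post = post / tot)
}

# Phylogenetic covariance by explicit root-to-MRCA path enumeration.
enum_vcv <- function(tree) {
  n_tip <- ape::Ntip(tree)
  tr <- stats::reorder(tree)
  parent <- integer(n_tip + tree$Nnode)
  elen <- numeric(n_tip + tree$Nnode)
  for (k in seq_len(nrow(tr$edge))) {
    parent[tr$edge[k, 2]] <- tr$edge[k, 1]
    elen[tr$edge[k, 2]] <- tr$edge.length[k]
  }
  root <- n_tip + 1L
  path_to_root <- function(v) {
    p <- v
    while (v != root) { v <- parent[v]; p <- c(p, v) }
    p
  }
  V <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip)) {
    pi_ <- path_to_root(i)
    for (j in i:n_tip) {
      shared <- intersect(pi_, path_to_root(j))
      shared <- setdiff(shared, root)
      V[i, j] <- V[j, i] <- sum(elen[shared])
      if (i == j) V[i, i] <- sum(elen[setdiff(pi_, root)])
    }
  }
  V
}

# Random small tree with exponential branch lengths (not via simulate_tree,
# so tree-shape bugs cannot cancel).
random_small_tree <- function(n_tip) {
  tr <- ape::rtree(n_tip, br = stats::rexp)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

random_binary_states <- function(tree) {
  st <- sample(0:1, ape::Ntip(tree), replace = TRUE)
  names(st) <- tree$tip.label
  st
}
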