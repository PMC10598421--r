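#' Two-state Markov (Mk) models of web evolution
#'
#' The discrete-trait machinery is built around a two-state continuous-time
#' Markov chain on the phylogeny with states 0 = no web and 1 = web. Three
#' constraints are supported, mirroring the classical model set for binary
#' ecological characters:
#'
#' * `"ER"` — equal rates: gain rate `q01` equals loss rate `q10` (1 free rate);
#' * `"ARD"` — all rates different (2 free rates);
#' * `"DOLLO"` — re-evolution suppressed: `q01 = 0`, losses only (1 free
#'   rate). Under this constraint the root is fixed in state 1, since any
#'   observed web then requires a web-bearing ancestor.
#'
#' @name mk-models
NULL

# Transition probability matrix of the 2-state chain over time t (closed form).
mk_pmat <- function(q01, q10, t) {
  s <- q01 + q10
  if (s == 0) return(diag(2))
  p0 <- q10 / s # stationary P(state 0)
  p1 <- q01 / s
  e <- exp(-s * t)
  matrix(c(p0 + p1 * e, p0 * (1 - e),
           p1 * (1 - e), p1 + p0 * e),
         nrow = 2, byrow = FALSE,
         dimnames = list(from = c("0", "1"), to = c("0", "1")))
}

# Postorder pruning pass. Returns the per-node conditional likelihoods
# ("down" partials, scaled) plus the log scaling factors, for reuse by the
# likelihood, the marginal posteriors and the stochastic-map sampler.
mk_prune <- function(tree, states, q01, q10) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  if (is.null(names(states))) stop("tip states must be named by tip label", call. = FALSE)
  missing_tips <- setdiff(tree$tip.label, names(states))
  if (length(missing_tips)) {
    stop("tips without a state: ", paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  st <- states[tree$tip.label]
  if (!all(st %in% c(0, 1))) stop("states must be 0/1", call. = FALSE)
  L <- matrix(0, n_all, 2)
  L[cbind(seq_len(n_tip), st + 1L)] <- 1
  L[(n_tip + 1L):n_all, ] <- 1
  logscale <- 0
  tr <- stats::reorder(tree, "postorder")
  P <- vector("list", nrow(tr$edge))
  for (k in seq_len(nrow(tr$edge))) {
    P[[k]] <- mk_pmat(q01, q10, tr$edge.length[k])
    par <- tr$edge[k, 1]
    child <- tr$edge[k, 2]
    L[par, ] <- L[par, ] * as.vector(P[[k]] %*% L[child, ])
    if (child > n_tip) { # rescale freshly completed internal contributions
      m <- max(L[par, ])
      if (m > 0 && m < 1e-200) {
        L[par, ] <- L[par, ] / m
        logscale <- logscale + log(m)
      }
    }
  }
  list(L = L, logscale = logscale, tree_post = tr, P = P, st = st)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tree A `phylo` object with branch lengths.
#' @param states Named 0/1 vector of tip states (names = tip labels).
#' @param q01 Gain rate (0 to 1) per unit branch length.
#' @param q10 Loss rate (1 to 0).
#' @param root_prior Length-2 probability vector over states at the root
#'   (default equal).
#' @return The natural-log likelihood; `-Inf` when the data are impossible
#'   under the rates (for example mixed tip states with both rates zero).
#' @export
mk_loglik <- function(tree, states, q01, q10, root_prior = c(0.5, 0.5)) {
  stopifnot(q01 >= 0, q10 >= 0, length(root_prior) == 2, all(root_prior >= 0))
  root_prior <- root_prior / sum(root_prior)
  pr <- mk_prune(tree, states, q01, q10)
  root <- ape::Ntip(tree) + 1L
  lik <- sum(root_prior * pr$L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale
}

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimized on the log scale within `[1e-8, 1e3]` per unit branch
#' length, with multiple random starts for the two-rate model. The result
#' carries the AICc, `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with `n` the
#' number of tips, so fits can be compared with [aicc_weights()].
#'
#' @inheritParams mk_loglik
#' @param model `"ER"`, `"ARD"` or `"DOLLO"`.
#' @param root_prior Root state distribution; default equal for ER/ARD and
#'   fixed at state 1 for DOLLO.
#' @param n_starts Random multi-starts for ARD.
#' @param seed Optional seed making the multi-starts reproducible.
#' @return An object of class `mk_fit` with elements `model`, `q01`, `q10`,
#'   `logLik`, `k_free`, `n`, `AICc`, `root_prior`.
#' @export
fit_mk <- function(tree, states, model = c("ER", "ARD", "DOLLO"),
                   root_prior = NULL, n_starts = 5, seed = NULL) {
  model <- match.arg(model)
  n <- ape::Ntip(tree)
  if (is.null(root_prior)) {
    root_prior <- if (model == "DOLLO") c(0, 1) else c(0.5, 0.5)
  }
  st <- states[tree$tip.label]
  if (min(table(factor(st, levels = 0:1))) < 2) {
    warning("fewer than 2 tips in one state; rate estimates may be unstable")
  }
  lb <- log(1e-8); ub <- log(1e3)
  if (!is.null(seed)) set.seed(seed)
  if (model %in% c("ER", "DOLLO")) {
    f <- function(lq) {
      q <- exp(lq)
      if (model == "ER") -mk_loglik(tree, states, q, q, root_prior)
      else -mk_loglik(tree, states, 0, q, root_prior)
    }
    opt <- stats::optimize(f, c(lb, ub), tol = 1e-10)
    q <- exp(opt$minimum)
    q01 <- if (model == "ER") q else 0
    q10 <- q
    ll <- -opt$objective
    k <- 1L
  } else {
    f <- function(lq) -mk_loglik(tree, states, exp(lq[1]), exp(lq[2]), root_prior)
    starts <- rbind(c(log(0.1), log(0.1)),
                    matrix(stats::runif(2 * (n_starts - 1), lb / 2, log(10)),
                           ncol = 2))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(starts[i, ], f, method = "L-BFGS-B", lower = lb, upper = ub),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("ARD optimization failed from every start", call. = FALSE)
    q01 <- exp(best$par[1]); q10 <- exp(best$par[2])
    ll <- -best$value
    k <- 2L
  }
  structure(list(model = model, q01 = q01, q10 = q10, logLik = ll,
                 k_free = k, n = n, AICc = aicc(ll, k, n),
                 root_prior = root_prior),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk model fit (", x$model, ")\n", sep = "")
  cat(sprintf("  gain rate q01 = %.6g\n  loss rate q10 = %.6g\n", x$q01, x$q10))
  cat(sprintf("  logLik = %.4f   AICc = %.4f   (n = %d tips, k = %d)\n",
              x$logLik, x$AICc, x$n, x$k_free))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.mk_fit <- function(x, ...) {
  tibble::tibble(term = c("q01", "q10"), estimate = c(x$q01, x$q10))
}

#' @importFrom generics glance
#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$logLik, AICc = x$AICc,
                 k_free = x$k_free, n = x$n)
}

#' Small-sample corrected AIC
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (tip count by convention here).
#' @export
aicc <- function(logLik, k, n) {
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc weights for a set of fitted models
#'
#' Takes any list of fits exposing `$AICc` (e.g. [fit_mk()] or
#' [fit_continuous()] results) or a numeric vector of AICc values, and returns
#' the normalized evidence weights `w_i = exp(-d_i/2) / sum(exp(-d_j/2))`
#' where `d_i = AICc_i - min(AICc)`.
#'
#' @param fits List of fit objects, or numeric AICc values.
#' @return A tibble with one row per model: `model`, `logLik`, `AICc`,
#'   `delta_AICc`, `weight` (weights sum to 1).
#' @export
aicc_weights <- function(fits) {
  if (is.numeric(fits)) {
    a <- fits
    tab <- tibble::tibble(model = names(a) %||% as.character(seq_along(a)),
                          logLik = NA_real_, AICc = a)
  } else {
    tab <- purrr::map_dfr(fits, function(f) {
      tibble::tibble(model = f$model, logLik = f$logLik, AICc = f$AICc)
    })
  }
  d <- unname(tab$AICc - min(tab$AICc))
  w <- exp(-d / 2)
  tab$AICc <- unname(tab$AICc)
  tab$delta_AICc <- d
  tab$weight <- w / sum(w)
  dplyr::arrange(tab, .data$AICc)
}

#' Marginal ancestral state posteriors
#'
#' Computes, for every internal node, the marginal posterior probability of
#' each state given the tip data and rates, by the standard up-down
#' message-passing algorithm (down partials from pruning, up partials by a
#' preorder pass; equivalent to re-rooting at each node).
#'
#' @inheritParams mk_loglik
#' @return A tibble with columns `node` (ape node number), `p0`, `p1`.
#' @export
ancestral_posteriors <- function(tree, states, q01, q10, root_prior = c(0.5, 0.5)) {
  root_prior <- root_prior / sum(root_prior)
  pr <- mk_prune(tree, states, q01, q10)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  tr <- pr$tree_post
  # up partials: U[v, i] = P(data outside subtree(v) | state at v = i)
  U <- matrix(0, n_all, 2)
  U[root, ] <- root_prior
  # children lists and per-edge "message into parent" = P %*% L[child]
  msg <- matrix(0, nrow(tr$edge), 2)
  for (k in seq_len(nrow(tr$edge))) msg[k, ] <- pr$P[[k]] %*% pr$L[tr$edge[k, 2], ]
  edges_of_parent <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  # preorder = reverse postorder over edges
  for (k in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
    sibs <- setdiff(edges_of_parent[[as.character(par)]], k)
    above <- U[par, ]
    for (s in sibs) above <- above * msg[s, ]
    U[child, ] <- as.vector(t(pr$P[[k]]) %*% above)
    m <- max(U[child, ])
    if (m > 0) U[child, ] <- U[child, ] / m
  }
  post <- pr$L * U
  post <- post / rowSums(post)
  tibble::tibble(node = (n_tip + 1L):n_all,
                 p0 = post[(n_tip + 1L):n_all, 1],
                 p1 = post[(n_tip + 1L):n_all, 2])
}

# --- endpoint-conditioned path sampling ------------------------------------

# Forward-simulate the 2-state chain from `from` over time t; first event
# optionally forced into [0, t] (truncated exponential) when forced = TRUE.
sim_path_forward <- function(from, t, rates, forced = FALSE) {
  times <- numeric(0); states <- integer(0)
  cur <- from; now <- 0
  first <- TRUE
  repeat {
    r <- rates[cur + 1L]
    if (r == 0) break
    if (first && forced) {
      u <- stats::runif(1)
      dt <- -log(1 - u * (1 - exp(-r * t))) / r
    } else {
      dt <- stats::rexp(1, r)
    }
    first <- FALSE
    now <- now + dt
    if (now >= t) break
    cur <- 1L - cur
    times <- c(times, now); states <- c(states, cur)
  }
  list(end = cur, times = times, states = states)
}

# Uniformization sampler for a 2-state path conditioned on both endpoints.
sim_path_uniformized <- function(from, to, t, q01, q10) {
  rates <- c(q01, q10)
  Lam <- max(rates)
  Q <- matrix(c(-q01, q01, q10, -q10), 2, byrow = TRUE)
  B <- diag(2) + Q / Lam
  Pij <- mk_pmat(q01, q10, t)[from + 1L, to + 1L]
  # sample number of auxiliary jumps n
  u <- stats::runif(1) * Pij
  n <- 0L
  Bn <- diag(2) # B^n
  cum <- 0
  lt <- Lam * t
  repeat {
    term <- exp(-lt + n * log(lt) - lgamma(n + 1)) * Bn[from + 1L, to + 1L]
    cum <- cum + term
    if (cum >= u || n > 10000L) break
    n <- n + 1L
    Bn <- Bn %*% B
  }
  if (n == 0L) return(list(times = numeric(0), states = integer(0)))
  # powers of B up to n for the bridge
  Bpow <- vector("list", n + 1L)
  Bpow[[1]] <- diag(2)
  for (m in seq_len(n)) Bpow[[m + 1]] <- Bpow[[m]] %*% B
  jump_states <- integer(n)
  cur <- from
  for (m in seq_len(n)) {
    w <- B[cur + 1L, ] * Bpow[[n - m + 1L]][, to + 1L]
    cur <- sample.int(2L, 1L, prob = w) - 1L
    jump_states[m] <- cur
  }
  times <- sort(stats::runif(n, 0, t))
  keep <- logical(n)
  prev <- from
  for (m in seq_len(n)) { # drop virtual (self) jumps
    keep[m] <- jump_states[m] != prev
    prev <- jump_states[m]
  }
  list(times = times[keep], states = jump_states[keep])
}

# One endpoint-conditioned path: rejection sampling with uniformization
# fallback after `max_reject` failures.
sim_path_conditional <- function(from, to, t, q01, q10, max_reject = 1000L) {
  rates <- c(q01, q10)
  if (rates[from + 1L] == 0 && from != to) {
    stop("impossible endpoint pair under the rate matrix", call. = FALSE)
  }
  if (from == to && rates[from + 1L] == 0) {
    return(list(times = numeric(0), states = integer(0)))
  }
  for (i in seq_len(max_reject)) {
    # when from != to the first jump is forced into [0, t] (truncated
    # exponential) and the draw accepted iff the end state matches
    p <- sim_path_forward(from, t, rates, forced = from != to)
    if (p$end == to) return(list(times = p$times, states = p$states))
  }
  sim_path_uniformized(from, to, t, q01, q10)
}

#' Sample stochastic character maps
#'
#' Draws full character histories conditional on the tip data and rates:
#' node states are sampled from their joint conditional distribution by
#' backward sampling on the pruning partials, then each branch history is
#' sampled conditional on its endpoint states (rejection sampling with a
#' uniformization fallback). Transition counts (losses 1 to 0, gains 0 to 1)
#' are tallied per map.
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of maps to sample.
#' @param seed Optional RNG seed.
#' @return A list of class `simmap_sample`: `maps` — tibble of events
#'   (`map`, `edge`, `time`, `from`, `to`); `node_states` — integer matrix
#'   (maps x nodes) of sampled states for all nodes; `counts` — tibble with
#'   per-map `n_loss`, `n_gain`; `mean_loss`, `mean_gain`.
#' @export
sample_maps <- function(tree, states, q01, q10, n_maps = 100,
                        root_prior = c(0.5, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  root_prior <- root_prior / sum(root_prior)
  if (!is.finite(mk_loglik(tree, states, q01, q10, root_prior))) {
    stop("tip data impossible under the supplied rates/root prior", call. = FALSE)
  }
  pr <- mk_prune(tree, states, q01, q10)
  tr <- pr$tree_post
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  n_edge <- nrow(tr$edge)
  edge_order <- rev(seq_len(n_edge)) # preorder
  node_states <- matrix(NA_integer_, n_maps, n_all)
  ev_map <- list()
  n_loss <- integer(n_maps); n_gain <- integer(n_maps)
  for (m in seq_len(n_maps)) {
    ns <- integer(n_all)
    w_root <- root_prior * pr$L[root, ]
    ns[root] <- sample.int(2L, 1L, prob = w_root) - 1L
    ev_list <- vector("list", n_edge)
    losses <- 0L; gains <- 0L
    for (k in edge_order) {
      par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
      w <- pr$P[[k]][ns[par] + 1L, ] * pr$L[child, ]
      ns[child] <- sample.int(2L, 1L, prob = w) - 1L
      path <- sim_path_conditional(ns[par], ns[child], tr$edge.length[k], q01, q10)
      if (length(path$times)) {
        from_states <- c(ns[par], path$states[-length(path$states)])
        ev_list[[k]] <- data.frame(edge = k, time = path$times,
                                   from = from_states, to = path$states)
        losses <- losses + sum(from_states == 1L & path$states == 0L)
        gains <- gains + sum(from_states == 0L & path$states == 1L)
      }
    }
    node_states[m, ] <- ns
    ev <- dplyr::bind_rows(ev_list)
    if (nrow(ev)) ev$map <- m
    ev_map[[m]] <- ev
    n_loss[m] <- losses; n_gain[m] <- gains
  }
  maps <- dplyr::bind_rows(ev_map)
  if (!nrow(maps)) {
    maps <- tibble::tibble(map = integer(), edge = integer(), time = numeric(),
                           from = integer(), to = integer())
  } else {
    maps <- tibble::as_tibble(maps[, c("map", "edge", "time", "from", "to")])
  }
  structure(list(maps = maps,
                 node_states = node_states,
                 counts = tibble::tibble(map = seq_len(n_maps),
                                         n_loss = n_loss, n_gain = n_gain),
                 mean_loss = mean(n_loss), mean_gain = mean(n_gain),
                 tree = tree, q01 = q01, q10 = q10),
            class = "simmap_sample")
}

#' @export
print.simmap_sample <- function(x, ...) {
  cat("Stochastic character maps:", nrow(x$counts), "maps\n")
  cat(sprintf("  mean losses (1->0): %.2f\n  mean gains  (0->1): %.2f\n",
              x$mean_loss, x$mean_gain))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
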