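test_that("cherry likelihood matches the closed form", {
  tr <- read_newick("(A:1,B:1);")
  # ER q = 0.5, t = 1, tips (0,1), equal root prior:
  # (0.5 + 0.5 e^-2qt)(0.5 - 0.5 e^-2qt)
  expect_equal(exp(mk_loglik(tr, c(A = 0, B = 1), 0.5, 0.5)),
               (0.5 + 0.5 * exp(-1)) * (0.5 - 0.5 * exp(-1)),
               tolerance = 1e-12)
  expect_equal(exp(mk_loglik(tr, c(A = 0, B = 1), 0.5, 0.5)), 0.21617,
               tolerance = 1e-4)
})

test_that("zero-rate limits behave", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(mk_loglik(tr, c(A = 0, B = 0, C = 0), 0, 0), log(0.5))
  expect_equal(mk_loglik(tr, c(A = 0, B = 1, C = 0), 0, 0), -Inf)
  expect_error(mk_loglik(tr, c(A = 0, B = 1), 0.5, 0.5), "without a state")
})

test_that("pruning equals exhaustive enumeration on random small trees", {
  set.seed(123)
  for (i in 1:25) {
    tr <- random_small_tree(sample(2:6, 1))
    st <- random_binary_states(tr)
    q01 <- runif(1, 0.05, 2); q10 <- runif(1, 0.05, 2)
    e <- enum_mk(tr, st, q01, q10)
    expect_equal(mk_loglik(tr, st, q01, q10), log(e$lik), tolerance = 1e-10)
  }
})

test_that("transition matrices are proper stochastic matrices", {
  for (q01 in c(0, 0.3, 5)) for (q10 in c(0.01, 2)) for (t in c(0.1, 1, 40)) {
    P <- phylosprint:::mk_pmat(q01, q10, t)
    expect_equal(rowSums(P), c("0" = 1, "1" = 1), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("fit_mk honours constraints and nesting", {
  tr <- simulate_tree(80, seed = 21)
  st <- simulate_discrete(tr, 0.4, 0.7, seed = 2)$tip_states
  er <- fit_mk(tr, st, "ER")
  ard <- fit_mk(tr, st, "ARD", seed = 1)
  dollo <- fit_mk(tr, st, "DOLLO")
  expect_equal(er$q01, er$q10)
  expect_equal(dollo$q01, 0)
  expect_gte(ard$logLik, er$logLik - 1e-6) # ER nested in ARD
  expect_equal(er$AICc, aicc(er$logLik, 1, 80))
  expect_equal(glance(er)$AICc, er$AICc)
  expect_equal(tidy(dollo)$estimate[1], 0)
})

test_that("ER rate is recovered from simulated data", {
  tr <- simulate_tree(300, seed = 31)
  tr$edge.length <- tr$edge.length / tree_height(tr)
  hits <- 0
  for (s in 1:20) {
    st <- simulate_discrete(tr, 0.3, 0.3, seed = s)$tip_states
    f <- suppressWarnings(fit_mk(tr, st, "ER"))
    if (f$q01 >= 0.15 && f$q01 <= 0.6) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("AICc weights follow the exponential-delta formula", {
  w <- aicc_weights(c(a = 100, b = 100))
  expect_equal(w$weight, c(0.5, 0.5))
  w2 <- aicc_weights(c(best = 10, other = 12))
  expect_equal(w2$weight, c(exp(0), exp(-1)) / (exp(0) + exp(-1)),
               tolerance = 1e-12)
  expect_equal(w2$weight, c(0.7310586, 0.2689414), tolerance = 1e-6)
  w3 <- aicc_weights(c(4, 9, 2.5))
  expect_equal(sum(w3$weight), 1)
})

test_that("ancestral posteriors match enumeration and symmetry cases", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  all1 <- ancestral_posteriors(tr, c(A = 1, B = 1, C = 1), 0, 0.0)
  expect_equal(all1$p1, c(1, 1))

  cherry <- read_newick("(A:1,B:1);")
  sym <- ancestral_posteriors(cherry, c(A = 0, B = 1), 0.5, 0.5)
  expect_equal(sym$p1, 0.5)

  set.seed(77)
  for (i in 1:20) {
    tr <- random_small_tree(sample(3:6, 1))
    st <- random_binary_states(tr)
    q01 <- runif(1, 0.05, 1.5); q10 <- runif(1, 0.05, 1.5)
    ap <- ancestral_posteriors(tr, st, q01, q10)
    e <- enum_mk(tr, st, q01, q10)
    expect_equal(ap$p1, e$post[, 2], tolerance = 1e-10)
  }
})

test_that("stochastic maps are endpoint-consistent and count correctly", {
  tr <- simulate_tree(12, seed = 41)
  st <- simulate_discrete(tr, 0.6, 0.6, seed = 3)$tip_states
  sm <- sample_maps(tr, st, 0.6, 0.6, n_maps = 50, seed = 5)
  n_tip <- ape::Ntip(tr)
  tr_post <- stats::reorder(tr, "postorder")
  for (m in c(1, 25, 50)) {
    ns <- sm$node_states[m, ]
    expect_equal(unname(ns[seq_len(n_tip)]), unname(st[tr$tip.label]))
    ev <- sm$maps[sm$maps$map == m, ]
    for (k in seq_len(nrow(tr_post$edge))) {
      e_k <- ev[ev$edge == k, ]
      start <- ns[tr_post$edge[k, 1]]
      end <- if (nrow(e_k)) e_k$to[nrow(e_k)] else start
      expect_equal(end, unname(ns[tr_post$edge[k, 2]]))
      if (nrow(e_k)) {
        expect_true(all(diff(e_k$time) > 0))
        expect_true(all(e_k$time < tr_post$edge.length[k]))
        expect_equal(e_k$from[1], unname(start))
        expect_true(all(e_k$from != e_k$to))
      }
    }
    expect_equal(sm$counts$n_loss[m], sum(ev$from == 1 & ev$to == 0))
    expect_equal(sm$counts$n_gain[m], sum(ev$from == 0 & ev$to == 1))
  }
  # near-zero rates on uniform data produce essentially no events
  uni <- rep(1, 12); names(uni) <- tr$tip.label
  sm0 <- sample_maps(tr, uni, 1e-8, 1e-8, n_maps = 20, seed = 1)
  expect_lte(sm0$mean_loss + sm0$mean_gain, 0.01)
})

test_that("Dollo maps never contain a gain and reject impossible endpoints", {
  tr <- simulate_tree(15, seed = 51)
  st <- simulate_discrete(tr, 0, 0.5, root_state = 1, seed = 2)$tip_states
  sm <- sample_maps(tr, st, 0, 0.5, n_maps = 100, root_prior = c(0, 1), seed = 7)
  expect_equal(sum(sm$counts$n_gain), 0)
  expect_error(phylosprint:::sim_path_conditional(0, 1, 1, 0, 0.5),
               "impossible")
})

test_that("map node-state frequencies agree with marginal posteriors", {
  set.seed(61)
  tr <- random_small_tree(6)
  st <- c(0, 1, 1, 0, 1, 1); names(st) <- tr$tip.label
  q01 <- 0.4; q10 <- 0.6
  sm <- sample_maps(tr, st, q01, q10, n_maps = 2000, seed = 9)
  ap <- ancestral_posteriors(tr, st, q01, q10)
  freq <- colMeans(sm$node_states[, ap$node, drop = FALSE])
  expect_lt(max(abs(freq - ap$p1)), 0.04) # MC error at 2000 maps
})

test_that("mean map counts match forward-simulation truth under matched rates", {
  # paired comparison: for each replicate, the generating history's counts
  # vs the mean counts of maps sampled from that replicate's tip data
  tr <- simulate_tree(100, seed = 71)
  tr$edge.length <- tr$edge.length / tree_height(tr)
  q <- 0.4
  diffs <- t(vapply(1:15, function(s) {
    sim <- simulate_discrete(tr, q, q, seed = s)
    sm <- sample_maps(tr, sim$tip_states, q, q, n_maps = 30, seed = 500 + s)
    c(sm$mean_loss - sim$n_loss, sm$mean_gain - sim$n_gain)
  }, numeric(2)))
  se <- apply(diffs, 2, sd) / sqrt(nrow(diffs))
  expect_lt(abs(mean(diffs[, 1])), 3 * se[1] + 0.5)
  expect_lt(abs(mean(diffs[, 2])), 3 * se[2] + 0.5)
})

test_that("uniformization path sampler matches transition probabilities", {
  # distribution check: P(no event | 0 -> 0) over t from the sampler's
  # acceptance structure vs closed form
  q01 <- 0.8; q10 <- 0.3; t <- 0.9
  set.seed(5)
  draws <- replicate(4000, {
    p <- phylosprint:::sim_path_uniformized(0, 0, t, q01, q10)
    length(p$times) == 0
  })
  P <- phylosprint:::mk_pmat(q01, q10, t)
  p_no_event <- exp(-q01 * t) / P[1, 1]
  expect_lt(abs(mean(draws) - p_no_event), 0.03)
})
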