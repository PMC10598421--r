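test_that("cherry BM log-likelihood matches the bivariate normal density", {
  tr <- read_newick("(A:1,B:1);")
  # identity covariance, values (0,0): logL = -log(2 pi)
  expect_equal(cont_loglik(tr, c(A = 0, B = 0), "BM", sigma2 = 1, z0 = 0),
               -log(2 * pi), tolerance = 1e-12)
})

test_that("transform identities carry over to the likelihood", {
  tr <- simulate_tree(25, seed = 81)
  x <- simulate_continuous(tr, "BM", sigma2 = 1.5, z0 = 2, seed = 1)
  expect_equal(cont_loglik(tr, x, "lambda", 1.5, 2, param = 1),
               cont_loglik(tr, x, "BM", 1.5, 2))
  expect_equal(cont_loglik(tr, x, "EB", 1.5, 2, param = -1e-9),
               cont_loglik(tr, x, "BM", 1.5, 2), tolerance = 1e-6)
})

test_that("Cholesky likelihood equals dense-inverse evaluation", {
  set.seed(91)
  for (i in 1:5) {
    tr <- simulate_tree(30, seed = 90 + i)
    x <- simulate_continuous(tr, "BM", sigma2 = 2, z0 = 1, seed = i)
    V <- 2 * phylo_vcv(tr)
    dev <- as.numeric(x[tr$tip.label]) - 1
    dense <- -0.5 * (30 * log(2 * pi) + determinant(V)$modulus +
                     t(dev) %*% solve(V) %*% dev)
    expect_equal(cont_loglik(tr, x, "BM", 2, 1), as.numeric(dense),
                 tolerance = 1e-9)
  }
})

test_that("fit_continuous recovers BM parameters and respects nesting", {
  tr <- simulate_tree(200, seed = 101)
  hits <- 0
  for (s in 1:20) {
    x <- simulate_continuous(tr, "BM", sigma2 = 2, z0 = 0, seed = s)
    f <- fit_continuous(tr, x, "BM")
    if (f$sigma2 > 1.5 && f$sigma2 < 2.5) hits <- hits + 1
    if (s == 1) {
      fl <- fit_continuous(tr, x, "lambda")
      expect_gte(fl$logLik, f$logLik - 1e-6) # BM nested in lambda
    }
  }
  expect_gte(hits, 16)
})

test_that("lambda fit detects a star phylogeny signal", {
  tr <- simulate_tree(200, seed = 111)
  hits <- 0
  for (s in 1:20) {
    x <- simulate_continuous(tr, "lambda", sigma2 = 1, z0 = 0, param = 0, seed = s)
    f <- fit_continuous(tr, x, "lambda")
    if (f$param <= 0.1) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("profiled estimates agree with an independent GLS implementation", {
  tr <- simulate_tree(40, seed = 121)
  x <- simulate_continuous(tr, "BM", sigma2 = 2, z0 = 3, seed = 5)
  f <- fit_continuous(tr, x, "BM")
  d <- data.frame(x = as.numeric(x[tr$tip.label]), sp = tr$tip.label)
  g <- nlme::gls(x ~ 1, data = d,
                 correlation = ape::corBrownian(phy = tr, form = ~sp),
                 method = "ML")
  expect_equal(f$z0, unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("model table ranks by AICc with weights summing to one", {
  tr <- simulate_tree(100, seed = 131)
  x <- simulate_continuous(tr, "OU", sigma2 = 1, z0 = 0,
                           param = 2 / tree_height(tr), seed = 3)
  tab <- model_table(tr, x)
  expect_setequal(tab$model, c("BM", "OU", "EB", "lambda"))
  expect_equal(sum(tab$weight), 1)
  expect_true(!is.unsorted(tab$AICc))
  expect_equal(tab$delta_AICc[1], 0)
})

test_that("ancestral values: constants, symmetry, and conditional-normal oracle", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  cst <- c(A = 4, B = 4, C = 4)
  f4 <- structure(list(model = "BM", sigma2 = 1, z0 = 4, param = NA_real_),
                  class = "cont_fit")
  av <- ancestral_values(tr, cst, f4)
  expect_equal(av$estimate, rep(4, 2), tolerance = 1e-8)

  cherry <- read_newick("(A:1,B:1);")
  xc <- c(A = 1, B = 5)
  fc <- structure(list(model = "BM", sigma2 = 1, z0 = 3, param = NA_real_),
                  class = "cont_fit")
  expect_equal(ancestral_values(cherry, xc, fc)$estimate, 3)

  set.seed(141)
  for (i in 1:5) {
    tr <- random_small_tree(sample(4:6, 1))
    x <- simulate_continuous(tr, "BM", sigma2 = 1, z0 = 0, seed = i)
    f <- fit_continuous(tr, x, "BM")
    av <- ancestral_values(tr, x, f)
    # oracle: explicit joint-normal conditioning from first principles
    n_tip <- ape::Ntip(tr)
    J <- phylosprint:::joint_node_vcv(tr)
    tips <- seq_len(n_tip); nodes <- (n_tip + 1):(n_tip + tr$Nnode)
    mu <- f$z0 + J[nodes, tips] %*%
      solve(J[tips, tips], as.numeric(x[tr$tip.label]) - f$z0)
    expect_equal(av$estimate, as.numeric(mu), tolerance = 1e-8)
    # cross-check against ape's ML reconstruction
    expect_equal(av$estimate, unname(ape::ace(x, tr, method = "ML")$ace),
                 tolerance = 1e-4)
  }
  fo <- structure(list(model = "OU", sigma2 = 1, z0 = 0, param = 1),
                  class = "cont_fit")
  expect_error(ancestral_values(tr, x, fo), "BM and lambda")
})
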