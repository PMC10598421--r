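#' Continuous-trait evolutionary models
#'
#' Species-level continuous traits (sprint speed in body lengths per second,
#' spination index) are modelled as a multivariate normal over the tips with
#' mean `z0` (the root value) and covariance `sigma2 * T(C)`, where `C` is the
#' Brownian-motion covariance of the tree and `T` one of the branch-length
#' transformations:
#'
#' * `"BM"` — `T(C) = C` (2 free parameters: `sigma2`, `z0`);
#' * `"OU"` — single-optimum Ornstein-Uhlenbeck with the optimum tied to the
#'   root value and attraction `alpha` (3 parameters);
#' * `"EB"` — early burst with exponent `a <= 0` (3 parameters);
#' * `"lambda"` — Pagel's lambda scaling of the off-diagonal covariance
#'   (3 parameters).
#'
#' @name continuous-models
NULL

cont_build_V <- function(C, model, param, tree_height, ultrametric = TRUE) {
  switch(model,
    BM = C,
    OU = transform_covariance(C, "OU", param, tree_height, ultrametric),
    EB = transform_covariance(C, "EB", param),
    lambda = transform_covariance(C, "lambda", param)
  )
}

#' Log-likelihood of a continuous-trait model
#'
#' Multivariate-normal log density of the tip values with mean `z0` and
#' covariance `sigma2 * T(C)`, evaluated through a Cholesky factorization.
#'
#' @param tree A `phylo` object.
#' @param trait Named numeric vector of tip values (names = tip labels).
#' @param model One of `"BM"`, `"OU"`, `"EB"`, `"lambda"`.
#' @param sigma2 Rate parameter (> 0), trait units squared per unit time.
#' @param z0 Root value (and OU optimum).
#' @param param Transformation parameter (`alpha`, `a` or `lambda`); ignored
#'   for BM.
#' @return Scalar log-likelihood.
#' @export
cont_loglik <- function(tree, trait, model = c("BM", "OU", "EB", "lambda"),
                        sigma2, z0, param = NULL) {
  model <- match.arg(model)
  x <- align_trait(tree, trait)
  C <- phylo_vcv(tree)
  V <- cont_build_V(C, model, param, tree_height(tree),
                    ultrametric = is_ultrametric_tree(tree))
  mvn_loglik(x, rep(z0, length(x)), sigma2 * V)
}

mvn_loglik <- function(x, mu, V) {
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

align_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait values must be named by tip label", call. = FALSE)
  missing_tips <- setdiff(tree$tip.label, names(trait))
  if (length(missing_tips)) {
    stop("tips without trait values: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  trait[tree$tip.label]
}

# Profile z0 and sigma2 analytically (GLS / ML estimators) for a fixed
# unit-rate covariance V0; returns the profiled log-likelihood and estimates.
profile_gls <- function(x, V0) {
  n <- length(x)
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(list(logLik = -Inf))
  ones <- rep(1, n)
  iV1 <- backsolve(R, backsolve(R, ones, transpose = TRUE))
  z0 <- sum(iV1 * x) / sum(iV1)
  r <- x - z0
  w <- backsolve(R, r, transpose = TRUE)
  s2 <- sum(w^2) / n
  if (s2 <= 0) return(list(logLik = -Inf))
  ll <- -0.5 * n * log(2 * pi * s2) - sum(log(diag(R))) - 0.5 * n
  list(logLik = ll, z0 = z0, sigma2 = s2)
}

#' Fit a continuous-trait model by maximum likelihood
#'
#' The root value `z0` and rate `sigma2` are profiled analytically via GLS
#' inside a bounded one-dimensional search over the remaining parameter
#' (`alpha` for OU in `[1e-8, 50/T]`, `a` for EB in `[-10/T, 0]`, `lambda`
#' in `[0, 1]`, with T the tree height). AICc uses the tip count as sample
#' size.
#'
#' @inheritParams cont_loglik
#' @return Object of class `cont_fit`: `model`, `sigma2`, `z0`, `param`
#'   (`NA` for BM), `logLik`, `k_free`, `n`, `AICc`.
#' @export
fit_continuous <- function(tree, trait, model = c("BM", "OU", "EB", "lambda")) {
  model <- match.arg(model)
  x <- align_trait(tree, trait)
  n <- length(x)
  if (n < 3) stop("need at least 3 tips", call. = FALSE)
  C <- phylo_vcv(tree)
  Tht <- tree_height(tree)
  ultra <- is_ultrametric_tree(tree)
  if (model == "OU" && !ultra) stop("OU fit requires an ultrametric tree", call. = FALSE)
  if (model == "BM") {
    p <- profile_gls(x, C)
    fit <- list(param = NA_real_, logLik = p$logLik, z0 = p$z0, sigma2 = p$sigma2)
    k <- 2L
  } else {
    bounds <- switch(model,
      OU = c(1e-8, 50 / Tht),
      EB = c(-10 / Tht, -1e-10),
      lambda = c(0, 1))
    obj <- function(par) {
      V <- cont_build_V(C, model, par, Tht, ultra)
      -profile_gls(x, V)$logLik
    }
    opt <- stats::optimize(obj, bounds, tol = 1e-8)
    # compare against the boundary values (BM limits live there)
    cand <- c(opt$minimum, bounds)
    vals <- vapply(cand, obj, numeric(1))
    par_hat <- cand[which.min(vals)]
    p <- profile_gls(x, cont_build_V(C, model, par_hat, Tht, ultra))
    fit <- list(param = par_hat, logLik = p$logLik, z0 = p$z0, sigma2 = p$sigma2)
    k <- 3L
  }
  structure(list(model = model, sigma2 = fit$sigma2, z0 = fit$z0,
                 param = fit$param, logLik = fit$logLik, k_free = k, n = n,
                 AICc = aicc(fit$logLik, k, n)),
            class = "cont_fit")
}

#' @export
print.cont_fit <- function(x, ...) {
  pname <- switch(x$model, BM = NULL, OU = "alpha", EB = "a", lambda = "lambda")
  cat("Continuous-trait model fit (", x$model, ")\n", sep = "")
  cat(sprintf("  sigma2 = %.6g   z0 = %.6g", x$sigma2, x$z0))
  if (!is.null(pname)) cat(sprintf("   %s = %.6g", pname, x$param))
  cat(sprintf("\n  logLik = %.4f   AICc = %.4f   (n = %d, k = %d)\n",
              x$logLik, x$AICc, x$n, x$k_free))
  invisible(x)
}

#' @export
tidy.cont_fit <- function(x, ...) {
  pname <- switch(x$model, BM = character(0), OU = "alpha", EB = "a", lambda = "lambda")
  tibble::tibble(term = c("sigma2", "z0", pname),
                 estimate = c(x$sigma2, x$z0, if (length(pname)) x$param))
}

#' @export
glance.cont_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$logLik, AICc = x$AICc,
                 k_free = x$k_free, n = x$n)
}

#' Ranked model-comparison table
#'
#' Fits the requested model set to one trait and ranks by AICc with evidence
#' weights.
#'
#' @inheritParams fit_continuous
#' @param models Character vector of models to fit.
#' @return A tibble: `model`, `sigma2`, `z0`, `param`, `logLik`, `AICc`,
#'   `delta_AICc`, `weight`.
#' @export
model_table <- function(tree, trait, models = c("BM", "OU", "EB", "lambda")) {
  fits <- purrr::map(models, function(m) fit_continuous(tree, trait, m))
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$model, sigma2 = f$sigma2, z0 = f$z0,
                   param = f$param, logLik = f$logLik, AICc = f$AICc)
  })
  w <- aicc_weights(fits)
  dplyr::left_join(tab, w[, c("model", "delta_AICc", "weight")], by = "model") |>
    dplyr::arrange(.data$AICc)
}

#' Ancestral value estimates under BM or a fitted lambda model
#'
#' Expected trait values at internal nodes given the tip data: the
#' conditional mean of the joint tip-plus-node normal distribution under the
#' fitted model (for lambda, the tree is rescaled so its tip covariance
#' matches the lambda transform, then BM conditioning applies).
#'
#' @inheritParams fit_continuous
#' @param fit A `cont_fit` of model `"BM"` or `"lambda"`.
#' @return A tibble: `node` (ape numbering), `estimate`.
#' @export
ancestral_values <- function(tree, trait, fit) {
  stopifnot(inherits(fit, "cont_fit"))
  if (!fit$model %in% c("BM", "lambda")) {
    stop("ancestral values supported for BM and lambda fits only", call. = FALSE)
  }
  x <- align_trait(tree, trait)
  tr <- if (fit$model == "lambda") rescale_tree_lambda(tree, fit$param) else tree
  n_tip <- ape::Ntip(tr)
  n_all <- n_tip + tr$Nnode
  J <- joint_node_vcv(tr) # BM covariance over tips + internal nodes
  tips <- seq_len(n_tip)
  nodes <- (n_tip + 1L):n_all
  Vtt <- J[tips, tips]
  Vnt <- J[nodes, tips, drop = FALSE]
  R <- chol(Vtt)
  iV_dev <- backsolve(R, backsolve(R, x - fit$z0, transpose = TRUE))
  est <- fit$z0 + as.vector(Vnt %*% iV_dev)
  tibble::tibble(node = nodes, estimate = est)
}
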