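#' Synthetic data with known ground truth
#'
#' Every input the pipeline consumes can be generated with known parameters:
#' birth-death trees, binary traits evolved under a two-state Markov process
#' (with the full event history retained), continuous traits under
#' BM/OU/EB/lambda, regression datasets with a binary-predictor mean shift,
#' and tracking trajectories built from a smooth speed profile plus a
#' periodic body-centre oscillation plus Gaussian pixel jitter. All
#' generators are deterministic given their `seed`.
#'
#' @name synthetic-data
NULL

#' Simulate an ultrametric birth-death tree
#'
#' Wraps [ape::rphylo()] (conditioned on the number of extant tips) and
#' validates the result against the package's tree invariants.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth,death Speciation and extinction rates per unit time
#'   (`birth > death >= 0`).
#' @param seed Optional RNG seed.
#' @return A `phylo` object, ultrametric with positive branch lengths.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  stopifnot(n_tips >= 2, birth > death, death >= 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = death, fossils = FALSE)
  # guard against numerically zero branches from the sampler
  tr$edge.length[tr$edge.length < 1e-10] <- 1e-10
  validate_phylo(tr)
}

#' Forward-simulate a binary character with full history
#'
#' States evolve root-to-tips by exponential waiting times under the rate
#' matrix with gain rate `q01` (0 to 1) and loss rate `q10`. The complete
#' per-branch event history is returned so inference (stochastic maps,
#' fitted rates) can be checked against the generating truth.
#'
#' @param tree A `phylo` object.
#' @param q01,q10 Gain and loss rates (>= 0).
#' @param root_state Root state, or `NULL` to draw from `root_prior`.
#' @param root_prior Distribution used when `root_state` is `NULL`.
#' @param seed Optional RNG seed.
#' @return A list: `tip_states` (named 0/1 vector), `node_states` (all
#'   nodes, ape numbering), `history` — tibble (`edge`, `time`, `from`,
#'   `to`) of every event, `n_loss`, `n_gain`.
#' @export
simulate_discrete <- function(tree, q01, q10, root_state = NULL,
                              root_prior = c(0.5, 0.5), seed = NULL) {
  stopifnot(q01 >= 0, q10 >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  tr <- stats::reorder(tree) # cladewise: parents before children
  ns <- integer(n_all)
  ns[root] <- if (is.null(root_state)) {
    sample(0:1, 1, prob = root_prior)
  } else as.integer(root_state)
  rates <- c(q01, q10)
  ev <- vector("list", nrow(tr$edge))
  for (k in seq_len(nrow(tr$edge))) {
    cur <- ns[tr$edge[k, 1]]
    t_br <- tr$edge.length[k]
    now <- 0
    times <- numeric(0); tos <- integer(0)
    repeat {
      r <- rates[cur + 1L]
      if (r == 0) break
      now <- now + stats::rexp(1, r)
      if (now >= t_br) break
      cur <- 1L - cur
      times <- c(times, now); tos <- c(tos, cur)
    }
    ns[tr$edge[k, 2]] <- cur
    if (length(times)) {
      ev[[k]] <- data.frame(edge = k, time = times,
                            from = c(ns[tr$edge[k, 1]], tos[-length(tos)]),
                            to = tos)
    }
  }
  history <- dplyr::bind_rows(ev)
  if (!nrow(history)) {
    history <- tibble::tibble(edge = integer(), time = numeric(),
                              from = integer(), to = integer())
  } else history <- tibble::as_tibble(history)
  tips <- ns[seq_len(n_tip)]
  names(tips) <- tr$tip.label
  list(tip_states = tips, node_states = ns, history = history,
       n_loss = sum(history$from == 1L & history$to == 0L),
       n_gain = sum(history$from == 0L & history$to == 1L),
       edge_table = tr$edge)
}

#' Simulate a continuous trait on the tree
#'
#' Draws tip values from the multivariate normal with mean `z0` and
#' covariance `sigma2 * T(C)` matching [transform_covariance()].
#'
#' @inheritParams cont_loglik
#' @param seed Optional RNG seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_continuous <- function(tree, model = c("BM", "OU", "EB", "lambda"),
                                sigma2 = 1, z0 = 0, param = NULL, seed = NULL) {
  model <- match.arg(model)
  stopifnot(sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_vcv(tree)
  V <- sigma2 * cont_build_V(C, model, param, tree_height(tree),
                             ultrametric = is_ultrametric_tree(tree))
  x <- z0 + rmvn_chol(V)
  names(x) <- tree$tip.label
  x
}

rmvn_chol <- function(V) {
  if (all(V == 0)) return(numeric(nrow(V)))
  R <- chol(V + diag(1e-12 * max(diag(V)), nrow(V)))
  as.vector(t(R) %*% stats::rnorm(nrow(V)))
}

#' Simulate a species table for phylogenetic regression
#'
#' `y = beta0 + beta * group + eps`, `eps ~ MVN(0, sigma2 * T(C))`. The
#' binary group labels are drawn Bernoulli(`p_group`) per tip unless given.
#'
#' @inheritParams simulate_continuous
#' @param groups Optional named 0/1 vector over tips; drawn at random when
#'   `NULL`.
#' @param beta0,beta Intercept and group effect (trait units).
#' @param p_group Probability of group 1 when labels are drawn.
#' @return A tibble: `species`, `group`, `y`.
#' @export
simulate_regression_dataset <- function(tree, groups = NULL, beta0 = 0, beta = 0,
                                        model = "BM", sigma2 = 1, param = NULL,
                                        p_group = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  if (is.null(groups)) {
    groups <- stats::rbinom(n, 1, p_group)
    names(groups) <- tree$tip.label
  }
  groups <- groups[tree$tip.label]
  eps <- simulate_continuous(tree, model, sigma2 = sigma2, z0 = 0, param = param)
  tibble::tibble(species = tree$tip.label,
                 group = as.integer(groups),
                 y = beta0 + beta * as.integer(groups) + as.numeric(eps))
}

#' Simulate a tracking trajectory with known speed profile
#'
#' Builds frame-by-frame pixel coordinates from a true instantaneous speed
#' profile: displacement along x integrates the profile; a sinusoidal
#' oscillation (the gait-induced wobble of the tracked body point) is added
#' to both coordinates; Gaussian pixel jitter emulates tracking error. The
#' true profile is returned alongside for validation.
#'
#' @param duration_s Trial duration (s).
#' @param fps Frame rate (default 250).
#' @param px_per_cm Scale (default 40).
#' @param body_length_cm Body length (default 1).
#' @param profile Function of time (s) returning true speed (cm/s), or
#'   `NULL` for a smooth raised-cosine bump peaking at `peak_speed`
#'   mid-trial (acceleration is continuous, as in a real sprint).
#' @param peak_speed Peak of the default speed profile (cm/s).
#' @param osc_amp_bl Oscillation amplitude in body lengths (default 0.15).
#' @param osc_freq_hz Oscillation frequency (default 8 Hz).
#' @param jitter_px SD of Gaussian pixel jitter (default 1).
#' @param seed Optional RNG seed.
#' @return A list: `frames` (tibble `frame`, `x_px`, `y_px`), `fps`,
#'   `px_per_cm`, `body_length_cm`, `true_speed` (tibble `t`, `v_cm_s`),
#'   `true_max` (cm/s).
#' @export
simulate_trajectory <- function(duration_s = 1, fps = 250, px_per_cm = 40,
                                body_length_cm = 1, profile = NULL,
                                peak_speed = 50, osc_amp_bl = 0.15,
                                osc_freq_hz = 8, jitter_px = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_frames <- floor(duration_s * fps) + 1
  if (n_frames < 10) stop("duration and fps must yield at least 10 frames", call. = FALSE)
  tt <- (seq_len(n_frames) - 1) / fps
  if (is.null(profile)) {
    profile <- function(t) peak_speed * sin(pi * t / duration_s)^2
  }
  v_true <- profile(tt)
  if (any(v_true < 0)) stop("speed profile must be non-negative", call. = FALSE)
  # cumulative displacement (cm) by trapezoidal integration of the profile
  x_cm <- c(0, cumsum((v_true[-1] + v_true[-n_frames]) / 2 / fps))
  amp_px <- osc_amp_bl * body_length_cm * px_per_cm
  osc_y <- amp_px * sin(2 * pi * osc_freq_hz * tt)
  osc_x <- 0.5 * amp_px * sin(2 * pi * osc_freq_hz * tt + pi / 2)
  x_px <- x_cm * px_per_cm + osc_x + stats::rnorm(n_frames, 0, jitter_px)
  y_px <- osc_y + stats::rnorm(n_frames, 0, jitter_px)
  list(frames = tibble::tibble(frame = seq_len(n_frames) - 1L,
                               x_px = x_px, y_px = y_px),
       fps = fps, px_per_cm = px_per_cm, body_length_cm = body_length_cm,
       true_speed = tibble::tibble(t = tt, v_cm_s = v_true),
       true_max = max(v_true))
}
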