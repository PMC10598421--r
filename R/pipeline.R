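#' Write a complete synthetic fixture directory
#'
#' Emits, under `dir`, the file set the pipeline reads: `tree.nwk`
#' (ultrametric birth-death tree), `ecology.csv` (species, web, cribellar,
#' ground), `morphology.csv` (long-format measurements), `tracks.csv` and
#' `track_meta.csv` (trajectories for every individual and trial). Traits
#' are generated with known structure: web use evolves under an ER Markov
#' process; log sprint speed under a lambda model with a group mean shift;
#' spination under an OU model.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed; fully determines the fixture.
#' @param n_species,n_individuals,n_trials Fixture sizes.
#' @return Invisibly, a list with the generating truth (tree, tip states,
#'   per-species true peak speeds).
#' @export
write_fixture_dir <- function(dir, seed = 1, n_species = 12,
                              n_individuals = 2, n_trials = 2) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  tree <- simulate_tree(n_species, birth = 1, death = 0.3)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  write_newick(tree, file.path(dir, "tree.nwk"))
  Tht <- tree_height(tree)
  web <- simulate_discrete(tree, q01 = 0.5 / Tht, q10 = 0.5 / Tht, root_state = 1)
  eco <- tibble::tibble(species = tree$tip.label,
                        web = as.integer(web$tip_states[tree$tip.label]),
                        cribellar = stats::rbinom(n_species, 1, 0.4),
                        ground = stats::rbinom(n_species, 1, 0.5))
  utils::write.csv(eco, file.path(dir, "ecology.csv"), row.names = FALSE)
  # species-level true peak sprint speeds (cm/s), lognormal around 40
  peak <- exp(stats::rnorm(n_species, log(40), 0.3))
  names(peak) <- tree$tip.label
  # morphology: 2 specimens per species, front/hind segments + spines
  morpho <- purrr::map_dfr(tree$tip.label, function(sp) {
    purrr::map_dfr(1:2, function(i) {
      segs <- stats::runif(5, 1, 3)
      spines <- stats::runif(stats::rpois(1, 6) + 1, 0.05, 0.4)
      hind <- stats::runif(5, 1.5, 4)
      tibble::tibble(
        specimen = sprintf("%s_m%d", sp, i), species = sp,
        structure = c(rep("front_segment", 5), rep("front_spine", length(spines)),
                      rep("hind_segment", 5), "carapace_width", "body_length"),
        measurement_mm = c(segs, spines, hind, stats::runif(1, 1, 3),
                           stats::runif(1, 3, 10)))
    })
  })
  utils::write.csv(morpho, file.path(dir, "morphology.csv"), row.names = FALSE)
  tracks <- list(); meta <- list()
  for (sp in tree$tip.label) {
    bl <- stats::runif(1, 0.5, 1.5)
    for (ind in seq_len(n_individuals)) {
      for (tri in seq_len(n_trials)) {
        tj <- simulate_trajectory(duration_s = 0.8, fps = 250, px_per_cm = 40,
                                  body_length_cm = bl,
                                  peak_speed = peak[sp] * stats::runif(1, 0.85, 1))
        id <- tibble::tibble(species = sp,
                             individual = sprintf("%s_i%d", sp, ind),
                             trial = tri)
        tracks[[length(tracks) + 1L]] <- dplyr::bind_cols(
          id[rep(1, nrow(tj$frames)), ], tj$frames)
        meta[[length(meta) + 1L]] <- dplyr::bind_cols(
          id, tibble::tibble(fps = tj$fps, px_per_cm = tj$px_per_cm,
                             body_length_cm = tj$body_length_cm))
      }
    }
  }
  utils::write.csv(dplyr::bind_rows(tracks), file.path(dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(dplyr::bind_rows(meta), file.path(dir, "track_meta.csv"),
                   row.names = FALSE)
  invisible(list(tree = tree, web = web, peak_speed = peak))
}

#' Run the comparative pipeline on a fixture directory
#'
#' Sequences the full analysis: kinematics (per-trial summaries aggregated
#' to species sprint speed), morphometrics (spination index), discrete-trait
#' model comparison and stochastic mapping of web use (ER, ARD, Dollo),
#' continuous-trait model tables, phylogenetic regressions of sprint and
#' spination on each ecological predictor, and bootstrap effect sizes.
#' Species with trait data but no tip in the tree are dropped and reported;
#' tips without trait data are pruned from the tree.
#'
#' @param dir Directory holding the fixture files (see
#'   [write_fixture_dir()]).
#' @param n_maps Stochastic maps per Mk model.
#' @param B Bootstrap replicates for effect sizes.
#' @param seed RNG seed governing map sampling and bootstrap.
#' @param trees Optional named list of `phylo` objects to analyse instead of
#'   `tree.nwk` (the dual-topology loop); each gets its own result block.
#' @return A list: `trials`, `speeds`, `traits`, `dropped`, and per-topology
#'   `comparative` (Mk table + simmap counts, continuous model tables, PGLS
#'   contrasts, effect sizes).
#' @export
run_pipeline <- function(dir, n_maps = 100, B = 1000, seed = 1, trees = NULL) {
  read <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  if (is.null(trees)) {
    trees <- list(main = read_newick(file.path(dir, "tree.nwk")))
  }
  tracks <- read("tracks.csv")
  meta <- read("track_meta.csv")
  eco <- read("ecology.csv")
  morpho <- read("morphology.csv")
  trials <- summarize_trials(tracks, meta)
  speeds <- aggregate_speeds(trials)
  spin <- spination_index(morpho)
  tt <- species_trait_table(spin, speeds$species, eco, trees[[1]])
  traits <- tt$traits
  comparative <- purrr::imap(trees, function(tree, label) {
    complete <- traits$species[stats::complete.cases(
      traits[, c("web", "sprint_rel", "spination_index")])]
    keep <- intersect(tree$tip.label, complete)
    pruned_tips <- setdiff(tree$tip.label, keep)
    tr <- if (length(pruned_tips)) ape::drop.tip(tree, pruned_tips) else tree
    dat <- traits[match(tr$tip.label, traits$species), ]
    web <- stats::setNames(dat$web, dat$species)
    sprint <- stats::setNames(dat$sprint_rel, dat$species)
    spination <- stats::setNames(dat$spination_index, dat$species)
    fits <- list(fit_mk(tr, web, "ER"),
                 fit_mk(tr, web, "ARD", seed = seed),
                 fit_mk(tr, web, "DOLLO"))
    mk_tab <- aicc_weights(fits)
    er <- fits[[1]]; dollo <- fits[[3]]
    maps_er <- sample_maps(tr, web, er$q01, er$q10, n_maps = n_maps,
                           root_prior = er$root_prior, seed = seed)
    maps_dollo <- sample_maps(tr, web, dollo$q01, dollo$q10, n_maps = n_maps,
                              root_prior = dollo$root_prior, seed = seed + 1)
    cont <- list(sprint = model_table(tr, sprint),
                 spination = model_table(tr, spination))
    pgls_tab <- purrr::map_dfr(c("web", "cribellar", "ground"), function(pred) {
      if (length(unique(dat[[pred]])) < 2) return(NULL)
      purrr::map_dfr(c(sprint = "sprint_rel", spination = "spination_index"),
                     function(col) {
        f <- stats::as.formula(paste(col, "~", pred))
        method <- if (col == "sprint_rel") "lambda" else "OU"
        fit <- phylo_lm(f, dat, tr, method = method)
        rep <- group_contrast_report(fit, pred)
        dplyr::mutate(rep, trait = col, predictor = pred, topology = label,
                      .before = 1)
      })
    })
    eff <- purrr::map_dfr(c("web", "cribellar", "ground"), function(pred) {
      purrr::map_dfr(c("sprint_rel", "spination_index"), function(col) {
        if (length(unique(dat[[pred]])) < 2) return(NULL)
        es <- bootstrap_ci(dat, !!rlang::sym(col), !!rlang::sym(pred),
                           B = B, seed = seed)
        dplyr::mutate(tidy(es), trait = col, predictor = pred,
                      topology = label, .before = 1)
      })
    })
    list(tree = tr, pruned_tips = pruned_tips, mk_table = mk_tab,
         simmap = list(ER = maps_er, DOLLO = maps_dollo),
         continuous = cont, pgls = pgls_tab, effects = eff)
  })
  list(trials = trials, speeds = speeds, traits = traits,
       dropped = tt$dropped, comparative = comparative)
}
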