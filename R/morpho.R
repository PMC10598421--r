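#' Spination index
#'
#' Sum of the lengths of all spines (macrosetae) visible on the measured
#' front-leg segments, divided by the summed length of those segments
#' (segments measured between condyles, excluding coxa, trochanter and
#' pretarsus). Dimensionless; 0 when no spines are present; invariant to the
#' measurement unit.
#'
#' @param measurements Long-format data frame with columns `specimen`,
#'   `species`, `structure` (one of `"front_segment"`, `"front_spine"`,
#'   `"hind_segment"`, `"carapace_width"`, `"body_length"`) and
#'   `measurement_mm` (> 0).
#' @return A tibble with one row per specimen: `specimen`, `species`,
#'   `spination_index`.
#' @export
spination_index <- function(measurements) {
  m <- check_measurements(measurements)
  m |>
    dplyr::group_by(.data$specimen, .data$species) |>
    dplyr::summarise(
      seg = sum(.data$measurement_mm[.data$structure == "front_segment"]),
      spi = sum(.data$measurement_mm[.data$structure == "front_spine"]),
      .groups = "drop") |>
    (\(d) {
      if (any(d$seg == 0)) {
        stop("specimen(s) without front-leg segment measurements: ",
             paste(d$specimen[d$seg == 0], collapse = ", "), call. = FALSE)
      }
      d
    })() |>
    dplyr::transmute(.data$specimen, .data$species,
                     spination_index = .data$spi / .data$seg)
}

#' Relative leg length
#'
#' Sum of all measured segments of the hind (posterior) leg divided by
#' carapace width. Dimensionless.
#'
#' @inheritParams spination_index
#' @return A tibble: `specimen`, `species`, `relative_leg_length`.
#' @export
relative_leg_length <- function(measurements) {
  m <- check_measurements(measurements)
  m |>
    dplyr::group_by(.data$specimen, .data$species) |>
    dplyr::summarise(
      hind = sum(.data$measurement_mm[.data$structure == "hind_segment"]),
      cw = sum(.data$measurement_mm[.data$structure == "carapace_width"]),
      .groups = "drop") |>
    (\(d) {
      bad <- d$hind == 0 | d$cw == 0
      if (any(bad)) {
        stop("specimen(s) missing hind-leg segments or carapace width: ",
             paste(d$specimen[bad], collapse = ", "), call. = FALSE)
      }
      d
    })() |>
    dplyr::transmute(.data$specimen, .data$species,
                     relative_leg_length = .data$hind / .data$cw)
}

check_measurements <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  need <- c("specimen", "species", "structure", "measurement_mm")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    stop("measurement table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(m$measurement_mm <= 0)) stop("all measurements must be > 0", call. = FALSE)
  m
}

#' Assemble the species-level trait table
#'
#' Joins per-specimen morphology (averaged within species), per-species
#' sprint speed and the ecological codings into the single table consumed by
#' the comparative modules, and reports species that carry trait data but are
#' absent from the tree (those are dropped from comparative analysis).
#'
#' @param morpho Tibble from [spination_index()] (optionally joined with
#'   [relative_leg_length()]).
#' @param speeds Species-level tibble from [aggregate_speeds()]
#'   (`$species`).
#' @param ecology Data frame: `species`, `web` (0/1), `cribellar` (0/1),
#'   `ground` (0/1).
#' @param tree Optional `phylo`; species not among its tips are listed in
#'   the drop report and flagged.
#' @return A list: `traits` — one row per species with mean spination,
#'   sprint speed and ecological codings plus `in_tree`; `dropped` —
#'   character vector of species with trait data but no tip.
#' @export
species_trait_table <- function(morpho, speeds = NULL, ecology = NULL, tree = NULL) {
  tab <- morpho |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     n_specimens = dplyr::n(), .groups = "drop")
  if (!is.null(speeds)) {
    tab <- dplyr::full_join(tab, speeds, by = "species")
  }
  if (!is.null(ecology)) {
    tab <- dplyr::left_join(tab, tibble::as_tibble(ecology), by = "species")
  }
  dropped <- character(0)
  if (!is.null(tree)) {
    tab$in_tree <- tab$species %in% tree$tip.label
    dropped <- tab$species[!tab$in_tree]
  }
  list(traits = tab, dropped = dropped)
}
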