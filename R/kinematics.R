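#' Sprint-speed extraction from tracking trajectories
#'
#' High-speed video tracking yields a series of x-y pixel coordinates per
#' frame. The kinematics chain converts these to a per-frame velocity series
#' (pixels to centimetres via the recording's scale, frame gaps normalized by
#' the actual frame delta), smooths it with a cubic smoothing spline using
#' `floor(N/2) + 1` knots (N = number of frames) to remove the periodic
#' oscillation of the tracked body point during running, and reports the mean
#' speed and the sprint speed (maximum of the smoothed series), both absolute
#' (cm/s) and relative to body length (bl/s). Per-individual sprint speed is
#' the maximum over that individual's trials; the species value is the mean
#' over its individuals.
#'
#' @name kinematics
NULL

#' Per-interval velocities from frame coordinates
#'
#' @param frames Data frame with columns `frame`, `x_px`, `y_px`; frame
#'   indices strictly increasing (gaps allowed; velocity over a gap is
#'   normalized by the frame delta).
#' @param fps Recording frame rate (frames per second).
#' @param px_per_cm Pixels per centimetre from the reference scale.
#' @return A tibble with one row per frame interval: `t_mid` (s, interval
#'   midpoint), `v_cm_s`.
#' @export
frame_velocities <- function(frames, fps, px_per_cm) {
  stopifnot(fps > 0, px_per_cm > 0)
  frames <- dplyr::arrange(as.data.frame(frames), .data$frame)
  if (anyDuplicated(frames$frame)) stop("duplicate frame indices", call. = FALSE)
  if (nrow(frames) < 2) stop("need at least 2 frames", call. = FALSE)
  f <- frames$frame
  if (!(fps >= 100 && fps <= 750)) {
    warning("frame rate ", fps, " fps is outside the typical 100-750 range")
  }
  dx <- diff(frames$x_px); dy <- diff(frames$y_px); df_ <- diff(f)
  dist_cm <- sqrt(dx^2 + dy^2) / px_per_cm
  dt <- df_ / fps
  tibble::tibble(t_mid = (f[-length(f)] + f[-1]) / 2 / fps,
                 v_cm_s = dist_cm / dt)
}

#' Spline-smooth a velocity series
#'
#' Cubic smoothing spline ([stats::smooth.spline()]) fitted to the velocity
#' series with the knot count fixed at `floor(n_frames/2) + 1` (knots placed
#' at quantiles of the time points) and the penalty chosen by generalized
#' cross-validation. Fitted values are evaluated at the original interval
#' midpoints; negative fits are clipped to zero since speed is a magnitude.
#'
#' @param vel Tibble from [frame_velocities()] (`t_mid`, `v_cm_s`).
#' @param n_frames Number of frames N in the trajectory (knot rule input).
#' @return The input tibble with a `v_smooth` column added.
#' @export
smooth_speed <- function(vel, n_frames) {
  n_pts <- nrow(vel)
  if (n_pts < 4) stop("too few velocity points to smooth; drop this trial", call. = FALSE)
  K <- floor(n_frames / 2) + 1
  K <- min(K, n_pts) # smooth.spline requires nknots <= number of points
  sm <- stats::smooth.spline(vel$t_mid, vel$v_cm_s, nknots = K, cv = FALSE)
  fit <- stats::predict(sm, vel$t_mid)$y
  dplyr::mutate(vel, v_smooth = pmax(fit, 0))
}

#' Path straightness index and trial filter
#'
#' Net displacement divided by total path length, in `[0, 1]`; trials below
#' the threshold (runs with turns, loops or reversals) are flagged for
#' exclusion, since only runs in a roughly constant direction give a clean
#' sprint estimate.
#'
#' @inheritParams frame_velocities
#' @param threshold Minimum straightness to keep a trial (default 0.9).
#' @param n_segments The path length is measured over this many evenly
#'   spaced waypoints (default 25) rather than frame by frame, so that
#'   frame-level tracking jitter and gait oscillation, which inflate the
#'   raw step-sum without changing the direction of travel, do not sink the
#'   index. Loops and reversals still show up at this resolution. Set to
#'   `Inf` for the raw per-frame path length.
#' @return A one-row tibble: `straightness`, `keep`.
#' @export
straightness_filter <- function(frames, threshold = 0.9, n_segments = 25) {
  frames <- dplyr::arrange(as.data.frame(frames), .data$frame)
  n <- nrow(frames)
  idx <- if (is.finite(n_segments) && n > n_segments + 1) {
    unique(round(seq(1, n, length.out = n_segments + 1)))
  } else seq_len(n)
  dx <- diff(frames$x_px[idx]); dy <- diff(frames$y_px[idx])
  total <- sum(sqrt(dx^2 + dy^2))
  net <- sqrt((frames$x_px[n] - frames$x_px[1])^2 +
              (frames$y_px[n] - frames$y_px[1])^2)
  s <- if (total == 0) 0 else min(net / total, 1)
  tibble::tibble(straightness = s, keep = s >= threshold)
}

#' Summarize one trial
#'
#' @param smoothed Tibble from [smooth_speed()].
#' @param body_length_cm Body length of the individual (cm).
#' @param use_smoothed_mean Compute the mean speed on the smoothed series
#'   (default) or on the raw velocities.
#' @return One-row tibble: `mean_abs`, `sprint_abs` (cm/s), `mean_rel`,
#'   `sprint_rel` (bl/s).
#' @export
trial_summary <- function(smoothed, body_length_cm, use_smoothed_mean = TRUE) {
  stopifnot(body_length_cm > 0, "v_smooth" %in% names(smoothed))
  sprint_abs <- max(smoothed$v_smooth)
  mean_abs <- if (use_smoothed_mean) mean(smoothed$v_smooth) else mean(smoothed$v_cm_s)
  tibble::tibble(mean_abs = mean_abs, sprint_abs = sprint_abs,
                 mean_rel = mean_abs / body_length_cm,
                 sprint_rel = sprint_abs / body_length_cm)
}

#' Process a set of trials end to end
#'
#' Runs the straightness filter, velocity computation, smoothing and trial
#' summary for every trial in a long tracking table.
#'
#' @param tracks Data frame with columns `species`, `individual`, `trial`,
#'   `frame`, `x_px`, `y_px`.
#' @param meta Data frame keyed by (`species`, `individual`, `trial`) with
#'   `fps`, `px_per_cm`, `body_length_cm`.
#' @param straightness_threshold Passed to [straightness_filter()].
#' @param min_frames Trials with fewer frames are dropped (default 10).
#' @return A tibble with one row per trial: ids, `n_frames`, `straightness`,
#'   `keep`, and (for kept trials) the [trial_summary()] columns.
#' @export
summarize_trials <- function(tracks, meta, straightness_threshold = 0.9,
                             min_frames = 10) {
  keys <- c("species", "individual", "trial")
  tracks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      m <- dplyr::inner_join(key, meta, by = keys)
      if (nrow(m) != 1) stop("no unique metadata row for trial ",
                             paste(unlist(key), collapse = "/"), call. = FALSE)
      n_frames <- nrow(df)
      sf <- straightness_filter(df, straightness_threshold)
      base <- dplyr::bind_cols(tibble::tibble(n_frames = n_frames), sf)
      if (n_frames < min_frames) {
        base$keep <- FALSE
        return(base)
      }
      if (!sf$keep) return(base)
      vel <- frame_velocities(df, m$fps, m$px_per_cm) |>
        smooth_speed(n_frames)
      dplyr::bind_cols(base, trial_summary(vel, m$body_length_cm))
    }) |>
    dplyr::ungroup()
}

#' Aggregate trial summaries to individuals and species
#'
#' Individual sprint = maximum over the individual's kept trials; species
#' sprint = mean over its individuals. Mean speed aggregates the same way
#' except the individual value is also the maximum-trial's companion
#' statistic convention is not needed: mean speeds average within individual.
#'
#' @param trials Output of [summarize_trials()] (dropped trials, lacking
#'   summary columns, are ignored).
#' @return A list of two tibbles: `individuals` (`species`, `individual`,
#'   `n_trials`, `sprint_rel`, `sprint_abs`, `mean_rel`), `species`
#'   (`species`, `n_individuals`, `sprint_rel`, `sprint_abs`, `mean_rel`).
#' @export
aggregate_speeds <- function(trials) {
  kept <- dplyr::filter(trials, .data$keep, !is.na(.data$sprint_rel))
  if (!nrow(kept)) stop("no kept trials to aggregate", call. = FALSE)
  ind <- kept |>
    dplyr::group_by(.data$species, .data$individual) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     sprint_rel = max(.data$sprint_rel),
                     sprint_abs = max(.data$sprint_abs),
                     mean_rel = mean(.data$mean_rel),
                     .groups = "drop")
  sp <- ind |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_individuals = dplyr::n(),
                     sprint_rel = mean(.data$sprint_rel),
                     sprint_abs = mean(.data$sprint_abs),
                     mean_rel = mean(.data$mean_rel),
                     .groups = "drop")
  list(individuals = ind, species = sp)
}

#' Plot raw and smoothed speed for one trial
#'
#' @param smoothed Tibble from [smooth_speed()].
#' @return A ggplot object.
#' @export
plot_speed_series <- function(smoothed) {
  ggplot2::ggplot(smoothed, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$v_cm_s), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$v_smooth), colour = "black",
                       linewidth = 0.8) +
    ggplot2::labs(x = "time (s)", y = "speed (cm/s)",
                  subtitle = "grey: per-frame velocity; black: smoothed") +
    ggplot2::theme_minimal()
}
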