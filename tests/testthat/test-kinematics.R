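make_frames <- function(x, y, frame = seq_along(x) - 1L) {
  tibble::tibble(frame = frame, x_px = x, y_px = y)
}

test_that("frame velocities follow the px -> cm -> speed arithmetic", {
  fr <- make_frames(x = seq(0, 190, by = 10), y = rep(0, 20))
  v <- frame_velocities(fr, fps = 100, px_per_cm = 20)
  expect_equal(nrow(v), 19)
  expect_equal(v$v_cm_s, rep(10 / 20 * 100, 19)) # 50 cm/s

  still <- make_frames(x = rep(3, 15), y = rep(4, 15))
  expect_true(all(frame_velocities(still, 100, 20)$v_cm_s == 0))

  # a 2-frame gap with doubled displacement gives the same velocity
  gap <- tibble::tibble(frame = c(0, 1, 3), x_px = c(0, 10, 30), y_px = 0)
  vg <- frame_velocities(gap, fps = 100, px_per_cm = 20)
  expect_equal(vg$v_cm_s, c(50, 50))

  dup <- tibble::tibble(frame = c(0, 1, 1), x_px = 1:3, y_px = 0)
  expect_error(frame_velocities(dup, 100, 20), "duplicate")
  expect_warning(frame_velocities(fr, fps = 50, px_per_cm = 20), "frame rate")
})

test_that("smoothing reproduces constants and ramps, clips negatives", {
  fr <- make_frames(x = seq(0, 10 * 49, by = 10), y = rep(0, 50))
  v <- frame_velocities(fr, 100, 20)
  sm <- smooth_speed(v, n_frames = 50)
  expect_equal(sm$v_smooth, v$v_cm_s, tolerance = 1e-8)

  ramp <- v
  ramp$v_cm_s <- seq(10, 60, length.out = nrow(v))
  smr <- smooth_speed(ramp, n_frames = 50)
  expect_equal(smr$v_smooth, ramp$v_cm_s, tolerance = 1e-6)

  expect_error(smooth_speed(v[1:3, ], n_frames = 4), "drop this trial")
})

test_that("smoothing removes body-centre oscillation rather than tracking it", {
  # oscillation + tracking jitter, as in real footage: the GCV spline should
  # suppress the wobble, pulling the max toward the true 40 cm/s plateau
  n <- 201
  t <- (0:(n - 2) + 0.5) / 250
  set.seed(8)
  vel <- tibble::tibble(t_mid = t,
                        v_cm_s = 40 + 10 * sin(2 * pi * 8 * t) + rnorm(n - 1, 0, 5))
  sm <- smooth_speed(vel, n_frames = n)
  expect_lte(max(sm$v_smooth), 50)
  expect_lt(abs(max(sm$v_smooth) - 40), max(vel$v_cm_s) - 40)
})

test_that("trial summaries and aggregation follow max/mean rules", {
  sm <- tibble::tibble(t_mid = 1:5, v_cm_s = rep(50, 5), v_smooth = rep(50, 5))
  ts <- trial_summary(sm, body_length_cm = 2.5)
  expect_equal(ts$sprint_rel, 20)
  expect_equal(ts$mean_rel, 20)

  sm2 <- sm; sm2$v_smooth <- c(30, 40, 55, 45, 30)
  ts2 <- trial_summary(sm2, 2.5)
  expect_gte(ts2$sprint_rel, ts2$mean_rel)

  trials <- tibble::tibble(
    species = "sp1", individual = c("a", "a", "a", "b"),
    trial = c(1, 2, 3, 1), keep = TRUE,
    sprint_rel = c(30, 45, 40, 35), sprint_abs = c(60, 90, 80, 70),
    mean_rel = c(20, 30, 25, 22))
  ag <- aggregate_speeds(trials)
  expect_equal(ag$individuals$sprint_rel, c(45, 35))
  expect_equal(ag$species$sprint_rel, 40)

  one <- aggregate_speeds(trials[4, ])
  expect_equal(one$species$sprint_rel, 35)
})

test_that("straightness index separates straight runs from loops and U-turns", {
  straight <- make_frames(x = 1:50, y = rep(0, 50))
  s <- straightness_filter(straight)
  expect_equal(s$straightness, 1)
  expect_true(s$keep)

  th <- seq(0, 2 * pi, length.out = 60)
  loop <- make_frames(x = 100 * cos(th), y = 100 * sin(th))
  sl <- straightness_filter(loop)
  expect_lt(sl$straightness, 0.05)
  expect_false(sl$keep)

  uturn <- make_frames(x = c(1:25, 24:1), y = rep(0, 49))
  expect_equal(straightness_filter(uturn)$straightness, 0)
})

test_that("sprint extraction is invariant to rigid motion and consistent rescaling", {
  tj <- simulate_trajectory(seed = 3)
  v1 <- smooth_speed(frame_velocities(tj$frames, tj$fps, tj$px_per_cm),
                     nrow(tj$frames))
  th <- 0.7
  rot <- tj$frames
  rot$x_px <- cos(th) * tj$frames$x_px - sin(th) * tj$frames$y_px + 500
  rot$y_px <- sin(th) * tj$frames$x_px + cos(th) * tj$frames$y_px - 200
  v2 <- smooth_speed(frame_velocities(rot, tj$fps, tj$px_per_cm), nrow(rot))
  expect_equal(v2$v_smooth, v1$v_smooth, tolerance = 1e-8)

  sc <- tj$frames
  sc$x_px <- sc$x_px * 3; sc$y_px <- sc$y_px * 3
  v3 <- smooth_speed(frame_velocities(sc, tj$fps, tj$px_per_cm * 3), nrow(sc))
  expect_equal(v3$v_smooth, v1$v_smooth, tolerance = 1e-8)
})

test_that("noise-free constant-speed sprint is exact; noisy sprint is close", {
  tj <- simulate_trajectory(profile = function(t) rep(40, length(t)),
                            osc_amp_bl = 0, jitter_px = 0, seed = 1)
  sm <- smooth_speed(frame_velocities(tj$frames, tj$fps, tj$px_per_cm),
                     nrow(tj$frames))
  expect_equal(max(sm$v_smooth), 40, tolerance = 1e-9)

  tj2 <- simulate_trajectory(seed = 2) # default oscillation + jitter
  sm2 <- smooth_speed(frame_velocities(tj2$frames, tj2$fps, tj2$px_per_cm),
                      nrow(tj2$frames))
  expect_lt(abs(max(sm2$v_smooth) - tj2$true_max) / tj2$true_max, 0.05)
})

test_that("summarize_trials drops short and crooked trials with a report", {
  tj <- simulate_trajectory(seed = 4)
  tracks <- dplyr::bind_cols(
    tibble::tibble(species = "sp1", individual = "i1", trial = 1)[
      rep(1, nrow(tj$frames)), ], tj$frames)
  th <- seq(0, 2 * pi, length.out = 80)
  loop <- tibble::tibble(species = "sp1", individual = "i1", trial = 2,
                         frame = 0:79, x_px = 50 * cos(th), y_px = 50 * sin(th))
  short <- tibble::tibble(species = "sp1", individual = "i1", trial = 3,
                          frame = 0:5, x_px = 1:6, y_px = 0)
  meta <- tibble::tibble(species = "sp1", individual = "i1", trial = 1:3,
                         fps = 250, px_per_cm = 40, body_length_cm = 1)
  out <- summarize_trials(dplyr::bind_rows(tracks, loop, short), meta)
  expect_equal(nrow(out), 3)
  expect_equal(out$keep, c(TRUE, FALSE, FALSE))
  expect_false(is.na(out$sprint_rel[1]))
})
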