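test_that("step metrics give distances and speeds in both unit systems", {
  ts <- make_track(rbind(c(0, 0), c(0, 3)), dt = 3)
  st <- step_metrics(ts$points, 3)
  expect_equal(st$d_um, 3)
  expect_equal(st$speed_um_min, 1)
  expect_equal(st$speed_um_h, 60)

  still <- make_track(matrix(0, 5, 2), dt = 10)
  expect_true(all(step_metrics(still$points, 10)$d_um == 0))

  single <- make_track(matrix(0, 1, 2), dt = 10)
  out <- step_metrics(single$points, 10)
  expect_equal(nrow(out), 0L)
  expect_identical(attr(out, "flag"), "single_point")
})

test_that("empirical mean step speed matches the lognormal moment", {
  p <- muscle_preset("wt", f_mobile = 1, landmark_noise_sd_um = 0)
  sc <- simulate_tracks(p, 40, seed = 21, duration_h = 24,
                        fibre_motion = FALSE)
  st <- step_metrics(sc$tracks_true$points[
    sc$tracks_true$points$cell_id == "cell_0001", ], p$dt_min)
  analytic <- p$mobile_speed_mean_um_h / 60
  sd_ln <- analytic * sqrt(exp(p$mobile_speed_sigma_log^2) - 1)
  se <- sd_ln / sqrt(nrow(st))
  expect_lt(abs(mean(st$speed_um_min) - analytic), 3 * se)
  # and pooled across all mobile cells
  pooled <- unlist(lapply(split(sc$tracks_true$points,
                                sc$tracks_true$points$cell_id),
                          function(s) step_metrics(s, p$dt_min)$speed_um_min))
  expect_lt(abs(mean(pooled) - analytic), 3 * sd_ln / sqrt(length(pooled)))
})

test_that("path summary: straightness of canonical shapes", {
  straight <- make_track(cbind(0:2, 0))
  expect_equal(path_summary(straight$points, 10)$straightness, 1)

  lshape <- make_track(rbind(c(0, 0), c(1, 0), c(1, 1)))
  ps <- path_summary(lshape$points, 10)
  expect_equal(ps$total_um, 2)
  expect_equal(ps$net_um, sqrt(2))
  expect_equal(ps$straightness, sqrt(2) / 2, tolerance = 1e-12)

  loop <- make_track(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
  expect_equal(path_summary(loop$points, 10)$net_um, 0)
  expect_equal(path_summary(loop$points, 10)$straightness, 0)

  bad <- tibble::tibble(frame = c(0, 1), t_min = c(0, 0), x_um = c(0, 1),
                        y_um = 0, z_um = 0)
  expect_error(path_summary(bad, 10), "zero-duration")
})

test_that("turning angles span [0, 180] with zero steps skipped", {
  straight <- make_track(cbind(0:3, 0))
  expect_equal(turning_angles(straight$points), c(0, 0))

  corner <- make_track(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(turning_angles(corner$points), 90)

  reverse <- make_track(rbind(c(0, 0), c(1, 0), c(0, 0)))
  expect_equal(turning_angles(reverse$points), 180)

  paused <- make_track(rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0)))
  expect_equal(turning_angles(paused$points), 0)   # zero step skipped

  still <- make_track(matrix(0, 4, 2))
  out <- turning_angles(still$points)
  expect_length(out, 0L)
  expect_identical(attr(out, "flag"), "no_motion")
})

test_that("derived threshold is the median of pooled step speeds", {
  expect_equal(derive_threshold(rep(0.5, 10))$value, 0.5)
  expect_equal(derive_threshold(c(0.1, 0.2, 0.4, 0.8, 1.6))$value, 0.4)
  expect_error(derive_threshold(numeric(0)), "no strictly positive")
  expect_identical(derive_threshold(1)$provenance, "derived")
  expect_identical(default_threshold()$provenance, "default_paper")
})

test_that("threshold derived from a two-population reference lands in the
           inter-mode gap", {
  sc <- simulate_tracks(muscle_preset("wt"), 300, seed = 31, duration_h = 12,
                        fibre_motion = FALSE)
  thr <- derive_threshold(sc$tracks_true)
  expect_gt(thr$value, 0.3)
  expect_lt(thr$value, 0.5)
})

test_that("mobility classification is correct and threshold-monotone", {
  expect_identical(classify_mobility(1.0, 0.41), "mobile")
  expect_identical(classify_mobility(0.1, 0.41), "static")
  expect_identical(classify_mobility(1.0, 0.41, excluded = TRUE), "excluded")

  sc <- simulate_tracks(muscle_preset("wt"), 150, seed = 32, duration_h = 12,
                        fibre_motion = FALSE)
  ms <- motility_summary(sc$tracks_true, threshold = 1)  # recompute below
  fractions <- vapply(c(0.1, 0.3, 0.41, 0.6, 1, 2), function(thr)
    mean(classify_mobility(ms$avg_speed_um_min, thr) == "mobile"),
    numeric(1))
  expect_true(all(diff(fractions) <= 0))
})

test_that("the pipeline recovers the preset mobile fraction", {
  p <- muscle_preset("wt")
  sc <- simulate_tracks(p, 200, seed = 33, duration_h = 12)
  reg <- register_landmarks(sc$landmarks)
  corr <- correct_tracks(sc$tracks_observed, reg$correction)
  ms <- motility_summary(corr, threshold = default_threshold())
  expect_lt(abs(mean(ms$mobility_class == "mobile") - p$f_mobile), 0.05)
  # classes agree with the generator truth cell by cell
  truth <- sc$truth$mobility$class[match(ms$cell_id,
                                         sc$truth$mobility$cell_id)]
  expect_gt(mean(ms$mobility_class == truth), 0.98)
})

test_that("motility statistics are invariant under global rigid motion", {
  set.seed(44)
  xy <- apply(matrix(rnorm(40, 0, 3), ncol = 2), 2, cumsum)
  ts <- make_track(xy)
  tf <- planar_transform(73, c(12, -8), centre = c(3, 4))
  moved <- ts
  out <- rt_apply(tf, as.matrix(ts$points[, c("x_um", "y_um", "z_um")]))
  moved$points$x_um <- out[, 1]; moved$points$y_um <- out[, 2]
  a <- path_summary(ts$points, 10); b <- path_summary(moved$points, 10)
  for (col in c("total_um", "net_um", "straightness", "avg_speed_um_h",
                "mean_turn_deg"))
    expect_equal(a[[col]], b[[col]], tolerance = 1e-9)
})

test_that("net distance never exceeds total distance on generated scenes", {
  sc <- simulate_tracks(muscle_preset("mdx"), 60, seed = 55, duration_h = 8)
  ms <- motility_summary(sc$tracks_observed, threshold = 0.41)
  expect_true(all(ms$net_um <= ms$total_um + 1e-9))
  expect_true(all(ms$straightness >= 0 & ms$straightness <= 1, na.rm = TRUE))
  expect_true(all(ms$mean_turn_deg >= 0 & ms$mean_turn_deg <= 180,
                  na.rm = TRUE))
})

test_that("motility statistics of corrected tracks match ground truth", {
  sc <- simulate_tracks(muscle_preset("wt"), 40, seed = 66, duration_h = 8)
  reg <- register_landmarks(sc$landmarks)
  corr <- correct_tracks(sc$tracks_observed, reg$correction)
  a <- motility_summary(corr, threshold = 0.41)
  b <- motility_summary(sc$tracks_true, threshold = 0.41)
  expect_equal(a$total_um, b$total_um, tolerance = 0.01)
  expect_equal(a$avg_speed_um_h, b$avg_speed_um_h, tolerance = 0.01)
})

test_that("sister co-migration separates same- and opposite-moving pairs", {
  dt <- 10
  mk <- function(dirs) {
    # mother still at origin for 3 frames, divides; daughters move along dirs
    pts <- dplyr::bind_rows(
      tibble::tibble(cell_id = "m", frame = 0:2, t_min = (0:2) * dt,
                     x_um = 0, y_um = 0, z_um = 0),
      tibble::tibble(cell_id = "d1", frame = 2:8, t_min = (2:8) * dt,
                     x_um = dirs[1] * (0:6), y_um = 0, z_um = 0),
      tibble::tibble(cell_id = "d2", frame = 2:8, t_min = (2:8) * dt,
                     x_um = dirs[2] * (0:6), y_um = 0, z_um = 0))
    lin <- tibble::tibble(
      cell_id = c("m", "d1", "d2"), parent_id = c(NA, "m", "m"),
      birth_t = c(0, 20, 20), end_t = c(20, 80, 80),
      end_reason = c("division", "censored", "censored"), fate = "unknown")
    track_set(pts, lin, dt = dt)
  }
  opp <- sister_comigration(mk(c(1, -1)))
  expect_true(all(opp$fraction == 0))
  expect_true(all(opp$n_divisions == 1))
  same <- sister_comigration(mk(c(1, 2)))
  expect_true(all(same$fraction == 1))
  # a daughter censored before the offset drops the division
  short <- mk(c(1, -1))
  short$points <- short$points[!(short$points$cell_id == "d2" &
                                   short$points$frame > 4), ]
  short$lineage$end_t[short$lineage$cell_id == "d2"] <- 40
  res <- sister_comigration(short, offsets_min = c(20, 60))
  expect_equal(res$n_divisions, c(1L, 0L))
  expect_equal(res$n_dropped, c(0L, 1L))
})

test_that("generated sister pairs disperse in opposite directions", {
  sc <- simulate_lineages(wt_small(), 40, seed = 77)
  cm <- sister_comigration(sc$tracks_true)
  expect_true(all(cm$n_divisions > 50))
  expect_true(all(cm$fraction < 0.1))   # repulsive dispersal, WT-like
})
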