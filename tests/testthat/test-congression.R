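cfg <- analysis_config()

test_that("polar/aligned classification follows the two-rule union", {
  fr <- spindle_frame(c(0, 0), c(10, 0), 0)
  # closer to the pole than the centre, both sisters > 3 um from the plane
  expect_identical(
    classify_pair(pair_geometry(fr, c(1.1, 0), c(1.9, 0)), cfg), "polar")
  # one sister within 3 um of the plane
  expect_identical(
    classify_pair(pair_geometry(fr, c(3.6, 0), c(4.4, 0)), cfg), "aligned")
  # midpoint exactly on the plane
  expect_identical(
    classify_pair(pair_geometry(fr, c(5, 1), c(5, -1)), cfg), "aligned")
})

test_that("classification partitions pairs and is monotone in the threshold", {
  set.seed(21)
  wide <- analysis_config(aligned_dist_threshold = 4.5,
                          alignment_cross_threshold = 2)
  for (i in 1:300) {
    fr <- spindle_frame(stats::rnorm(2, 0, 3),
                        stats::rnorm(2, 8, 3), 0)
    s1 <- stats::rnorm(2, 3, 4)
    s2 <- s1 + stats::rnorm(2, 0, 1)
    g <- pair_geometry(fr, s1, s2)
    cls <- classify_pair(g, cfg)
    expect_true(cls %in% c("polar", "aligned"))
    # widening the aligned band can only move pairs polar -> aligned
    if (cls == "aligned") {
      expect_identical(classify_pair(g, wide), "aligned")
    }
  }
})

test_that("alignment event fires at the first 2-um crossing", {
  # midpoint x(t) = 0.5 + 0.5 t on a 10-um spindle: first |x - 5| <= 2
  # at t = 5 (x = 3.0)
  tt <- 0:10
  cell <- make_cell(list(0.5 + 0.5 * tt), pole_b = c(10, 0))
  g <- pair_frame_table(cell, "K01", cfg)
  ev <- detect_alignment(g, cfg)
  expect_equal(ev$t_alignment, 5)
  expect_false(ev$censored)

  # stationary far from the plane: censored
  cell <- make_cell(list(rep(0.8, 11)), pole_b = c(10, 0))
  ev <- detect_alignment(pair_frame_table(cell, "K01", cfg), cfg)
  expect_true(ev$censored)
  expect_identical(ev$censor_reason, "end_of_track")
  ev2 <- detect_alignment(pair_frame_table(cell, "K01", cfg), cfg,
                          t_anaphase_onset = 10)
  expect_identical(ev2$censor_reason, "anaphase")

  # already within the crossing threshold at the first frame
  cell <- make_cell(list(rep(3.5, 11)), pole_b = c(10, 0))
  ev <- detect_alignment(pair_frame_table(cell, "K01", cfg), cfg)
  expect_equal(ev$t_alignment, 0)
})

test_that("alignment detection agrees with a brute-force scan", {
  set.seed(22)
  for (i in 1:1000) {
    nt <- 15
    mx <- cumsum(c(stats::runif(1, -2, 6), stats::rnorm(nt - 1, 0.4, 0.8)))
    my <- cumsum(c(stats::runif(1, -2, 2), stats::rnorm(nt - 1, 0, 0.3)))
    cell <- make_cell(list(mx), list(my), pole_b = c(10, 0))
    g <- pair_frame_table(cell, "K01", cfg)
    ev <- detect_alignment(g, cfg)
    oracle <- brute_alignment_scan(rep(0, nt), rep(0, nt), rep(10, nt),
                                   rep(0, nt), mx, my, 0:(nt - 1), 2)
    if (is.na(oracle)) {
      expect_true(ev$censored)
    } else {
      expect_equal(ev$t_alignment, oracle)
    }
  }
})

test_that("congression velocity matches hand-computed window rates", {
  # straight-line approach at 1.05 um/min: dist_plane 8.3 at
  # t_align - 6 and 2.0 at t_align
  tt <- 0:6
  cell <- make_cell(list(-3.3 + 1.05 * tt), pole_b = c(10, 0))
  g <- pair_frame_table(cell, "K01", cfg)
  ev <- detect_alignment(g, cfg)
  expect_equal(ev$t_alignment, 6)
  vel <- congression_velocity(g, ev$t_alignment, cfg)
  expect_equal(vel$velocity, (8.3 - 2.0) / 6, tolerance = 1e-9)
  expect_false(vel$partial_window)

  # constant 1.0 um/min
  tt <- 0:8
  cell <- make_cell(list(-4.5 + 1.0 * tt), pole_b = c(10, 0))
  g <- pair_frame_table(cell, "K01", cfg)
  ev <- detect_alignment(g, cfg)
  vel <- congression_velocity(g, ev$t_alignment, cfg)
  expect_equal(vel$velocity, 1.0, tolerance = 1e-9)

  # only 2 minutes of pre-crossing coverage: undefined, flagged
  tt <- 0:2
  cell <- make_cell(list(1.2 + 0.9 * tt), pole_b = c(10, 0))
  g <- pair_frame_table(cell, "K01", cfg)
  ev <- detect_alignment(g, cfg)
  expect_equal(ev$t_alignment, 2)
  vel <- congression_velocity(g, ev$t_alignment, cfg)
  expect_true(is.na(vel$velocity))
  expect_true(vel$partial_window)
})

test_that("velocity recovers ground truth on constant-velocity tracks", {
  # noise-free: exact; 0.05-um positional noise: MAE < 0.05 um/min
  set.seed(23)
  err_free <- err_noisy <- numeric(200)
  for (i in 1:200) {
    v <- stats::runif(1, 0.5, 1.2)
    tt <- 0:10
    mx <- (4 - 7.3 * v) + v * tt
    cell <- make_cell(list(mx), pole_b = c(12, 0))
    g <- pair_frame_table(cell, "K01", cfg)
    ev <- detect_alignment(g, cfg)
    vel <- congression_velocity(g, ev$t_alignment, cfg)
    err_free[i] <- abs(vel$velocity - v)

    noisy <- cell
    noisy$pair_tracks$x1_um <- noisy$pair_tracks$x1_um +
      stats::rnorm(11, 0, 0.05)
    noisy$pair_tracks$y1_um <- noisy$pair_tracks$y1_um +
      stats::rnorm(11, 0, 0.05)
    noisy$pair_tracks$x2_um <- noisy$pair_tracks$x2_um +
      stats::rnorm(11, 0, 0.05)
    noisy$pair_tracks$y2_um <- noisy$pair_tracks$y2_um +
      stats::rnorm(11, 0, 0.05)
    g <- pair_frame_table(noisy, "K01", cfg)
    ev <- detect_alignment(g, cfg)
    vel <- congression_velocity(g, ev$t_alignment, cfg)
    err_noisy[i] <- abs(vel$velocity - v)
  }
  expect_lt(max(err_free), 1e-9)
  expect_lt(mean(err_noisy, na.rm = TRUE), 0.05)
})

test_that("residence time handles alignment, censoring and boundaries", {
  r <- residence_time(10, t_alignment = 40)
  expect_equal(r$time, 30)
  expect_false(r$censored)

  r <- residence_time(10, t_anaphase_onset = 120)
  expect_equal(r$time, 110)
  expect_true(r$censored)

  r <- residence_time(10, t_alignment = 10)
  expect_equal(r$time, 0)

  expect_warning(r <- residence_time(10, t_alignment = 8), "clamped")
  expect_equal(r$time, 0)

  r <- residence_time(10, t_end = 50)
  expect_true(r$censored)
  expect_equal(r$time, 40)
})

test_that("polar counts tally classified pairs totally and per pole", {
  # 3 pairs parked 1 um from a pole on a 12-um spindle (2 at P1, 1 at
  # P2), 2 pairs at the plate
  mk <- function(x) list(rep(x, 11))
  cell <- make_cell(c(mk(1), mk(1), mk(11), mk(6), mk(6.2)))
  pc <- polar_count(cell, 5, cfg)
  expect_equal(pc$n_polar, 3L)
  expect_equal(pc$per_pole$n_polar[pc$per_pole$pole_id == "P1"], 2L)
  expect_equal(pc$per_pole$n_polar[pc$per_pole$pole_id == "P2"], 1L)
  # classify_pair agrees pairwise
  g <- pair_frame_table(cell, "K01", cfg)
  expect_identical(classify_pair(g[6, ], cfg), "polar")

  # all pairs aligned
  cell <- make_cell(c(mk(6), mk(5.5), mk(6.5)))
  expect_equal(polar_count(cell, 5, cfg)$n_polar, 0L)

  # time outside the imaged span
  expect_error(polar_count(cell, 99, cfg), "outside")
})

test_that("mitosis duration stops one frame before anaphase", {
  mk <- list(rep(6, 61))
  cell <- make_cell(mk, t_ana = 60)
  md <- mitosis_duration(cell)
  expect_equal(md$duration, 59)
  expect_false(md$censored)

  # 0.5-min frames
  cell <- make_cell(list(rep(6, 61)), dt = 0.5, t_ana = 30)
  expect_equal(mitosis_duration(cell)$duration, 29.5)

  # no anaphase: censored at the last frame
  cell <- make_cell(list(rep(6, 121)))
  md <- mitosis_duration(cell)
  expect_true(md$censored)
  expect_equal(md$duration, 120)
})

test_that("initiation-vs-distance recovers an exact linear relation", {
  # three polar pairs on a 20-um spindle with (distance, duration) =
  # (1, 9), (2, 8), (3, 7): slope -1, R^2 = 1
  tt <- 0:10
  traj <- function(x0, t_al) ifelse(tt < t_al, x0, 10)
  cell <- make_cell(list(traj(1, 9), traj(2, 8), traj(3, 7)),
                    pole_b = c(20, 0))
  iv <- initiation_vs_distance(list(cell), cfg)
  expect_equal(nrow(iv$table), 3)
  expect_equal(iv$fit$slope, -1, tolerance = 1e-6)
  expect_equal(iv$fit$r_squared, 1, tolerance = 1e-9)

  # single uncensored pair: no slope can be fit
  cell1 <- make_cell(list(traj(1, 9), rep(1.5, 11)), pole_b = c(20, 0))
  expect_error(initiation_vs_distance(list(cell1), cfg), "unavailable")

  # all censored: table returned, no fit
  cell2 <- make_cell(list(rep(1, 11), rep(1.5, 11)), pole_b = c(20, 0))
  iv <- initiation_vs_distance(list(cell2), cfg)
  expect_null(iv$fit)
  expect_equal(nrow(iv$table), 2)
  expect_true(all(iv$table$censored))
})

test_that("distance-increasing hazard yields negative duration slopes", {
  # acentriolar spindles have a hazard rising with distance from the
  # pole, so congression duration falls with initial distance
  slopes <- vapply(1:100, function(r) {
    cells <- lapply(1:10, function(i) {
      simulate_cell(spindle_preset("cenpe_inhibited_0v0"),
                    r * 1000 + i)$cell
    })
    initiation_vs_distance(cells, cfg)$fit$slope
  }, numeric(1))
  expect_gte(mean(slopes < 0), 0.95)
})

test_that("short track gaps are interpolated, long gaps split the track", {
  mx <- c(1, 1.5, NA, NA, 3, 3.5, 4)
  cell <- make_cell(list(mx), pole_b = c(10, 0))
  g <- pair_frame_table(cell, "K01", cfg)
  # 2-frame gap (<= max_gap): linear interpolation at frames 2 and 3
  expect_equal(g$mx[3], 2.0, tolerance = 1e-9)
  expect_equal(g$mx[4], 2.5, tolerance = 1e-9)

  mx <- c(1, 1.5, NA, NA, NA, 3.5, 4)
  cell <- make_cell(list(mx), pole_b = c(10, 0))
  g <- pair_frame_table(cell, "K01", cfg)
  expect_true(all(is.na(g$mx[3:5])))
})

test_that("per-pair residence never exceeds mitosis duration by more than a frame", {
  co <- simulate_experiment(spindle_preset("control_2v2"), 5, 31,
                            with_intensities = FALSE)
  for (cell in co$cells) {
    res <- analyze_cell(cell, cfg)
    md <- mitosis_duration(cell)
    dt <- 1
    expect_true(all(res$residence_time <= md$duration + dt + 1e-9))
  }
})

test_that("cell records validate pole counts and event ordering", {
  mk <- list(rep(6, 5))
  expect_error(make_cell(mk, t_bip = 10, t_ana = 5), "event times")
  cell <- make_cell(mk)
  bad_poles <- cell$pole_tracks[cell$pole_tracks$pole_id == "P1", ]
  expect_error(
    cell_record("x", "c", bad_poles, cell$pair_tracks, 0, 0, NA),
    "exactly 2 pole tracks")
})
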