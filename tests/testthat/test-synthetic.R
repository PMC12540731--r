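cfg <- analysis_config()

test_that("the activity gradient matches its closed form and support", {
  expect_equal(aurora_activity(0, 1, 1.5), 1)
  expect_equal(aurora_activity(1, 1, 1.5), exp(-1 / 4.5))
  expect_equal(aurora_activity(1, 1, 1.5), 0.8007, tolerance = 1e-4)
  expect_equal(aurora_activity(1, 0.25, 1.5), 0.2002, tolerance = 1e-4)
  # ~3 um working radius: < 14% of the pole value beyond 3 um
  expect_lt(aurora_activity(3.0001, 1, 1.5), 0.14)
  expect_equal(aurora_activity(3, 1, 1.5), exp(-9 / 4.5), tolerance = 1e-12)
})

test_that("the initiation hazard encodes gradient gating and CENP-E bypass", {
  p <- spindle_preset("cenpe_inhibited_1v0")
  # saturated gradient near a centriolar pole: hazard 0
  expect_equal(initiation_hazard(1, p, centriolar = TRUE), 0)
  # acentriolar pole at 1 um: h = 0.55 (1 - 0.2002/0.4) ~ 0.275
  expect_equal(initiation_hazard(1, p, centriolar = FALSE),
               0.55 * (1 - 0.25 * exp(-1 / 4.5) / 0.4), tolerance = 1e-12)
  expect_equal(initiation_hazard(1, p, centriolar = FALSE), 0.2748,
               tolerance = 5e-4)
  # CENP-E active: flat h_max
  pc <- spindle_preset("control_2v2")
  expect_equal(initiation_hazard(c(0.5, 1, 5), pc, centriolar = TRUE),
               rep(0.55, 3))
})

test_that("the hazard is non-decreasing in distance without CENP-E", {
  for (nm in c("cenpe_inhibited_2v2", "cenpe_inhibited_0v0",
               "cenpe_inhibited_2v2_auroraA_inhibited")) {
    p <- spindle_preset(nm)
    d <- seq(0, 8, by = 0.05)
    for (cen in c(TRUE, FALSE)) {
      h <- initiation_hazard(d, p, centriolar = cen)
      expect_true(all(diff(h) >= -1e-12))
      expect_true(all(h >= 0 & h <= p$h_max))
    }
  }
})

test_that("presets validate their fields", {
  expect_error(spindle_preset("nope"), "unknown preset")
  expect_error(spindle_preset("control_2v2", acentriolar_factor = 1.5),
               "acentriolar_factor")
  expect_error(spindle_preset("control_2v2", h_max = -1), "positive")
  expect_error(spindle_preset("control_2v2", bogus = 1), "unknown preset fields")
  expect_identical(spindle_preset("cenpe_inhibited_1v0")$centriole_config,
                   c(1L, 0L))
})

test_that("identical preset and seed give identical cells", {
  p <- spindle_preset("cenpe_inhibited_1v0")
  s1 <- simulate_cell(p, 99)
  s2 <- simulate_cell(p, 99)
  expect_identical(s1$cell, s2$cell)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cell(p, 100)
  expect_false(identical(s1$cell$pair_tracks, s3$cell$pair_tracks))
})

test_that("polar pairs near centriolar poles never initiate without CENP-E", {
  p <- spindle_preset("cenpe_inhibited_2v2")
  for (seed in 1:50) {
    tr <- simulate_cell(p, seed)$truth
    polar <- tr[tr$initially_polar, ]
    expect_true(all(polar$d_init <= p$polar_dist_max))
    expect_true(all(is.infinite(polar$t_initiation)))
  }
})

test_that("control initiation delays follow the exponential clock", {
  p <- spindle_preset("control_2v2")
  delays <- unlist(lapply(1:500, function(s) {
    tr <- simulate_cell(p, s)$truth
    tr$t_initiation[tr$initially_polar] - p$t_bipolarization
  }))
  expect_true(all(delays >= 0))
  expect_equal(mean(delays), 1 / 0.55, tolerance = 0.1)
})

test_that("zero pole noise gives exactly the amplitude-model pole ratio", {
  p <- spindle_preset("cenpe_inhibited_1v0", noise_cv_pole = 0)
  sim <- simulate_cell(p, 5)
  s <- simulate_intensities(sim, 6)
  r <- pole_ratio(s)
  expect_equal(r$ratio, 1 / p$acentriolar_factor, tolerance = 1e-12)
  expect_false(r$symmetric_pair)
})

test_that("1:1 spindles with 5% pole noise keep near-unit max/min ratios", {
  p <- spindle_preset("cenpe_inhibited_1v1")
  ratios <- vapply(1:200, function(s) {
    sim <- simulate_cell(p, s)
    pole_ratio(simulate_intensities(sim, s + 7e5))$ratio
  }, numeric(1))
  m <- mean(ratios)
  expect_gte(m, 1.0)
  expect_lte(m, 1.15)
})

test_that("kinetochore intensity decays with distance when noise is off", {
  p <- spindle_preset("cenpe_inhibited_2v2", noise_cv_kc = 0,
                      background_sd = 0, reference_sd = 0)
  sim <- simulate_cell(p, 11)
  s <- simulate_intensities(sim, 12)
  kc <- s[s$roi_kind == "kinetochore_pair", ]
  corr <- corrected_intensity(kc$mean_signal, kc$background_mean)$corrected
  norm <- normalize_to_reference(corr, kc$reference_mean)
  # strictly decreasing in the true distance (monotone map of d)
  d3 <- spindlekin:::final_frame_geometry(sim)$dist_pole_near_3d
  o <- order(d3)
  expect_true(all(diff(norm[o]) <= 1e-9))
})

test_that("cohorts are reproducible and reduce to single cells", {
  p <- spindle_preset("control_1v0")
  co1 <- simulate_experiment(p, 3, 17)
  co2 <- simulate_experiment(p, 3, 17)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$intensities, co2$intensities)
  expect_identical(co1$manifest$preset_hash, co2$manifest$preset_hash)

  co3 <- simulate_experiment(p, 1, 17)
  direct <- simulate_cell(p, co3$manifest$cell_seeds[1])
  expect_identical(co3$cells[[1]], direct$cell)

  # different root seeds: same model, different realizations, but
  # initiation-delay distributions agree in mean within Monte-Carlo error
  pa <- spindle_preset("cenpe_inhibited_0v0")
  d1 <- simulate_experiment(pa, 30, 1, with_intensities = FALSE)$truth
  d2 <- simulate_experiment(pa, 30, 2, with_intensities = FALSE)$truth
  m1 <- mean(d1$t_initiation[d1$initially_polar], na.rm = TRUE)
  m2 <- mean(d2$t_initiation[d2$initially_polar], na.rm = TRUE)
  expect_false(identical(d1$d_init, d2$d_init))
  expect_equal(m1, m2, tolerance = 0.15)
})

test_that("ground-truth initiation respects bipolarization and track span", {
  p <- spindle_preset("cenpe_inhibited_1v0")
  for (s in 1:10) {
    sim <- simulate_cell(p, s)
    polar <- sim$truth[sim$truth$initially_polar, ]
    expect_true(all(polar$t_initiation >= p$t_bipolarization))
    # tracks share the pole-track time base
    expect_true(all(sim$cell$pair_tracks$time_min %in%
                      sim$cell$pole_tracks$time_min))
  }
})
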