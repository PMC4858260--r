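# Stimuli, sampling geometries and the corridor renderer.

test_that("grating luminance follows its definition", {
  g <- grating("sine", wavelength = 20, angular_velocity = 0, contrast = 0.8)
  # zero crossings of the wave sit at the mean luminance
  expect_equal(grating_luminance(g, 0), 0.5)
  expect_equal(grating_luminance(g, 10), 0.5)

  gs <- grating("square", wavelength = 20, contrast = 1)
  expect_equal(grating_luminance(gs, 5), 1.0)   # bright half-cycle from phase 0
  expect_equal(grating_luminance(gs, 15), 0.0)  # dark half-cycle

  # moving at 100 deg/s for 1 s equals a 100 deg shift of the pattern
  gm <- grating("sine", 38, angular_velocity = 100, contrast = 1)
  ang <- seq(0, 200, by = 0.5)
  expect_equal(grating_luminance(gm, ang, t = 1),
               grating_luminance(gm, ang - 100, t = 0))

  expect_error(grating("sine", wavelength = -3), "wavelength")
  expect_error(grating("sine", 20, contrast = 2), "contrast")
  expect_error(grating("sine", 20, mean_luminance = 0.9, contrast = 0.5),
               "luminance")
})

test_that("test-array sampling respects its geometry", {
  geom <- test_array_geometry()
  expect_length(geom$angles, 200)
  expect_equal(geom$n_avdus, 198L)

  # contrast 0: a uniform field at the mean
  g0 <- grating("sine", 38, 100, contrast = 0)
  expect_equal(sample_test_array(geom, g0, 0.3), rep(0.5, 200))

  # rows are parallel to the motion axis and see identical samples
  g <- grating("square", 19, 70)
  s <- sample_test_array(geom, g, 0.11)
  expect_identical(s[1:100], s[101:200])

  # wavelength = 2 x spacing: adjacent receptors sample opposite phases
  g4 <- grating("sine", 4, 0, contrast = 1, mean_luminance = 0.5, phase0 = -1)
  s4 <- sample_test_array(geom, g4, 0)
  expect_equal(s4[1:99] - 0.5, -(s4[2:100] - 0.5), tolerance = 1e-12)

  # vectorised time sampling agrees with per-time sampling
  tt <- c(0, 0.01, 0.5)
  m <- sample_test_array(geom, g, tt)
  expect_equal(m[2, ], sample_test_array(geom, g, tt[2]))
})

test_that("system builders instantiate the documented detector counts", {
  p <- avdu_params()
  expect_equal(build_test_system(p)$n_avdus, 198L)
  one_row <- test_array_geometry(n_rows = 1)
  expect_equal(build_test_system(p, one_row)$n_avdus, 99L)
  # adjacent-pair rule: n locations -> n - 1 AVDUs per row
  for (n in c(2, 7, 33)) {
    expect_equal(build_test_system(p, test_array_geometry(n_per_row = n,
                                                          n_rows = 1))$n_avdus,
                 n - 1L)
  }

  fs <- build_full_system(p)
  expect_equal(unname(fs$n_avdus), c(66L, 66L, 35L))
  expect_equal(fs$subregions$left$n_avdus / length(9:14), 11)   # per row
  expect_equal(fs$subregions$centre$n_avdus / length(13:19), 5) # per column

  expect_error(subregion_layout(right_cols = 12:32), "overlap")
})

test_that("bee/model spatial-frequency conversion inverts itself", {
  f <- c(0.05, 0.15, 0.6, 0.8)
  m <- scale_spatial_frequency(f, "bee_to_model")
  expect_equal(m, f / 5)
  expect_equal(scale_spatial_frequency(m, "model_to_bee"), f)
})

test_that("corridor rendering is exact on constructed scenes", {
  # uniform world: every sample at the mean luminance
  wu <- corridor_world(left_wall = wall_pattern("uniform"),
                       right_wall = wall_pattern("uniform"),
                       floor = wall_pattern("uniform"))
  fr <- render_corridor(wu, bee_pose())
  expect_true(all(fr == 0.5))

  # centred bee, identical walls: frame is left/right mirror symmetric
  w <- sine_corridor(0.03)
  fr <- render_corridor(w, bee_pose(x = 0))
  expect_equal(fr, fr[, 32:1], tolerance = 1e-12)

  # determinism
  expect_identical(fr, render_corridor(w, bee_pose(x = 0)))

  # hand-computed ray-plane intersection: ommatidium nearest (az -90, el 0),
  # bee 5 cm from the left wall
  grid <- ommatidial_grid()
  col <- which.min(abs(grid$azimuth + 90))   # az = -90.1875 is not on grid
  row <- which.min(abs(grid$elevation))
  az <- grid$azimuth[col] * pi / 180
  el <- grid$elevation[row] * pi / 180
  pose <- bee_pose(x = -5, y = 12)
  tt <- (-10 - pose$x) / (sin(az) * cos(el))
  expect_equal(tt, 5, tolerance = 0.01)               # hit distance about 5 cm
  y_hit <- pose$y + tt * cos(az) * cos(el)
  lam_cm <- 1 / cpd_to_cycles_per_cm(0.03, 10)
  by_hand <- 0.5 * (1 + sin(2 * pi * y_hit / lam_cm))
  fr <- render_corridor(w, pose)
  expect_equal(fr[row, col], by_hand, tolerance = 1e-12)

  # translating the bee by one floor-pattern wavelength reproduces the frame
  wf <- corridor_world(left_wall = wall_pattern("uniform"),
                       right_wall = wall_pattern("uniform"))
  lam_floor <- 1 / cpd_to_cycles_per_cm(wf$floor$freq_cpd, 10)
  f1 <- render_corridor(wf, bee_pose(y = 0))
  f2 <- render_corridor(wf, bee_pose(y = lam_floor))
  expect_equal(f1, f2, tolerance = 1e-9)

  expect_warning(render_corridor(w, bee_pose(x = 15)), "clamped")
})

test_that("wall patterns validate their inputs", {
  expect_error(wall_pattern("sine", 0), "freq_cpd")
  expect_error(wall_pattern("sine", 0.1, contrast = 1.2), "contrast")
  expect_silent(wall_pattern("uniform"))
  expect_error(corridor_world(width = -1), "positive")
})
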