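test_that("generators are bit-identical under a fixed seed", {
  a <- make_fish_scene(5, 20, 0.5, seed = 42, img_size = c(48, 48), n_planes = 3)
  b <- make_fish_scene(5, 20, 0.5, seed = 42, img_size = c(48, 48), n_planes = 3)
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_identical(a$truth$mrnas, b$truth$mrnas)
  f1 <- make_frap_trace(0.6, 20, seed = 9)
  f2 <- make_frap_trace(0.6, 20, seed = 9)
  expect_identical(f1$values, f2$values)
  m1 <- make_live_movie(3, 0.2, 0.01, n_frames = 10, seed = 3, img_size = c(32, 32))
  m2 <- make_live_movie(3, 0.2, 0.01, n_frames = 10, seed = 3, img_size = c(32, 32))
  expect_identical(m1$stack$pixels, m2$stack$pixels)
})

test_that("fish scene geometry matches its truth labels", {
  sc <- make_fish_scene(6, 60, 1, seed = 1, img_size = c(96, 96))
  expect_true(all(sc$truth$mrnas$recruited))
  # every recruited mRNA lies within its condensate radius
  tc <- sc$truth$condensates
  m <- sc$truth$mrnas
  d <- sqrt((m$x - tc$x[m$condensate])^2 + (m$y - tc$y[m$condensate])^2) * 110
  expect_true(all(d <= tc$radius_nm[m$condensate] + 1e-9))
  expect_true(all(m$z == tc$z[m$condensate]))

  sc0 <- make_fish_scene(6, 40, 0, seed = 2, img_size = c(96, 96))
  m0 <- sc0$truth$mrnas
  expect_false(any(m0$recruited))
  dmin <- apply(sqrt(outer(m0$x, sc0$truth$condensates$x, `-`)^2 +
                     outer(m0$y, sc0$truth$condensates$y, `-`)^2), 1, min)
  expect_true(all(dmin * 110 > 2 * sc0$truth$recruit_radius_nm))

  expect_error(make_fish_scene(0, 10, 0.5, seed = 1), "zero condensates")
})

test_that("camera noise follows Poisson + read statistics", {
  nse <- noise_config(photon_gain = 2, read_noise_sd = 3, background_level = 50)
  vals <- withr::with_seed(11, replicate(4000, {
    condquant:::apply_camera_noise(matrix(100, 1, 1), nse)[1, 1]
  }))
  expect_equal(mean(vals), 150, tolerance = 0.01)
  expect_equal(var(vals), 150 / 2 + 9, tolerance = 0.08)
})

test_that("live movie honours binding limits and step statistics", {
  m <- make_live_movie(5, 0.2, 0.01, binding = list(k_on = 0, k_off = 1,
                                                    capture_radius_nm = 400),
                       n_frames = 50, seed = 4, render = FALSE)
  expect_false(any(m$truth$bound))
  m2 <- make_live_movie(5, 0.2, 0.001,
                        binding = list(k_on = 1e5, k_off = 0, capture_radius_nm = 2000),
                        n_frames = 120, seed = 5, img_size = c(24, 24), render = FALSE)
  # once bound, bound forever
  for (s in 1:5) {
    b <- m2$truth$bound[, s]
    if (any(b)) expect_true(all(b[which(b)[1]:length(b)]))
  }
  # step variance oracle: var per axis = 2 D dt (in um^2)
  m3 <- make_live_movie(20, 0.3, 0, n_frames = 501, seed = 6,
                        n_condensates = 0, boundary = "none", render = FALSE)
  steps_um <- diff(m3$truth$mrna_xy_px[, , 1]) * 110 / 1000
  expect_equal(var(as.vector(steps_um)), 2 * 0.3 * 0.05, tolerance = 0.05)
  expect_error(make_live_movie(2, 0.1, 0, optics = optics_config(frame_interval_s = NA),
                               seed = 1),
               "frame_interval_s|positive")
})

test_that("frap trace matches its closed form", {
  tr <- make_frap_trace(1, 20, noise_sd = 0, seed = 1, n_frames = 400)
  expect_equal(tail(tr$values, 1), 1, tolerance = 1e-6)
  tr0 <- make_frap_trace(0, 20, noise_sd = 0, seed = 1)
  expect_true(all(abs(tr0$values[-(1:10)] - 0.3) < 1e-12))
  tr6 <- make_frap_trace(0.6, 20, noise_sd = 0, seed = 1, frame_interval_s = 1)
  # value at t = tau after bleach: b + (1-b) * M * (1 - exp(-1))
  v <- tr6$values[tr6$pre_frames + 1 + 20]
  expect_equal(v, 0.3 + 0.7 * 0.6 * (1 - exp(-1)), tolerance = 1e-9)
  expect_error(make_frap_trace(0.5, 10, pre_frames = 0, seed = 1), "pre_frames")
})

test_that("reporter traces follow the synthesis-loss decay model", {
  cfg <- reporter_config(inhibition_alpha = 0, noise_sd = 0)
  flat <- make_reporter_traces(3, cfg, duration_h = 12, seed = 2)
  for (cell in split(flat$traces, flat$traces$cell))
    expect_equal(cell$value / cell$value[1], rep(1, nrow(cell)))
  # alpha = 1, T1/2 = 6 h, t = 12 h -> 0.25; alpha = 0.5 -> 0.625
  for (al in c(1, 0.5)) {
    cfg <- reporter_config(inhibition_alpha = al, noise_sd = 0)
    tr <- make_reporter_traces(1, cfg, duration_h = 12, seed = 3)$traces
    expect_equal(tail(tr$value, 1) / tr$value[1], (1 - al) + al * 0.25,
                 tolerance = 1e-9)
  }
})

test_that("phase scan places the clustering transition at csat", {
  low <- make_phase_scan(100, csat = 1000,
                         expression_dist = c(log(10), 0.3), seed = 4)
  expect_equal(sum(low$cells$clustered), 0)
  ps <- make_phase_scan(4000, csat = 100, seed = 5, shift_with_mrna = 0)
  near <- abs(log(ps$cells$c1 / 100)) < 0.02
  expect_gt(sum(near), 50)
  expect_equal(mean(ps$cells$clustered[near]), 0.5, tolerance = 0.15)
})

test_that("spine series truth volumes follow the analytic sphere", {
  sp <- make_spine_series(3, c(4, 5, 6), 1, seed = 6, n_timepoints = 4)
  expect_equal(sp$truth$volumes_vox[1, ], 4 / 3 * pi * c(4, 5, 6)^3)
  expect_true(all(apply(sp$truth$volumes_vox, 2, function(v) length(unique(v)) == 1)))
  sp2 <- make_spine_series(2, 4, 1.5, seed = 7, n_timepoints = 5, stim_frame = 3)
  expect_equal(sp2$truth$volumes_vox[5, ] / sp2$truth$volumes_vox[1, ], c(1.5, 1.5))
  expect_error(make_spine_series(2, 1, 1.5, seed = 1), ">= 2 px")
  expect_error(make_spine_series(3, 6, 1.5, seed = 1, spacing_px = 4),
               "overlap")
})

test_that("bead pairs encode the channel offset", {
  bp <- make_bead_pair(8, c(0, 0), seed = 8)
  expect_lt(max(abs(phase_cross_correlation(bp$ref$pixels,
                                            bp$moving$pixels))), 0.05)
  expect_error(make_bead_pair(2, c(1, 1), seed = 1), "at least 3")
})
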