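test_that("trajectory linking preserves identities and the step constraint", {
  # single slow spot -> one full-length trajectory
  frames <- lapply(1:20, function(f)
    data.frame(x_px = 10 + 0.1 * f, y_px = 5 + 0.05 * f))
  tr <- link_trajectories(frames, max_disp_px = 2)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 20)
  # two spots crossing with per-frame steps < max_disp keep identities
  fr2 <- lapply(1:21, function(f)
    data.frame(x_px = c(0 + 0.5 * (f - 1), 10 - 0.5 * (f - 1)),
               y_px = c(0, 3)))
  tr2 <- link_trajectories(fr2, max_disp_px = 1.2)
  expect_length(tr2, 2)
  ys <- vapply(tr2, function(t) unique(t$y_px), 0)
  expect_setequal(ys, c(0, 3))
  # dense random field: no linked step exceeds max_disp
  set.seed(1)
  fr3 <- lapply(1:15, function(f)
    data.frame(x_px = runif(12, 0, 50), y_px = runif(12, 0, 50)))
  tr3 <- link_trajectories(fr3, max_disp_px = 3, max_gap = 1)
  for (t in tr3) {
    if (nrow(t) < 2) next
    stp <- sqrt(diff(t$x_px)^2 + diff(t$y_px)^2) / diff(t$frame)
    expect_true(all(stp <= 3 + 1e-12))
  }
})

test_that("tracking works end-to-end from rendered movie frames", {
  mv <- make_live_movie(3, 0.05, 0, n_frames = 12, seed = 13,
                        n_condensates = 0, img_size = c(64, 64))
  frames <- lapply(1:12, function(t) {
    img <- stack_plane(mv$stack, channel = 2, t = t)
    cand <- detect_spots(img)
    sp <- localize_gaussian(img, cand)
    sp[sp$fit_ok, c("x_px", "y_px")]
  })
  tr <- link_trajectories(frames, max_disp_px = 4)
  long <- tr[vapply(tr, nrow, 0L) >= 10]
  expect_equal(length(long), 3)
  # each long track shadows one truth particle within localization error
  for (t in long) {
    d0 <- vapply(1:3, function(s)
      mean(sqrt((t$x_px - mv$truth$mrna_xy_px[t$frame, s, 1])^2 +
                (t$y_px - mv$truth$mrna_xy_px[t$frame, s, 2])^2)), 0)
    expect_lt(min(d0), 0.3)
  }
})

test_that("MSD matches the double-loop oracle and handles degeneracies", {
  set.seed(2)
  traj <- data.frame(frame = 1:40, x_px = cumsum(rnorm(40)),
                     y_px = cumsum(rnorm(40)))
  msd <- compute_msd(traj, pixel_size_nm = 110, frame_interval_s = 0.05)
  um <- 0.11
  for (L in seq_len(nrow(msd))) {
    acc <- 0; n <- 0
    for (i in 1:(40 - L)) {
      acc <- acc + ((traj$x_px[i + L] - traj$x_px[i])^2 +
                    (traj$y_px[i + L] - traj$y_px[i])^2) * um^2
      n <- n + 1
    }
    expect_equal(msd$msd_um2[L], acc / n, tolerance = 1e-9)
  }
  expect_true(all(diff(msd$n_pairs) <= 0))
  # stationary spot
  still <- data.frame(frame = 1:20, x_px = 3, y_px = 4)
  expect_true(all(compute_msd(still, 110, 0.05)$msd_um2 == 0))
  # ballistic drift: MSD(n dt) = n^2 px^2
  bal <- data.frame(frame = 1:40, x_px = 1:40, y_px = 0)
  mb <- compute_msd(bal, 1000, 1)   # 1 um pixels
  expect_equal(mb$msd_um2, (seq_len(nrow(mb)))^2, tolerance = 1e-12)
  expect_error(compute_msd(still[1:4, ], 110, 0.05), "short")
})

test_that("diffusion fit uses lags 2-4 with a free intercept", {
  lag <- (1:8) * 0.05
  exact <- data.frame(lag_s = lag, msd_um2 = 4 * 0.5 * lag, n_pairs = 100)
  f <- fit_diffusion(exact)
  expect_equal(f$D_um2_s, 0.5, tolerance = 1e-12)
  expect_equal(f$intercept_um2, 0, tolerance = 1e-12)
  offs <- exact; offs$msd_um2 <- offs$msd_um2 + 0.02
  f2 <- fit_diffusion(offs)
  expect_equal(f2$D_um2_s, 0.5, tolerance = 1e-12)
  expect_equal(f2$intercept_um2, 0.02, tolerance = 1e-12)
  expect_error(fit_diffusion(exact[1:3, ]), "4")
})

test_that("diffusion is recovered from simulated ensembles and ranks species", {
  mv <- make_live_movie(30, 0.3, 0.01, n_frames = 300, seed = 11,
                        n_condensates = 0, boundary = "none", render = FALSE)
  D <- mean(vapply(1:30, function(s)
    fit_diffusion(compute_msd(truth_traj(mv$truth, s), 110, 0.05))$D_um2_s, 0))
  expect_lt(abs(D / 0.3 - 1), 0.1)
  # faster species ranks faster (mRNA vs condensate mobility contrast)
  mvc <- make_live_movie(15, 0.3, 0.01, n_frames = 300, seed = 12,
                         boundary = "none", render = FALSE, n_condensates = 8)
  Dc <- mean(vapply(1:8, function(k) {
    tr <- data.frame(frame = seq_len(300),
                     x_px = mvc$truth$condensate_xy_px[, k, 1],
                     y_px = mvc$truth$condensate_xy_px[, k, 2])
    fit_diffusion(compute_msd(tr, 110, 0.05))$D_um2_s
  }, 0))
  Dm <- mean(vapply(1:15, function(s)
    fit_diffusion(compute_msd(truth_traj(mvc$truth, s), 110, 0.05))$D_um2_s, 0))
  expect_gt(Dm, Dc)
})

test_that("distance traces match a per-frame scan and propagate gaps", {
  set.seed(3)
  mr <- data.frame(frame = 1:30, x_px = cumsum(rnorm(30, sd = .3)),
                   y_px = cumsum(rnorm(30, sd = .3)))
  cds <- list(
    data.frame(frame = 1:30, x_px = 5 + cumsum(rnorm(30, sd = .1)),
               y_px = 5 + cumsum(rnorm(30, sd = .1))),
    data.frame(frame = 5:25, x_px = 2, y_px = 2))
  dt <- distance_trace(mr, cds, 110)
  for (i in c(1, 10, 27)) {
    f <- mr$frame[i]
    ds <- c()
    for (cd in cds) {
      j <- match(f, cd$frame)
      if (!is.na(j)) ds <- c(ds, sqrt((cd$x_px[j] - mr$x_px[i])^2 +
                                      (cd$y_px[j] - mr$y_px[i])^2) * 110)
    }
    expect_equal(dt$dist_nm[i], min(ds))
  }
  # co-moving pair -> constant trace
  co <- distance_trace(mr, list(transform(mr, x_px = x_px + 1)), 110)
  expect_true(all(abs(co$dist_nm - 110) < 1e-9))
  expect_error(distance_trace(mr, list(data.frame(frame = 100:110, x_px = 0,
                                                  y_px = 0)), 110),
               "overlap")
})

test_that("binding-event detection reproduces switch times and dwell stats", {
  # square wave: 10-frame half periods at 20 Hz -> 0.5 s events
  sq <- data.frame(frame = 1:100,
                   dist_nm = rep(c(rep(100, 10), rep(900, 10)), 5))
  ev <- detect_binding_events(sq, frame_interval_s = 0.05)
  expect_equal(ev$summary$n_events, 5)
  expect_true(all(abs(ev$events$duration_s - 0.5) < 1e-9))
  expect_equal(ev$summary$fraction_transient, 1)
  # always far -> no events
  far <- data.frame(frame = 1:50, dist_nm = 700)
  expect_equal(detect_binding_events(far, frame_interval_s = 0.05)$summary$n_events, 0)
  # all-missing trace -> empty
  na <- data.frame(frame = 1:10, dist_nm = NA_real_)
  expect_equal(detect_binding_events(na, frame_interval_s = 0.05)$summary$n_events, 0)
  expect_error(detect_binding_events(sq, r_on_nm = 600, r_off_nm = 400,
                                     frame_interval_s = 0.05), "hysteresis")
  # telegraph simulation: median dwell within 20% of the generator truth
  # (medians are multiples of the frame interval, so average over seeds)
  meds <- vapply(21:23, function(s) {
    tg <- make_telegraph_trace(0.5, 2, n_frames = 8000, seed = s)
    det <- detect_binding_events(tg$trace, frame_interval_s = 0.05)
    c(det$summary$median_dwell_s, median(tg$truth$duration_s))
  }, numeric(2))
  expect_lt(abs(mean(meds[1, ]) / mean(meds[2, ]) - 1), 0.2)
})
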