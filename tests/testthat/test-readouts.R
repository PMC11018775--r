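test_that("reporter normalization and endpoint summaries", {
  tr <- data.frame(cell = rep(1:3, each = 4), t_h = rep(c(0, 4, 8, 12), 3),
                   value = rep(c(10, 50, 200), each = 4))
  rn <- reporter_normalize(tr)
  expect_true(all(rn$traces$value == 1))
  expect_equal(rn$endpoint$mean, 1)
  # noiseless alpha = 1 pipeline endpoint = 0.25 within 1e-6
  cfg <- reporter_config(inhibition_alpha = 1, noise_sd = 0)
  rp <- make_reporter_traces(8, cfg, duration_h = 12, seed = 41)
  expect_equal(reporter_normalize(rp$traces)$endpoint$mean, 0.25,
               tolerance = 1e-6)
  # zero initial value excluded with a warning
  tr0 <- rbind(tr, data.frame(cell = 4, t_h = c(0, 4, 8, 12), value = 0))
  expect_warning(rn0 <- reporter_normalize(tr0), "excluded")
  expect_equal(rn0$endpoint$n, 3)
})

test_that("expression binning uses half-open bins", {
  cells <- data.frame(expression = c(50, 100, 150, 399.9, 400, -5),
                      endpoint = c(1, 2, 3, 4, 5, 6))
  bb <- bin_by_expression(cells)
  expect_equal(bb$bins$n, c(1, 2, 0, 1))      # 100 falls in the second bin
  expect_equal(bb$n_excluded, 2)              # 400 and -5 outside
  expect_true(is.na(bb$bins$mean[3]))
  expect_error(bin_by_expression(cells, c(0, 0, 10)), "increase")
  # generator with endpoint decreasing in expression -> monotone bin means
  set.seed(42)
  cells2 <- data.frame(expression = runif(200, 0, 400))
  cells2$endpoint <- 1 - 0.002 * cells2$expression + rnorm(200, sd = 0.01)
  mb <- bin_by_expression(cells2)$bins$mean
  expect_true(all(diff(mb) < 0))
})

test_that("half-life fitting recovers the decay constant", {
  tr <- data.frame(t_h = seq(0, 24, 0.5))
  tr$value <- exp(-tr$t_h * log(2) / 6)
  expect_equal(fit_half_life(tr)$t_half_h, 6, tolerance = 1e-9)
  trf <- tr; trf$value <- 0.9 * exp(-trf$t_h * log(2) / 6) + 0.1
  expect_equal(fit_half_life(trf, floor = TRUE)$t_half_h, 6, tolerance = 0.02 * 6)
  rising <- data.frame(t_h = 0:9, value = 1:10)
  expect_error(fit_half_life(rising), "not decaying")
})

test_that("FRAP analysis recovers mobile fractions", {
  full <- make_frap_trace(1, 15, noise_sd = 0.005, seed = 51, n_frames = 200)
  expect_gt(frap_analyze(full)$mobile_fraction, 0.95)
  m6 <- frap_analyze(make_frap_trace(0.6, 20, noise_sd = 0.02, seed = 52))
  expect_lt(abs(m6$mobile_fraction - 0.6), 0.05)
  expect_equal(m6$immobile_fraction, 1 - m6$mobile_fraction)
  flat <- make_frap_trace(0, 20, noise_sd = 0.01, seed = 53)
  expect_lt(frap_analyze(flat)$mobile_fraction, 0.05)
  nob <- list(times = 0:20, values = rep(1, 21), pre_frames = 5)
  expect_error(frap_analyze(nob), "bleach")
})

test_that("spine volumes track blurred spheres and resist intensity scaling", {
  sp <- make_spine_series(6, c(4, 5, 6), 1.5, seed = 54)
  pre <- spine_preprocess(sp$stack)
  sv <- spine_volume(pre, sp$roi_boxes)
  relerr <- abs(sv$volumes_vox[1, ] / sp$truth$volumes_vox[1, ] - 1)
  expect_true(all(relerr <= 0.15))
  # doubling intensity changes volumes by < 5% (local threshold robustness)
  dbl <- pre; dbl$pixels <- dbl$pixels * 2
  sv2 <- spine_volume(dbl, sp$roi_boxes)
  expect_lt(max(abs(sv2$volumes_vox / sv$volumes_vox - 1)), 0.05)
  # blank ROI -> 0
  blank <- image_stack(array(0, c(30, 30, 3, 1)), c("Y", "X", "Z", "T"))
  expect_equal(sum(spine_volume(blank, data.frame(y0 = 5, y1 = 25, x0 = 5,
                                                  x1 = 25))$volumes_vox), 0)
  expect_error(spine_volume(blank, data.frame(y0 = 5, y1 = 45, x0 = 5, x1 = 25)),
               "inside")
})

test_that("spine change normalizes by baseline and reports s.e.m.", {
  vols <- cbind(c(10, 10, 10, 15, 15), c(20, 20, 20, 30, 30), c(0, 0, 0, 0, 0))
  ch <- spine_change(vols)
  expect_equal(ch$excluded, 3)
  expect_equal(ch$mean, c(1, 1, 1, 1.5, 1.5))
  expect_equal(ch$sem, apply(ch$normalized, 1, sd) / sqrt(2))
  const <- spine_change(cbind(rep(7, 5)))
  expect_true(all(const$normalized == 1))
})

test_that("OP-Puro intensities are measured per nucleus at the peak plane", {
  nuc <- withr::with_seed(55, {
    m <- condquant:::stamp_disc(matrix(0, 80, 80), 30, 40, 10, 200)
    m <- condquant:::stamp_disc(m, 48, 40, 10, 200)
    blur_gaussian(m, 1.5) + 50 + matrix(rnorm(6400, sd = 5), 80)
  })
  opp <- array(100, c(80, 80, 4))
  opp[, , 3] <- 160
  res <- oppuro_cell_intensity(opp, nuc)
  expect_equal(nrow(res), 2)          # touching nuclei split
  expect_equal(res$opp_intensity, c(160, 160))  # max over z picked plane 3
  empty <- oppuro_cell_intensity(opp, matrix(1, 80, 80))
  expect_equal(nrow(empty), 0)
})

test_that("PLA puncta are counted in 3D per cell mask", {
  stk <- withr::with_seed(56, {
    a <- array(0, c(72, 72, 3))
    gx <- rep(seq(8, 64, by = 14), 5)[1:25]
    gy <- rep(seq(8, 64, by = 14), each = 5)[1:25]
    zz <- rep(1:3, length.out = 25)
    for (i in 1:25) a[, , zz[i]] <- condquant:::render_spots_2d(
      a[, , zz[i]], gx[i], gy[i], 300, 1.2)
    for (z in 1:3) a[, , z] <- a[, , z] + 100 + matrix(rnorm(72 * 72, sd = 8), 72)
    a
  })
  masks <- matrix(0L, 72, 72)
  masks[, 1:36] <- 1L; masks[, 37:72] <- 2L
  out <- pla_count(stk, masks)
  expect_equal(sum(out$n_puncta), 25)
  blank <- array(withr::with_seed(57, rnorm(72 * 72 * 2, 100, 5)), c(72, 72, 2))
  expect_equal(sum(pla_count(blank, masks)$n_puncta), 0)
})

test_that("pooled t test matches hand formulas and conventions", {
  same <- ttest_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  tb <- ttest_two_tailed(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tb$t, -sqrt(1.5), tolerance = 1e-9)   # -1.2247
  expect_equal(tb$df, 4)
  swapped <- ttest_two_tailed(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swapped$t, -tb$t)
  expect_equal(swapped$p, tb$p)
  const <- ttest_two_tailed(c(1, 1), c(1, 1))
  expect_equal(const$p, 1)
  # agreement with the reference implementation
  set.seed(58)
  a <- rnorm(12); b <- rnorm(15, 0.4)
  ours <- ttest_two_tailed(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  w <- ttest_two_tailed(a, b, equal_var = FALSE)
  refw <- t.test(a, b)
  expect_equal(w$p, refw$p.value, tolerance = 1e-12)
})
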