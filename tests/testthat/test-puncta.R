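test_that("condensate segmentation finds discs and conserves intensity", {
  expect_equal(nrow(segment_condensates(matrix(3, 40, 40))), 0)
  img <- withr::with_seed(1, {
    m <- condquant:::stamp_disc(matrix(0, 64, 64), 18.5, 20.2, 4, 300)
    m <- condquant:::stamp_disc(m, 45.1, 44.8, 4, 300)
    blur_gaussian(m, 1) + 50 + matrix(rnorm(64 * 64, sd = 3), 64)
  })
  reg <- segment_condensates(img, threshold = "mad")
  expect_equal(nrow(reg), 2)
  reg <- reg[order(reg$x), ]
  expect_lt(max(abs(reg$x - c(18.5, 45.1))), 0.5)
  expect_lt(max(abs(reg$y - c(20.2, 44.8))), 0.5)
  # member intensities equal the masked image sum (exact up to FP order)
  lab <- attr(reg, "labels")
  expect_equal(sum(reg$integrated_intensity), sum(img[lab > 0]),
               tolerance = 1e-12)
  # integrated intensity (above background) close to stamped photon sum
  bgsub <- sum(reg$integrated_intensity) - 50 * sum(reg$area_px)
  expect_equal(bgsub, 2 * 300 * sum(condquant:::stamp_disc(
    matrix(0, 21, 21), 10, 10, 4, 1)), tolerance = 0.15)
})

test_that("spot detection is precise on well-separated fields", {
  expect_equal(nrow(detect_spots(matrix(1, 32, 32))), 0)
  nse <- noise_config()
  amp <- amplitude_for_snr(10, nse)
  set.seed(2)
  gx <- rep(seq(10, 110, by = 25), 4); gy <- rep(seq(10, 85, by = 25), each = 5)
  truth <- data.frame(x = gx + runif(20, -2, 2), y = gy + runif(20, -2, 2))
  img <- withr::with_seed(3, condquant:::apply_camera_noise(
    spot_image(truth$x, truth$y, rep(amp, 20), sigma = 1.2, size = c(96, 128)),
    nse))
  cand <- detect_spots(img)
  expect_equal(nrow(cand), 20)
  d <- sqrt(outer(cand$x, truth$x, `-`)^2 + outer(cand$y, truth$y, `-`)^2)
  expect_true(all(apply(d, 2, min) < 1.5))
  # two maxima 1 px apart collapse to one candidate
  two <- spot_image(c(15, 16), 15, c(100, 100), sigma = 1.2, size = c(31, 31))
  expect_equal(nrow(detect_spots(two + withr::with_seed(4,
    matrix(rnorm(961, sd = 0.5), 31)))), 1)
})

test_that("gaussian localization is exact on noiseless spots", {
  img <- spot_image(10.3, 7.8, 500, sigma = 1.3, size = c(24, 24), offset = 2)
  sp <- localize_gaussian(img, data.frame(x = 10, y = 8))
  expect_true(sp$fit_ok)
  expect_lt(abs(sp$x_px - 10.3), 0.02)
  expect_lt(abs(sp$y_px - 7.8), 0.02)
  expect_lt(abs(sp$amplitude - 500) / 500, 0.02)
  expect_equal(sp$offset, 2, tolerance = 0.01)
  # flat (saturated) window cannot fit
  flat <- localize_gaussian(matrix(9, 24, 24), data.frame(x = 12, y = 12))
  expect_false(flat$fit_ok)
  # off-edge candidate is skipped with the edge flag
  edge <- localize_gaussian(img, data.frame(x = 2, y = 2))
  expect_false(edge$fit_ok)
  expect_true(edge$edge)
  expect_error(localize_gaussian(img, data.frame(x = 10, y = 8), window = 8),
               "odd")
})

test_that("max-min amplitude matches a direct convolution oracle", {
  expect_equal(as.numeric(amplitude_maxmin(matrix(4, 20, 20), 10, 10)), 0)
  img <- matrix(0, 25, 25); img[13, 13] <- 80
  got <- as.numeric(amplitude_maxmin(img, 12, 12))
  # kernel-convolution oracle: blurred single pixel = amp * outer(k, k)
  k <- condquant:::gaussian_kernel(1)
  kpad <- rep(0, 25); kpad[13 + seq_along(k) - (length(k) + 1) / 2] <- k
  ora_img <- 80 * outer(kpad, kpad)
  win <- ora_img[9:17, 9:17]
  expect_equal(got, max(win) - min(win), tolerance = 1e-12)
  # two spots in one window: amplitude reflects the brighter peak
  img2 <- spot_image(c(12, 15), c(12, 12), c(100, 40), sigma = 1, size = c(25, 25))
  one <- spot_image(12, 12, 100, sigma = 1, size = c(25, 25))
  expect_gte(as.numeric(amplitude_maxmin(img2, 12, 12)),
             as.numeric(amplitude_maxmin(one, 12, 12)))
})

test_that("assign_z collapses chains at the brightest plane", {
  mk <- function(z, amp) data.frame(x_px = 10 + 0.1 * z, y_px = 20, amplitude = amp)
  planes <- list(NULL, NULL, mk(3, 5), mk(4, 8), mk(5, 12), mk(6, 9), mk(7, 4))
  res <- assign_z(planes)
  expect_equal(nrow(res), 1)
  expect_equal(res$z_index, 5)
  expect_equal(res$chain_len, 5)
  # two lateral spots 5 px apart never merge at the default link radius
  p2 <- list(data.frame(x_px = c(10, 15), y_px = c(5, 5), amplitude = c(3, 4)),
             data.frame(x_px = c(10, 15), y_px = c(5, 5), amplitude = c(5, 2)))
  expect_equal(nrow(assign_z(p2)), 2)
  # amplitude tie -> lower plane index wins
  p3 <- list(data.frame(x_px = 8, y_px = 8, amplitude = 7),
             data.frame(x_px = 8, y_px = 8, amplitude = 7))
  expect_equal(assign_z(p3)$z_index, 1)
})

test_that("condensate intensity timecourse tracks growth", {
  expect_true(all(condensate_intensity_timecourse(
    image_stack(array(2, c(32, 32, 3)), c("Y", "X", "T")))$total_intensity == 0))
  nt <- 5
  arr <- withr::with_seed(5, {
    a <- array(0, c(48, 48, nt))
    for (t in 1:nt)
      a[, , t] <- blur_gaussian(condquant:::stamp_disc(
        matrix(0, 48, 48), 24, 24, 2 + 0.8 * t, 200), 1) + 20 +
        matrix(rnorm(48 * 48, sd = 1), 48)
    a
  })
  tcr <- condensate_intensity_timecourse(
    image_stack(arr, c("Y", "X", "T")), threshold = "mad")
  expect_true(all(diff(tcr$total_intensity) > 0))
})
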