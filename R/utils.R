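# Shared numeric helpers. Coordinate convention (repo-wide): 0-based indices;
# the centre of pixel (row i, col j) sits at continuous coordinate (i, j);
# physical position = index * pixel size. Matrices are (Y, X) = (row, col).

#' Discrete Gaussian kernel
#'
#' Normalized 1D Gaussian sampled at integer offsets, truncated at
#' `ceiling(4 * sigma)`.
#'
#' @param sigma standard deviation in pixels (> 0).
#' @return numeric vector of odd length summing to 1.
#' @keywords internal
gaussian_kernel <- function(sigma) {
  stopifnot(is.finite(sigma), sigma > 0)
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

#' Gaussian blur of a matrix
#'
#' Separable convolution with replicate edge handling.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return blurred matrix of the same size.
#' @export
blur_gaussian <- function(img, sigma) {
  stopifnot(is.matrix(img))
  if (sigma <= 0) return(img)
  cpp_sepconv(img, gaussian_kernel(sigma))
}

#' 3x3 median filter
#'
#' Replicate-edge median filter; suppresses shot noise without displacing
#' edges, which makes it the prefilter of choice before morphological
#' background estimation and local thresholding.
#'
#' @param img numeric matrix.
#' @return filtered matrix.
#' @export
median_filter3 <- function(img) {
  stopifnot(is.matrix(img))
  cpp_median3(img)
}

# Integer-offset shift with edge replication (used by morphology-free code
# paths such as local-maximum detection).
shift_int <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  img[ri, ci, drop = FALSE]
}

#' Bilinear sub-pixel shift
#'
#' Shifts an image by a continuous (dy, dx) so that
#' `out[i, j] ~= img[i - dy, j - dx]`, with edge replication.
#'
#' @param img numeric matrix.
#' @param dy,dx shift in pixels along rows (y) and columns (x).
#' @return shifted matrix.
#' @export
shift_bilinear <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  yi <- seq_len(nr) - dy
  xi <- seq_len(nc) - dx
  y0 <- floor(yi); x0 <- floor(xi)
  fy <- yi - y0;  fx <- xi - x0
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  ya <- cl(y0, nr); yb <- cl(y0 + 1, nr)
  xa <- cl(x0, nc); xb <- cl(x0 + 1, nc)
  wy <- matrix(fy, nr, nc)
  wx <- matrix(fx, nr, nc, byrow = TRUE)
  img[ya, xa, drop = FALSE] * (1 - wy) * (1 - wx) +
    img[yb, xa, drop = FALSE] * wy * (1 - wx) +
    img[ya, xb, drop = FALSE] * (1 - wy) * wx +
    img[yb, xb, drop = FALSE] * wy * wx
}

# Disc/ball structuring element offsets for radius r (pixels).
# Returns list(offsets = integer matrix (dy, dx), height = numeric).
ball_element <- function(radius, flat = FALSE) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- g$dy^2 + g$dx^2
  keep <- d2 <= radius^2
  offs <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(offs) <- "integer"
  h <- if (flat) rep(0, sum(keep)) else sqrt(pmax(radius^2 - d2[keep], 0))
  list(offsets = offs, height = h)
}

# 8-neighbourhood local maxima: pixel >= all neighbours. Returns a logical
# matrix; ties on plateaus are resolved later by the minimum-separation rule.
local_maxima8 <- function(img) {
  res <- matrix(TRUE, nrow(img), ncol(img))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    res <- res & (img >= shift_int(img, dy, dx))
  }
  res
}

# Otsu threshold of a numeric matrix (256-bin histogram).
otsu_threshold <- function(img) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 257)
  h <- as.numeric(tabulate(findInterval(v, br, all.inside = TRUE), 256))
  w <- cumsum(h)
  m <- cumsum(h * seq_len(256))
  n <- w[256]; mt <- m[256]
  w1 <- w[-256]; m1 <- m[-256]
  between <- (mt * w1 - n * m1)^2 / (w1 * (n - w1))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  (br[k] + br[k + 1]) / 2
}

# Deterministic per-call RNG scope. All generators route their randomness
# through this so a recorded seed regenerates bit-identical output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
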