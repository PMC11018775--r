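# Preprocessing corrections applied before detection. All filters accept a
# plain (Y, X) matrix or an ImageStack; for a stack they are applied to every
# plane, shape and metadata are preserved, and provenance grows by exactly
# one entry per call.

# Apply fun to every plane of x (matrix or ImageStack).
map_planes <- function(x, fun, op, params = list()) {
  if (is.matrix(x)) return(fun(x))
  stopifnot(inherits(x, "ImageStack"))
  for (ch in seq_len(n_channels(x)))
    for (z in seq_len(n_planes(x)))
      for (t in seq_len(n_frames(x)))
        x <- set_stack_plane(x, fun(stack_plane(x, ch, z, t)), ch, z, t)
  add_provenance(x, op, params)
}

# Pull a (Y, X, T) array out of a movie-like input.
movie_frames <- function(stack, channel = 1L, z = 1L) {
  nt <- n_frames(stack)
  sapply(seq_len(nt), function(t) stack_plane(stack, channel, z, t),
         simplify = "array")
}

#' Estimate a flat-field (illumination) image from many frames
#'
#' Per-pixel median over frames, smoothed with a wide Gaussian (sigma = 10
#' percent of the image width) and normalized to mean 1. A simple,
#' documented estimator standing in for dedicated retrospective illumination
#' correction tools.
#'
#' @param stack an `ImageStack` with a T axis, or a (Y, X, T) array, with at
#'   least 20 frames.
#' @return flat-field matrix with mean 1.
#' @export
estimate_flat_field <- function(stack) {
  arr <- if (inherits(stack, "ImageStack")) movie_frames(stack) else stack
  stopifnot(length(dim(arr)) == 3)
  if (dim(arr)[3] < 20) stop("need at least 20 frames to estimate a flat field")
  med <- apply(arr, c(1, 2), median)
  sm <- blur_gaussian(med, 0.1 * ncol(med))
  sm / mean(sm)
}

#' Flat-field correction (pixelwise division)
#'
#' @param image matrix or `ImageStack`.
#' @param flat flat-field matrix, strictly positive, same (Y, X) size.
#' @return corrected image of the same type.
#' @export
flat_field_correct <- function(image, flat) {
  stopifnot(is.matrix(flat))
  if (any(flat <= 0)) stop("flat field must be positive everywhere")
  chk <- function(m) {
    if (!all(dim(m) == dim(flat))) stop("image / flat field shape mismatch")
    m / flat
  }
  map_planes(image, chk, "flat_field_correct")
}

#' Rolling-ball background subtraction
#'
#' Background is the grayscale opening of the image with a ball structuring
#' element of the given radius (the classic rolling-ball construction);
#' features narrower than the ball survive with their amplitude essentially
#' intact. By default the element is the flat disc (the unit ball of the
#' Euclidean metric), which preserves narrow peaks exactly; `spherical =
#' TRUE` uses a hemispherical height profile instead, whose curvature clips
#' diffraction-limited peaks and is kept only for comparison. Output is
#' clamped at zero.
#'
#' @param image matrix or `ImageStack`.
#' @param radius_px ball radius in pixels (>= 1 and smaller than the image).
#' @param spherical use the non-flat (hemisphere) element.
#' @param smooth_sigma if positive, the background is estimated on a
#'   Gaussian-smoothed copy (sigma in pixels) and subtracted from the
#'   original — the classic remedy against the downward bias of the
#'   min-statistic opening on shot noise.
#' @return background-subtracted image.
#' @export
subtract_background_rolling_ball <- function(image, radius_px,
                                             spherical = FALSE,
                                             smooth_sigma = 0) {
  if (radius_px < 1) stop("radius must be >= 1 px")
  dm <- if (is.matrix(image)) dim(image) else
    dim(image$pixels)[match(c("Y", "X"), image$axes)]
  if (radius_px >= min(dm)) stop("radius must be smaller than the image")
  el <- ball_element(radius_px, flat = !spherical)
  f <- function(m) {
    src <- if (smooth_sigma > 0) blur_gaussian(m, smooth_sigma) else m
    er <- cpp_morph(src, el$offsets, el$height, dilate = FALSE)
    bg <- cpp_morph(er, el$offsets, el$height, dilate = TRUE)
    pmax(m - bg, 0)
  }
  map_planes(image, f, "subtract_background_rolling_ball",
             list(radius_px = radius_px, smooth_sigma = smooth_sigma))
}

#' Band-pass filter (difference of Gaussians)
#'
#' `blur(low_sigma) - blur(high_sigma)`, clamped at zero: suppresses pixel
#' noise below `low_sigma` and background structure above `high_sigma`.
#'
#' @param image matrix or `ImageStack`.
#' @param low_sigma,high_sigma Gaussian sigmas in pixels, `low < high`.
#' @return filtered image.
#' @export
bandpass <- function(image, low_sigma = 1, high_sigma = 10) {
  if (!(low_sigma < high_sigma)) stop("low_sigma must be < high_sigma")
  f <- function(m) pmax(blur_gaussian(m, low_sigma) - blur_gaussian(m, high_sigma), 0)
  map_planes(image, f, "bandpass",
             list(low_sigma = low_sigma, high_sigma = high_sigma))
}

#' Photobleaching correction of a movie
#'
#' `"exponential"`: fits the frame means to `A * exp(-k t) + c` and divides
#' each frame by the fitted curve normalized to frame 0 (falling back to the
#' ratio method with a warning if the fit fails). `"ratio"`: divides each
#' frame by its mean over the frame-0 mean.
#'
#' @param stack `ImageStack` with a T axis and at least 5 frames.
#' @param method "exponential" (default) or "ratio".
#' @return corrected `ImageStack`.
#' @export
bleach_correct <- function(stack, method = c("exponential", "ratio")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "ImageStack"))
  nt <- n_frames(stack)
  if (nt < 5) stop("need at least 5 frames for bleach correction")
  for (ch in seq_len(n_channels(stack))) for (z in seq_len(n_planes(stack))) {
    fm <- vapply(seq_len(nt), function(t) mean(stack_plane(stack, ch, z, t)), 0)
    tt <- seq_len(nt) - 1
    fac <- NULL
    if (method == "exponential") {
      fit <- tryCatch(
        stats::nls(fm ~ SSasymp(tt, c0, A0, lrc)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        pred <- stats::predict(fit)
        if (all(is.finite(pred)) && all(pred > 0)) fac <- pred / pred[1]
      }
      if (is.null(fac)) {
        warning("exponential bleach fit failed; falling back to ratio method")
        fac <- fm / fm[1]
      }
    } else fac <- fm / fm[1]
    for (t in seq_len(nt))
      stack <- set_stack_plane(stack, stack_plane(stack, ch, z, t) / fac[t],
                               ch, z, t)
  }
  add_provenance(stack, "bleach_correct", list(method = method))
}

#' Channel registration from a bead image pair
#'
#' Localizes beads in both channels (detection + sub-pixel Gaussian fit),
#' matches them by mutual nearest neighbour, and reports the mean
#' localization difference as the channel offset, together with per-bead
#' residuals and a function that applies the correction to a stack plane.
#'
#' @param ref_beads,moving_beads single-plane `ImageStack`s or matrices of
#'   the same bead field in the two channels.
#' @param max_match_px maximal bead pairing distance.
#' @return list: `offset` c(dy, dx) such that `moving = ref + offset`,
#'   `residuals_px` per matched bead, `n_beads`, and `apply(image)` which
#'   shifts an image back by the offset.
#' @export
register_translation <- function(ref_beads, moving_beads, max_match_px = 10) {
  getm <- function(x) if (inherits(x, "ImageStack")) stack_plane(x) else x
  loc <- function(m) {
    cand <- detect_spots(m)
    sp <- localize_gaussian(m, cand)
    sp[sp$fit_ok, c("x_px", "y_px"), drop = FALSE]
  }
  a <- loc(getm(ref_beads)); b <- loc(getm(moving_beads))
  if (nrow(a) < 3 || nrow(b) < 3)
    stop("need at least 3 detectable beads in both channels")
  d <- outer(a$y_px, b$y_px, `-`)^2 + outer(a$x_px, b$x_px, `-`)^2
  fa <- max.col(-d, ties.method = "first")              # nearest b for each a
  fb <- max.col(-t(d), ties.method = "first")           # nearest a for each b
  mutual <- which(fb[fa] == seq_len(nrow(a)) &
                  sqrt(d[cbind(seq_len(nrow(a)), fa)]) <= max_match_px)
  if (length(mutual) < 3) stop("fewer than 3 mutually matched beads")
  dy <- b$y_px[fa[mutual]] - a$y_px[mutual]
  dx <- b$x_px[fa[mutual]] - a$x_px[mutual]
  off <- c(dy = mean(dy), dx = mean(dx))
  res <- sqrt((dy - off[1])^2 + (dx - off[2])^2)
  list(offset = off, residuals_px = res, n_beads = length(mutual),
       apply = function(image) shift_bilinear(image, -off[1], -off[2]))
}

# DFT frequency indices in fft output order, wrapped to signed values.
fft_freqs <- function(n) ((0:(n - 1) + floor(n / 2)) %% n) - floor(n / 2)

#' Sub-pixel shift between two images by phase cross-correlation
#'
#' Computes the normalized cross-power spectrum, locates the integer
#' correlation peak, then refines it by direct evaluation of the upsampled
#' discrete correlation around the peak.
#'
#' @param ref,moving numeric matrices of equal size.
#' @param upsample sub-pixel resolution is 1/upsample pixels.
#' @return c(dy, dx) such that `moving` is `ref` shifted by (dy, dx).
#' @export
phase_cross_correlation <- function(ref, moving, upsample = 20) {
  stopifnot(all(dim(ref) == dim(moving)))
  nr <- nrow(ref); nc <- ncol(ref)
  # Hann window suppresses the wrap-around discontinuity of the DFT
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  w <- outer(hann(nr), hann(nc))
  G <- fft((moving - mean(moving)) * w) * Conj(fft((ref - mean(ref)) * w))
  cc <- Re(fft(G, inverse = TRUE))
  p <- which.max(cc) - 1L
  py <- p %% nr; px <- p %/% nr
  s0 <- c(dy = ifelse(py > nr / 2, py - nr, py),
          dx = ifelse(px > nc / 2, px - nc, px))
  # upsampled correlation on a (3 px)^2 neighbourhood around the integer peak
  u <- upsample
  ng <- as.integer(3 * u)
  ry <- s0[1] - 1.5 + (0:(ng - 1)) / u
  rx <- s0[2] - 1.5 + (0:(ng - 1)) / u
  kr <- fft_freqs(nr); kc <- fft_freqs(nc)
  er <- exp(2i * pi * outer(ry, kr) / nr)           # ng x nr
  ec <- exp(2i * pi * outer(kc, rx) / nc)           # nc x ng
  cc_up <- Re(er %*% G %*% ec)
  b <- arrayInd(which.max(cc_up), dim(cc_up))
  c(dy = ry[b[1]], dx = rx[b[2]])
}

#' Drift correction of a movie against its first frame
#'
#' Per-frame (dy, dx) shifts are estimated by sub-pixel phase
#' cross-correlation against frame 0 and removed by bilinear interpolation.
#'
#' @param stack `ImageStack` with a T axis (>= 2 frames).
#' @param upsample sub-pixel upsampling factor.
#' @return list with `stack` (corrected) and `drift` (data.frame frame, dy,
#'   dx in pixels; first row zero).
#' @export
drift_correct <- function(stack, upsample = 20) {
  stopifnot(inherits(stack, "ImageStack"))
  nt <- n_frames(stack)
  if (nt < 2) stop("need at least 2 frames for drift correction")
  ref <- stack_plane(stack, 1, 1, 1)
  drift <- data.frame(frame = seq_len(nt), dy = 0, dx = 0)
  for (t in 2:nt) {
    cur <- stack_plane(stack, 1, 1, t)
    if (sd(cur) == 0 || sd(ref) == 0) {
      warning("empty frame; assuming zero shift")
      next
    }
    s <- phase_cross_correlation(ref, cur, upsample)
    drift$dy[t] <- s[1]; drift$dx[t] <- s[2]
    for (ch in seq_len(n_channels(stack))) for (z in seq_len(n_planes(stack)))
      stack <- set_stack_plane(
        stack, shift_bilinear(stack_plane(stack, ch, z, t), -s[1], -s[2]),
        ch, z, t)
  }
  list(stack = add_provenance(stack, "drift_correct", list(upsample = upsample)),
       drift = drift)
}

#' Walking (centred moving) average over time
#'
#' @param stack `ImageStack` with a T axis.
#' @param k odd window length; edges are truncated so the frame count is
#'   preserved.
#' @return averaged `ImageStack`.
#' @export
walking_average <- function(stack, k) {
  if (k < 1 || k %% 2 == 0) stop("k must be odd and >= 1")
  stopifnot(inherits(stack, "ImageStack"))
  if (k == 1) return(add_provenance(stack, "walking_average", list(k = 1)))
  nt <- n_frames(stack)
  h <- (k - 1) / 2
  out <- stack
  for (ch in seq_len(n_channels(stack))) for (z in seq_len(n_planes(stack))) {
    planes <- lapply(seq_len(nt), function(t) stack_plane(stack, ch, z, t))
    for (t in seq_len(nt)) {
      win <- max(1, t - h):min(nt, t + h)
      out <- set_stack_plane(out, Reduce(`+`, planes[win]) / length(win), ch, z, t)
    }
  }
  add_provenance(out, "walking_average", list(k = k))
}

#' Kymograph along a line
#'
#' Samples intensity along the segment between two endpoints (bilinear
#' interpolation, one sample per pixel of arc length) for every frame and
#' stacks the profiles as rows (time) by columns (position).
#'
#' @param movie `ImageStack` with a T axis.
#' @param line list or matrix with two endpoints in 0-based (x, y) pixels:
#'   `rbind(c(x0, y0), c(x1, y1))`.
#' @param channel channel to sample.
#' @return matrix (T rows, position columns).
#' @export
kymograph <- function(movie, line, channel = 1L) {
  stopifnot(inherits(movie, "ImageStack"))
  line <- as.matrix(line)
  stopifnot(all(dim(line) == c(2, 2)))
  len <- sqrt(sum((line[2, ] - line[1, ])^2))
  if (len <= 0) stop("degenerate line")
  nr <- axis_len(movie, "Y"); nc <- axis_len(movie, "X")
  if (any(line[, 1] < 0 | line[, 1] > nc - 1 | line[, 2] < 0 | line[, 2] > nr - 1))
    stop("line endpoints must lie inside the image")
  ns <- ceiling(len) + 1
  fr <- seq(0, 1, length.out = ns)
  xs <- line[1, 1] + fr * (line[2, 1] - line[1, 1])
  ys <- line[1, 2] + fr * (line[2, 2] - line[1, 2])
  nt <- n_frames(movie)
  out <- matrix(0, nt, ns)
  for (t in seq_len(nt)) {
    m <- stack_plane(movie, channel, 1, t)
    out[t, ] <- interp_bilinear(m, ys, xs)
  }
  out
}

# Bilinear interpolation of matrix m at 0-based (y, x) positions.
interp_bilinear <- function(m, y, x) {
  nr <- nrow(m); nc <- ncol(m)
  y0 <- pmin(pmax(floor(y), 0), nr - 1); x0 <- pmin(pmax(floor(x), 0), nc - 1)
  y1 <- pmin(y0 + 1, nr - 1); x1 <- pmin(x0 + 1, nc - 1)
  fy <- pmin(pmax(y - y0, 0), 1); fx <- pmin(pmax(x - x0, 0), 1)
  m[cbind(y0 + 1, x0 + 1)] * (1 - fy) * (1 - fx) +
    m[cbind(y1 + 1, x0 + 1)] * fy * (1 - fx) +
    m[cbind(y0 + 1, x1 + 1)] * (1 - fy) * fx +
    m[cbind(y1 + 1, x1 + 1)] * fy * fx
}
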