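# Condensate segmentation and single-molecule spot detection/localization.

#' Segment condensates in a 2D image
#'
#' Blur, rolling-ball background subtraction and thresholding followed by
#' 4-connected component labeling. Integrated intensities are computed on the
#' original (unfiltered) image within each mask, so the sum of member-region
#' intensities equals the masked image sum exactly.
#'
#' @param image numeric (Y, X) matrix (one plane).
#' @param blur_sigma Gaussian sigma for the detection blur (pixels).
#' @param bg_radius rolling-ball radius (pixels).
#' @param threshold `"otsu"`, `"mad"` (median + `mad_k` robust deviations of
#'   the processed image — the choice for sparse objects on a noisy
#'   background, where Otsu's bimodality assumption fails), or an absolute
#'   intensity value applied to the processed image.
#' @param mad_k robust threshold factor for `threshold = "mad"`.
#' @param min_area_px components smaller than this are dropped.
#' @return data.frame of class `CondensateRegions` with columns label, x, y
#'   (intensity-weighted centroid, 0-based), area_px, integrated_intensity;
#'   per-region pixel indices in `attr(, "pixels")`; the label image in
#'   `attr(, "labels")`.
#' @export
segment_condensates <- function(image, blur_sigma = 1.5, bg_radius = 8,
                                threshold = "otsu", mad_k = 8, min_area_px = 4) {
  stopifnot(is.matrix(image))
  proc <- blur_gaussian(image, blur_sigma)
  proc <- subtract_background_rolling_ball(proc, bg_radius)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(proc)
    else if (identical(threshold, "mad")) median(proc) + mad_k * mad(proc)
    else as.numeric(threshold)
  mask <- proc > thr
  empty <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area_px = integer(0), integrated_intensity = numeric(0))
  class(empty) <- c("CondensateRegions", "data.frame")
  if (!any(mask)) return(empty)
  lab <- cpp_label4(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_area_px)
  if (!length(keep)) return(empty)
  nr <- nrow(image)
  pix <- lapply(keep, function(k) which(lab == k))
  rows <- lapply(seq_along(keep), function(i) {
    p <- pix[[i]]
    ii <- (p - 1) %% nr          # 0-based row (y)
    jj <- (p - 1) %/% nr         # 0-based col (x)
    w <- image[p]
    sw <- sum(w)
    data.frame(label = i,
               x = if (sw > 0) sum(jj * w) / sw else mean(jj),
               y = if (sw > 0) sum(ii * w) / sw else mean(ii),
               area_px = length(p),
               integrated_intensity = sum(w))
  })
  out <- do.call(rbind, rows)
  attr(out, "pixels") <- pix
  attr(out, "labels") <- lab
  class(out) <- c("CondensateRegions", "data.frame")
  out
}

#' Integrated intensity of existing regions in another channel
#'
#' @param regions a `CondensateRegions` result.
#' @param image a registered image of the same size the regions came from.
#' @return numeric vector of per-region integrated intensities.
#' @export
region_intensity <- function(regions, image) {
  pix <- attr(regions, "pixels")
  vapply(pix, function(p) sum(image[p]), 0)
}

#' Detect spot candidates
#'
#' Band-passes the image, then keeps 8-neighbourhood local maxima above
#' `median + k * MAD` of the filtered image, with a minimum separation of
#' 2 px (the brighter candidate wins).
#'
#' @param image numeric (Y, X) matrix.
#' @param low_sigma,high_sigma band-pass sigmas (pixels).
#' @param k robust threshold factor (> 0); default 5.
#' @param min_sep minimum candidate separation in pixels.
#' @return data.frame with 0-based integer columns x, y and the filtered
#'   value.
#' @export
detect_spots <- function(image, low_sigma = 1, high_sigma = 3, k = 5,
                         min_sep = 2) {
  stopifnot(k > 0)
  # unclamped difference of Gaussians: clamping would zero out the lower half
  # of the distribution and collapse the MAD
  bp <- blur_gaussian(image, low_sigma) - blur_gaussian(image, high_sigma)
  thr <- median(bp) + k * mad(bp)
  # the relative floor guards against numeric dust on noise-free images
  cand <- which(local_maxima8(bp) & bp > thr & bp > 1e-9 * max(abs(bp)))
  if (!length(cand))
    return(data.frame(x = integer(0), y = integer(0), value = numeric(0)))
  nr <- nrow(image)
  df <- data.frame(x = (cand - 1) %/% nr, y = (cand - 1) %% nr,
                   value = bp[cand])
  df <- df[order(-df$value), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(df)) > i)
    if (!length(later)) break
    d2 <- (df$x[later] - df$x[i])^2 + (df$y[later] - df$y[i])^2
    keep[later[d2 < min_sep^2]] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Damped Gauss-Newton least-squares fit of a 2D Gaussian + offset to a square
# window. Returns parameters and a convergence flag.
fit_gauss2d <- function(w) {
  n <- nrow(w)
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE)
  ys <- matrix(0:(n - 1), n, n)
  b <- min(w); A <- max(w) - b
  wp <- pmax(w - b, 0); tw <- sum(wp)
  x0 <- if (tw > 0) sum(xs * wp) / tw else (n - 1) / 2
  y0 <- if (tw > 0) sum(ys * wp) / tw else (n - 1) / 2
  s <- 1.3
  th <- c(A = A, x0 = x0, y0 = y0, s = s, b = b)
  v <- as.vector(w)
  sse_of <- function(th) {
    g <- exp(-((as.vector(xs) - th[2])^2 + (as.vector(ys) - th[3])^2) / (2 * th[4]^2))
    sum((th[1] * g + th[5] - v)^2)
  }
  lambda <- 1e-3
  sse <- sse_of(th)
  conv <- FALSE
  for (it in 1:60) {
    dx <- as.vector(xs) - th[2]; dy <- as.vector(ys) - th[3]
    g <- exp(-(dx^2 + dy^2) / (2 * th[4]^2))
    r <- th[1] * g + th[5] - v
    J <- cbind(g,
               th[1] * g * dx / th[4]^2,
               th[1] * g * dy / th[4]^2,
               th[1] * g * (dx^2 + dy^2) / th[4]^3,
               1)
    JtJ <- crossprod(J); Jtr <- crossprod(J, r)
    ok <- FALSE
    for (tr in 1:8) {
      step <- tryCatch(solve(JtJ + lambda * diag(diag(JtJ) + 1e-12), -Jtr),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      thn <- th + as.vector(step)
      thn[4] <- max(thn[4], 0.1)
      ssen <- sse_of(thn)
      if (is.finite(ssen) && ssen <= sse) {
        th <- thn; sse <- ssen; lambda <- max(lambda / 3, 1e-9); ok <- TRUE
        if (max(abs(step[2:3])) < 1e-5) conv <- TRUE
        break
      }
      lambda <- lambda * 5
    }
    if (!ok || conv) break
  }
  list(amplitude = unname(th[1]), x = unname(th[2]), y = unname(th[3]),
       sigma = unname(th[4]), offset = unname(th[5]), converged = conv || sse < 1e-20)
}

#' Sub-pixel localization by 2D Gaussian least squares
#'
#' Fits amplitude, centre, width and offset of an isotropic 2D Gaussian on a
#' square window around each candidate. `fit_ok` is `FALSE` when the fit does
#' not converge, the width leaves `sigma_bounds`, or the amplitude is not
#' positive; candidates whose window leaves the image are skipped with
#' `fit_ok = FALSE` and `edge = TRUE`.
#'
#' @param image numeric (Y, X) matrix.
#' @param candidates data.frame with 0-based integer x, y (from
#'   [detect_spots()]).
#' @param window odd window size >= 7.
#' @param sigma_bounds allowed fitted sigma range (pixels).
#' @return data.frame of class `Spots`: x_px, y_px, amplitude, sigma_px,
#'   offset, fit_ok, edge.
#' @export
localize_gaussian <- function(image, candidates, window = 9,
                              sigma_bounds = c(0.5, 4)) {
  if (window %% 2 == 0 || window < 7) stop("window must be odd and >= 7")
  h <- (window - 1) / 2
  nr <- nrow(image); nc <- ncol(image)
  n <- nrow(candidates)
  out <- data.frame(x_px = rep(NA_real_, n), y_px = NA_real_,
                    amplitude = NA_real_, sigma_px = NA_real_,
                    offset = NA_real_, fit_ok = FALSE, edge = FALSE)
  for (i in seq_len(n)) {
    cx <- candidates$x[i]; cy <- candidates$y[i]
    if (cx - h < 0 || cx + h > nc - 1 || cy - h < 0 || cy + h > nr - 1) {
      out$edge[i] <- TRUE
      next
    }
    w <- image[(cy - h):(cy + h) + 1, (cx - h):(cx + h) + 1]
    f <- fit_gauss2d(w)
    out$x_px[i] <- cx - h + f$x
    out$y_px[i] <- cy - h + f$y
    out$amplitude[i] <- f$amplitude
    out$sigma_px[i] <- f$sigma
    out$offset[i] <- f$offset
    out$fit_ok[i] <- isTRUE(f$converged) && f$amplitude > 0 &&
      f$sigma >= sigma_bounds[1] && f$sigma <= sigma_bounds[2] &&
      f$x >= 0 && f$x <= window - 1 && f$y >= 0 && f$y <= window - 1
  }
  class(out) <- c("Spots", "data.frame")
  out
}

#' Max-minus-min spot amplitude in a blurred window
#'
#' The image is Gaussian-blurred (sigma 1 by default), then each spot's
#' amplitude is the maximum minus the minimum pixel value in the
#' `window x window` region centred on its rounded position (edge-clipped
#' windows are flagged). When several spots fall in one window the amplitude
#' reflects the brighter peak — a documented bias of this estimator.
#'
#' @param image numeric (Y, X) matrix.
#' @param x,y spot positions, 0-based pixels (rounded internally).
#' @param blur_sigma blur before measurement.
#' @param window odd window size (9 by default, i.e. 81 pixels).
#' @return numeric amplitudes, with attribute `clipped` marking edge windows.
#' @export
amplitude_maxmin <- function(image, x, y, blur_sigma = 1, window = 9) {
  stopifnot(length(x) == length(y))
  bl <- blur_gaussian(image, blur_sigma)
  h <- (window - 1) / 2
  nr <- nrow(bl); nc <- ncol(bl)
  amp <- numeric(length(x)); clipped <- logical(length(x))
  for (i in seq_along(x)) {
    cx <- round(x[i]); cy <- round(y[i])
    j0 <- max(0, cx - h); j1 <- min(nc - 1, cx + h)
    i0 <- max(0, cy - h); i1 <- min(nr - 1, cy + h)
    clipped[i] <- (j1 - j0 + 1 < window) || (i1 - i0 + 1 < window)
    w <- bl[(i0:i1) + 1, (j0:j1) + 1]
    amp[i] <- max(w) - min(w)
  }
  attr(amp, "clipped") <- clipped
  amp
}

#' Collapse per-plane spots into 3D spots
#'
#' Links spots across adjacent z planes by nearest neighbour within
#' `max_xy_link_px`, then collapses each chain to the plane of maximal
#' amplitude (ties broken toward the lower plane index).
#'
#' @param spot_planes list of per-plane data.frames with x_px, y_px,
#'   amplitude (plane order = list order).
#' @param max_xy_link_px link radius between adjacent planes.
#' @return data.frame: x_px, y_px, z_index (1-based plane), amplitude,
#'   chain_len, plus any other columns from the winning plane's row.
#' @export
assign_z <- function(spot_planes, max_xy_link_px = 2) {
  nz <- length(spot_planes)
  chains <- list()   # each: list(rows = data.frame with z, last_x, last_y, last_z)
  open_idx <- integer(0)
  for (z in seq_len(nz)) {
    df <- spot_planes[[z]]
    if (is.null(df) || nrow(df) == 0) { open_idx <- integer(0); next }
    df$z <- z
    used <- rep(FALSE, nrow(df))
    # match open chains (last plane z-1) to this plane's spots
    if (length(open_idx)) {
      lastx <- vapply(chains[open_idx], function(ch) tail(ch$x_px, 1), 0)
      lasty <- vapply(chains[open_idx], function(ch) tail(ch$y_px, 1), 0)
      pairs <- expand.grid(ci = seq_along(open_idx), si = seq_len(nrow(df)))
      pairs$d <- sqrt((lastx[pairs$ci] - df$x_px[pairs$si])^2 +
                      (lasty[pairs$ci] - df$y_px[pairs$si])^2)
      pairs <- pairs[pairs$d <= max_xy_link_px, , drop = FALSE]
      pairs <- pairs[order(pairs$d), , drop = FALSE]
      cdone <- rep(FALSE, length(open_idx))
      for (r in seq_len(nrow(pairs))) {
        ci <- pairs$ci[r]; si <- pairs$si[r]
        if (cdone[ci] || used[si]) next
        cdone[ci] <- TRUE; used[si] <- TRUE
        k <- open_idx[ci]
        chains[[k]] <- rbind(chains[[k]], df[si, , drop = FALSE])
      }
      open_idx <- open_idx[cdone]
      # chains extended into this plane stay open
      open_idx <- open_idx
    }
    for (si in which(!used)) {
      chains[[length(chains) + 1L]] <- df[si, , drop = FALSE]
      open_idx <- c(open_idx, length(chains))
    }
    # keep only chains whose last plane is z open for the next plane
    lastz <- vapply(chains, function(ch) tail(ch$z, 1), 0)
    open_idx <- which(lastz == z)
  }
  if (!length(chains))
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      z_index = integer(0), amplitude = numeric(0),
                      chain_len = integer(0)))
  rows <- lapply(chains, function(ch) {
    best <- which(ch$amplitude == max(ch$amplitude))[1]  # tie -> lower plane
    r <- ch[best, , drop = FALSE]
    r$z_index <- as.integer(r$z); r$z <- NULL
    r$chain_len <- nrow(ch)
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-frame total condensate intensity of a movie
#'
#' Segments every frame and sums the integrated intensities of all regions.
#'
#' @param movie `ImageStack` with a T axis.
#' @param channel channel to analyse.
#' @param ... passed to [segment_condensates()].
#' @return data.frame (frame, total_intensity, n_regions).
#' @export
condensate_intensity_timecourse <- function(movie, channel = 1L, ...) {
  stopifnot(inherits(movie, "ImageStack"))
  nt <- n_frames(movie)
  res <- lapply(seq_len(nt), function(t) {
    reg <- segment_condensates(stack_plane(movie, channel, 1, t), ...)
    data.frame(frame = t, total_intensity = sum(reg$integrated_intensity),
               n_regions = nrow(reg))
  })
  do.call(rbind, res)
}

#' Segment condensates across a z stack into 3D objects
#'
#' Runs 2D segmentation per plane and links region centroids across adjacent
#' planes (same rule as [assign_z()]); each linked object is reported at its
#' brightest plane.
#'
#' @param stack `ImageStack` with a Z axis (single channel index given).
#' @param channel channel to segment.
#' @param max_xy_link_px centroid link radius between planes.
#' @param threshold thresholding rule (default the robust `"mad"` rule; see
#'   [segment_condensates()]).
#' @param ... passed to [segment_condensates()].
#' @return data.frame: x, y, z_index, area_px, integrated_intensity,
#'   chain_len.
#' @export
condensates_3d <- function(stack, channel = 1L, max_xy_link_px = 3,
                           threshold = "mad", ...) {
  stopifnot(inherits(stack, "ImageStack"))
  nz <- n_planes(stack)
  per_plane <- lapply(seq_len(nz), function(z) {
    reg <- segment_condensates(stack_plane(stack, channel, z, 1),
                               threshold = threshold, ...)
    if (!nrow(reg)) return(data.frame(x_px = numeric(0), y_px = numeric(0),
                                      amplitude = numeric(0),
                                      area_px = integer(0)))
    data.frame(x_px = reg$x, y_px = reg$y, amplitude = reg$integrated_intensity,
               area_px = reg$area_px)
  })
  res <- assign_z(per_plane, max_xy_link_px = max_xy_link_px)
  if (!nrow(res))
    return(data.frame(x = numeric(0), y = numeric(0), z_index = integer(0),
                      integrated_intensity = numeric(0), chain_len = integer(0)))
  data.frame(x = res$x_px, y = res$y_px, z_index = res$z_index,
             area_px = res$area_px, integrated_intensity = res$amplitude,
             chain_len = res$chain_len)
}
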