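# Functional readouts: reporter decay, FRAP, half-life, spine volumes,
# nascent-protein assays, and the two-sample t test used for significance.

#' Normalize reporter traces to each cell's initial value
#'
#' @param traces data.frame (cell, t_h, value), at least 2 time points per
#'   cell. Cells with a zero/non-finite initial value are excluded with a
#'   warning.
#' @return list with `traces` (normalized) and `endpoint` (mean, sd, n and
#'   the per-cell values at the final common time).
#' @export
reporter_normalize <- function(traces) {
  out <- lapply(split(traces, traces$cell), function(df) {
    df <- df[order(df$t_h), ]
    if (nrow(df) < 2) stop("need at least 2 time points per cell")
    v0 <- df$value[df$t_h == min(df$t_h)][1]
    if (!is.finite(v0) || v0 == 0) return(NULL)
    df$value <- df$value / v0
    df
  })
  dropped <- sum(vapply(out, is.null, TRUE))
  if (dropped > 0) warning(dropped, " cell(s) excluded (zero initial value)")
  norm <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(norm) <- NULL
  tend <- max(norm$t_h)
  ev <- norm$value[norm$t_h == tend]
  list(traces = norm,
       endpoint = list(t_h = tend, mean = mean(ev), sd = sd(ev),
                       n = length(ev), values = ev))
}

#' Bin per-cell endpoints by expression level
#'
#' Half-open bins `[lo, hi)`; cells outside the edge range are excluded and
#' counted.
#'
#' @param cells data.frame with `expression` and `endpoint`.
#' @param bin_edges increasing numeric edges (default 0,100,...,400).
#' @return list with `bins` (data.frame lo, hi, n, mean, sd; `NA` statistics
#'   for empty bins) and `n_excluded`.
#' @export
bin_by_expression <- function(cells, bin_edges = c(0, 100, 200, 300, 400)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin edges must increase")
  idx <- findInterval(cells$expression, bin_edges, left.open = FALSE)
  inside <- idx >= 1 & cells$expression < tail(bin_edges, 1)
  nb <- length(bin_edges) - 1
  bins <- do.call(rbind, lapply(seq_len(nb), function(b) {
    v <- cells$endpoint[inside & idx == b]
    data.frame(lo = bin_edges[b], hi = bin_edges[b + 1], n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_)
  }))
  list(bins = bins, n_excluded = sum(!inside))
}

#' Exponential half-life fit
#'
#' Fits `A * exp(-k t)` (or `A * exp(-k t) + c` with `floor = TRUE`) to a
#' decaying trace and reports `t_half = ln 2 / k`.
#'
#' @param trace data.frame (t_h, value), at least 5 points, decaying.
#' @param floor include an additive plateau (maturation/background).
#' @return list (t_half_h, k_per_h, floor, fitted).
#' @export
fit_half_life <- function(trace, floor = FALSE) {
  stopifnot(nrow(trace) >= 5)
  trace <- trace[order(trace$t_h), ]
  if (tail(trace$value, 1) >= trace$value[1])
    stop("trace is not decaying; cannot fit a half-life")
  if (!floor) {
    if (any(trace$value <= 0)) stop("non-positive values; use floor = TRUE")
    fit <- lm(log(value) ~ t_h, data = trace)
    k <- -unname(coef(fit)[2])
    if (k <= 0) stop("fitted rate is not positive")
    return(list(t_half_h = log(2) / k, k_per_h = k, floor = 0,
                fitted = exp(stats::fitted(fit))))
  }
  # profile the floor: for a fixed floor the model is log-linear
  v <- trace$value; tt <- trace$t_h
  fit_at <- function(c0) {
    y <- v - c0
    if (any(y <= 0)) return(list(sse = Inf))
    f <- lm(log(y) ~ tt)
    k <- -unname(coef(f)[2])
    if (!is.finite(k) || k <= 0) return(list(sse = Inf))
    A <- exp(unname(coef(f)[1]))
    list(sse = sum((A * exp(-k * tt) + c0 - v)^2), k = k, A = A, c0 = c0)
  }
  upper <- min(v) - 1e-9 * diff(range(v))
  opt <- optimize(function(c0) fit_at(c0)$sse, c(0, max(upper, 1e-12)))
  best <- fit_at(opt$minimum)
  if (!is.finite(best$sse)) best <- fit_at(0)
  if (!is.finite(best$sse)) stop("floor-aware exponential fit failed")
  list(t_half_h = log(2) / best$k, k_per_h = best$k, floor = best$c0,
       fitted = best$A * exp(-best$k * tt) + best$c0)
}

#' Mobile fraction and recovery time from a FRAP trace
#'
#' Normalizes the post-bleach signal as
#' `I_n(t) = (I(t) - I(0+)) / (mean(I_pre) - I(0+))` with time measured from
#' the bleach, fits `M * (1 - exp(-t / tau))`, and reports the mobile
#' fraction M (clipped to [0, 1.05] with a flag) and `1 - M` as the immobile
#' fraction.
#'
#' @param trace a `FRAPTrace` (see [make_frap_trace()]) or a list with
#'   `times`, `values`, `pre_frames`.
#' @param double_normalize also divide the pre-bleach trace by its mean
#'   before normalizing (for drifting acquisitions).
#' @return list (mobile_fraction, immobile_fraction, tau_s, clipped,
#'   normalized data.frame).
#' @export
frap_analyze <- function(trace, double_normalize = FALSE) {
  pre <- seq_len(trace$pre_frames)
  v <- trace$values
  if (double_normalize) v <- v / mean(v[pre])
  ipre <- mean(v[pre])
  post <- (trace$pre_frames + 1):length(v)
  i0 <- v[post[1]]
  if (ipre <= i0) stop("no bleach detected (pre-bleach mean <= first post value)")
  tt <- trace$times[post] - trace$times[post[1]]
  yn <- (v[post] - i0) / (ipre - i0)
  sse <- function(log_tau) {
    g <- 1 - exp(-tt / exp(log_tau))
    m <- sum(g * yn) / sum(g * g)
    sum((m * g - yn)^2)
  }
  span <- range(tt[tt > 0])
  opt <- optimize(sse, c(log(span[1] / 10), log(span[2] * 10)))
  tau <- exp(opt$minimum)
  g <- 1 - exp(-tt / tau)
  m <- sum(g * yn) / sum(g * g)
  clipped <- m < 0 || m > 1.05
  m <- min(max(m, 0), 1.05)
  list(mobile_fraction = m, immobile_fraction = 1 - m, tau_s = tau,
       clipped = clipped,
       normalized = data.frame(t_s = tt, value = yn, fitted = m * g))
}

#' Phansalkar local threshold
#'
#' `t = m * (1 + p * exp(-q m) + k * (s/r - 1))` on the image normalized to
#' [0, 1] by its maximum, with local mean m and standard deviation s over a
#' square window. Designed for bright structures on a near-zero background
#' (background-subtract first). An all-non-positive image yields no
#' foreground.
#'
#' @param image numeric (Y, X) matrix.
#' @param window odd window size (default 15).
#' @param k,r,p,q method parameters (defaults 0.25, 0.5, 2, 10).
#' @param scale_max intensity mapped to 1; defaults to `max(image)`. Pass a
#'   global (stack-wide) maximum when thresholding sub-images so that empty
#'   regions do not rescale their own noise.
#' @return logical foreground matrix.
#' @export
threshold_phansalkar <- function(image, window = 15, k = 0.25, r = 0.5,
                                 p = 2, q = 10, scale_max = max(image)) {
  mx <- scale_max
  if (mx <= 0) return(matrix(FALSE, nrow(image), ncol(image)))
  img <- pmin(image / mx, 1)
  ms <- cpp_local_mean_sd(img, as.integer((window - 1) / 2))
  thr <- ms$mean * (1 + p * exp(-q * ms$mean) + k * (ms$sd / r - 1))
  img > thr
}

#' Standard spine-stack preprocessing
#'
#' The chain applied before [spine_volume()]: per plane, a 3x3 median filter
#' (shot-noise suppression) followed by flat rolling-ball background
#' subtraction. Flat-field, drift and bleach corrections, when needed, should
#' run before this.
#'
#' @param stack `ImageStack` with axes Y, X, Z, T.
#' @param bg_radius rolling-ball radius (pixels).
#' @return preprocessed `ImageStack`.
#' @export
spine_preprocess <- function(stack, bg_radius = 15) {
  stopifnot(inherits(stack, "ImageStack"))
  for (t in seq_len(n_frames(stack))) for (z in seq_len(n_planes(stack))) {
    pl <- median_filter3(stack_plane(stack, 1, z, t))
    stack <- set_stack_plane(
      stack, subtract_background_rolling_ball(pl, bg_radius), 1, z, t)
  }
  add_provenance(stack, "spine_preprocess", list(bg_radius = bg_radius))
}

#' Per-spine, per-time volumes from a z-stack series
#'
#' Within each ROI box, every z slice is binarized with the Phansalkar local
#' threshold and the foreground voxels are summed. Assumes preprocessing
#' (flat-field, drift, bleach, background subtraction) was applied upstream.
#'
#' @param stack `ImageStack` with axes Y, X, Z, T.
#' @param roi_boxes data.frame with 0-based inclusive y0, y1, x0, x1 (one row
#'   per spine).
#' @param window,k,r Phansalkar parameters.
#' @return list with `volumes_vox` (T x spine matrix) and `volumes_um3`
#'   (using pixel size and z step when available).
#' @export
spine_volume <- function(stack, roi_boxes, window = 15, k = 0.25, r = 0.5) {
  stopifnot(inherits(stack, "ImageStack"), nrow(roi_boxes) >= 1)
  nr <- axis_len(stack, "Y"); nc <- axis_len(stack, "X")
  if (any(roi_boxes$y0 < 0 | roi_boxes$y1 > nr - 1 |
          roi_boxes$x0 < 0 | roi_boxes$x1 > nc - 1 |
          roi_boxes$y1 < roi_boxes$y0 | roi_boxes$x1 < roi_boxes$x0))
    stop("ROI boxes must be non-empty and inside the stack")
  nt <- n_frames(stack); nz <- n_planes(stack)
  gmax <- max(stack$pixels)
  vols <- matrix(0, nt, nrow(roi_boxes))
  for (t in seq_len(nt)) for (z in seq_len(nz)) {
    pl <- stack_plane(stack, 1, z, t)
    for (s in seq_len(nrow(roi_boxes))) {
      sub <- pl[(roi_boxes$y0[s]:roi_boxes$y1[s]) + 1,
                (roi_boxes$x0[s]:roi_boxes$x1[s]) + 1, drop = FALSE]
      vols[t, s] <- vols[t, s] +
        sum(threshold_phansalkar(sub, window, k, r, scale_max = gmax))
    }
  }
  um3 <- NULL
  if (!is.null(stack$pixel_size_nm) && !is.null(stack$z_step_um))
    um3 <- vols * (stack$pixel_size_nm / 1000)^2 * stack$z_step_um
  list(volumes_vox = vols, volumes_um3 = um3)
}

#' Normalized spine-volume change and group summary
#'
#' Each spine is normalized by the mean of its baseline volumes; spines with
#' a zero baseline are excluded. The group trace is mean +/- s.e.m. per time
#' point.
#'
#' @param volumes T x spine matrix of volumes.
#' @param baseline_frames number of pre-stimulation time points (>= 3).
#' @return list: `normalized` (T x spine), `mean`, `sem`, `n` per time
#'   point, `excluded` spine indices.
#' @export
spine_change <- function(volumes, baseline_frames = 3) {
  stopifnot(baseline_frames >= 3, nrow(volumes) >= baseline_frames)
  base <- colMeans(volumes[seq_len(baseline_frames), , drop = FALSE])
  excl <- which(base <= 0)
  keep <- base > 0
  norm <- sweep(volumes[, keep, drop = FALSE], 2, base[keep], `/`)
  list(normalized = norm,
       mean = rowMeans(norm),
       sem = apply(norm, 1, sd) / sqrt(ncol(norm)),
       n = ncol(norm), excluded = excl)
}

#' Per-cell nascent-protein (OP-Puro) intensity
#'
#' Nuclei are detected on a maximum-z projection of the nuclear channel
#' (blur, rolling-ball background subtraction, Otsu threshold, distance-
#' transform marker split of touching nuclei, size filter); for each nucleus
#' mask the mean OPP intensity is measured on every z slice and the maximum
#' over z is reported.
#'
#' @param opp_stack (Y, X, Z) array (or matrix) of the OPP channel.
#' @param nuclei_stack (Y, X, Z) array (or matrix) of the nuclear channel.
#' @param blur_sigma,bg_radius,min_area nucleus detection parameters.
#' @param marker_min_dist minimal distance-transform peak separation used to
#'   split touching nuclei (pixels).
#' @return data.frame (cell, opp_intensity, area_px); empty when no nuclei
#'   are found.
#' @export
oppuro_cell_intensity <- function(opp_stack, nuclei_stack, blur_sigma = 2,
                                  bg_radius = 20, min_area = 50,
                                  marker_min_dist = 6) {
  as3 <- function(a) if (is.matrix(a)) array(a, c(dim(a), 1)) else a
  opp <- as3(opp_stack); nuc <- as3(nuclei_stack)
  proj <- apply(nuc, c(1, 2), max)
  proc <- subtract_background_rolling_ball(blur_gaussian(proj, blur_sigma), bg_radius)
  mask <- proc > otsu_threshold(proc)
  if (!any(mask)) return(data.frame(cell = integer(0), opp_intensity = numeric(0),
                                    area_px = integer(0)))
  # split touching nuclei: distance-transform peaks as markers, pixels
  # assigned to the nearest marker
  edt <- cpp_edt(mask)
  sm <- blur_gaussian(edt, 2)
  pk <- which(local_maxima8(sm) & mask & edt > 2)
  nr <- nrow(mask)
  py <- (pk - 1) %% nr; px <- (pk - 1) %/% nr
  ord <- order(-sm[pk])
  keep <- logical(length(pk))
  for (i in ord) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (py[keep] - py[i])^2 + (px[keep] - px[i])^2
    if (min(d2) >= marker_min_dist^2) keep[i] <- TRUE
  }
  py <- py[keep]; px <- px[keep]
  lab <- cpp_label4(mask)
  fg <- which(mask)
  fy <- (fg - 1) %% nr; fx <- (fg - 1) %/% nr
  if (length(py) > 1) {
    d2m <- outer(fy, py, `-`)^2 + outer(fx, px, `-`)^2
    assign <- max.col(-d2m, ties.method = "first")
    lab[fg] <- assign
  }
  ids <- sort(unique(lab[lab > 0]))
  nz <- dim(opp)[3]
  rows <- lapply(seq_along(ids), function(i) {
    sel <- lab == ids[i]
    if (sum(sel) < min_area) return(NULL)
    per_z <- vapply(seq_len(nz), function(z) mean(opp[, , z][sel]), 0)
    data.frame(cell = i, opp_intensity = max(per_z), area_px = sum(sel))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(cell = integer(0),
                                      opp_intensity = numeric(0),
                                      area_px = integer(0))
  out
}

#' Per-cell proximity-ligation puncta counts
#'
#' Detects puncta on every z plane, deduplicates them in 3D ([assign_z()]),
#' and assigns each punctum to the cell mask containing its rounded centroid.
#'
#' @param stack (Y, X, Z) array of the puncta channel.
#' @param cell_masks integer-labeled (Y, X) matrix of disjoint cell masks.
#' @param k detection threshold factor.
#' @param ... further [detect_spots()] parameters.
#' @return data.frame (cell, n_puncta) covering every label in `cell_masks`.
#' @export
pla_count <- function(stack, cell_masks, k = 5, ...) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  nz <- dim(stack)[3]
  planes <- lapply(seq_len(nz), function(z) {
    cand <- detect_spots(stack[, , z], k = k, ...)
    if (!nrow(cand)) return(data.frame(x_px = numeric(0), y_px = numeric(0),
                                       amplitude = numeric(0)))
    data.frame(x_px = cand$x, y_px = cand$y, amplitude = cand$value)
  })
  sp <- assign_z(planes)
  ids <- sort(unique(cell_masks[cell_masks > 0]))
  counts <- setNames(integer(length(ids)), ids)
  if (nrow(sp)) {
    li <- cell_masks[cbind(round(sp$y_px) + 1, round(sp$x_px) + 1)]
    tb <- table(li[li > 0])
    counts[names(tb)] <- as.integer(tb)
  }
  data.frame(cell = ids, n_puncta = as.integer(counts))
}

#' Two-tailed two-sample t test
#'
#' Pooled-variance Student's test by default (Welch optional); identical
#' constant samples return t = 0, p = 1 by convention.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param equal_var pooled variance (Student) if `TRUE`, Welch otherwise.
#' @return list (t, df, p).
#' @export
ttest_two_tailed <- function(sample_a, sample_b, equal_var = TRUE) {
  na <- length(sample_a); nb <- length(sample_b)
  stopifnot(na >= 2, nb >= 2)
  ma <- mean(sample_a); mb <- mean(sample_b)
  va <- var(sample_a); vb <- var(sample_b)
  if (va == 0 && vb == 0) {
    if (ma == mb) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(ma - mb) * Inf, df = na + nb - 2, p = 0))
  }
  if (equal_var) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    tt <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}
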