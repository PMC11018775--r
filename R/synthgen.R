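# Synthetic scene generation. Every generator takes an explicit seed and
# routes all randomness through one RNG scope, so identical seed + config
# reproduce bit-identical output. Spots are rendered as point-sampled
# Gaussians (PSF model: isotropic 2D Gaussian per z slice with a Gaussian
# amplitude envelope along z), matching the localization model exactly so
# that estimator bias can be measured against a known truth.

#' Optics configuration
#'
#' Physical imaging parameters shared by the generators and by any
#' unit-bearing analysis step.
#'
#' @param pixel_size_nm camera pixel size (nm/pixel). Default 110 nm, the
#'   value implied by a 330 nm ~ 3 pixel correspondence on a typical EMCCD
#'   with a 150x objective.
#' @param z_step_um axial step between z planes (micrometres); default 0.5.
#' @param psf_sigma_nm lateral Gaussian PSF sigma (nm); default 130.
#' @param frame_interval_s time between frames (seconds); default 0.05 (20 Hz).
#' @param channel_offset_px 2-vector (dy, dx) misregistration applied to the
#'   second channel.
#' @param psf_sigma_z_um axial amplitude-envelope sigma (micrometres).
#' @return list of class `OpticsConfig`.
#' @export
optics_config <- function(pixel_size_nm = 110, z_step_um = 0.5,
                          psf_sigma_nm = 130, frame_interval_s = 0.05,
                          channel_offset_px = c(0, 0), psf_sigma_z_um = 0.4) {
  stopifnot(pixel_size_nm > 0, z_step_um > 0, psf_sigma_nm > 0,
            frame_interval_s > 0, psf_sigma_z_um > 0,
            length(channel_offset_px) == 2)
  if (psf_sigma_nm < pixel_size_nm / 4)
    stop("psf_sigma_nm must be at least pixel_size_nm / 4 (undersampled PSF)")
  structure(list(pixel_size_nm = pixel_size_nm, z_step_um = z_step_um,
                 psf_sigma_nm = psf_sigma_nm, frame_interval_s = frame_interval_s,
                 channel_offset_px = channel_offset_px,
                 psf_sigma_z_um = psf_sigma_z_um),
            class = "OpticsConfig")
}

#' Camera/illumination noise configuration
#'
#' @param photon_gain photons per intensity unit (> 0); per-pixel shot-noise
#'   variance is mean/gain.
#' @param read_noise_sd Gaussian read noise (intensity units, >= 0).
#' @param background_level constant background intensity added before noise.
#' @param flatfield_amplitude relative amplitude of a linear illumination
#'   gradient along x, in [0, 1).
#' @param bleach_rate_per_frame exponential photobleaching rate (1/frame).
#' @return list of class `NoiseConfig`.
#' @export
noise_config <- function(photon_gain = 1, read_noise_sd = 2,
                         background_level = 100, flatfield_amplitude = 0,
                         bleach_rate_per_frame = 0) {
  stopifnot(photon_gain > 0, read_noise_sd >= 0, background_level >= 0,
            flatfield_amplitude >= 0, flatfield_amplitude < 1,
            bleach_rate_per_frame >= 0)
  structure(list(photon_gain = photon_gain, read_noise_sd = read_noise_sd,
                 background_level = background_level,
                 flatfield_amplitude = flatfield_amplitude,
                 bleach_rate_per_frame = bleach_rate_per_frame),
            class = "NoiseConfig")
}

#' Translation-reporter configuration
#'
#' @param half_life_h reporter protein half-life in hours (default 6, the
#'   decay timescale of a destabilized fluorescent reporter).
#' @param inhibition_alpha fraction of synthesis lost at light-on, in [0, 1].
#' @param noise_sd relative multiplicative measurement noise.
#' @param alpha_sd cell-to-cell spread of `inhibition_alpha` (truncated to
#'   [0, 1]); 0 for a homogeneous population.
#' @return list of class `ReporterConfig`.
#' @export
reporter_config <- function(half_life_h = 6, inhibition_alpha = 0.5,
                            noise_sd = 0.02, alpha_sd = 0) {
  stopifnot(half_life_h > 0, inhibition_alpha >= 0, inhibition_alpha <= 1,
            noise_sd >= 0, alpha_sd >= 0)
  structure(list(half_life_h = half_life_h, inhibition_alpha = inhibition_alpha,
                 noise_sd = noise_sd, alpha_sd = alpha_sd),
            class = "ReporterConfig")
}

# Linear illumination gradient along x, mean ~1, relative amplitude a.
flatfield_matrix <- function(nr, nc, a) {
  if (a <= 0) return(matrix(1, nr, nc))
  gx <- 1 + a * (2 * (seq_len(nc) - 1) / (nc - 1) - 1)
  matrix(gx, nr, nc, byrow = TRUE)
}

# Poisson + Gaussian camera model applied to an expected-intensity matrix.
apply_camera_noise <- function(signal, noise, flat = NULL, bleach_factor = 1) {
  lam <- (noise$background_level + signal) * bleach_factor
  if (!is.null(flat)) lam <- lam * flat
  g <- noise$photon_gain
  counts <- matrix(rpois(length(lam), as.vector(lam) * g) / g, nrow(lam), ncol(lam))
  counts + matrix(rnorm(length(lam), sd = noise$read_noise_sd), nrow(lam), ncol(lam))
}

#' Spot amplitude achieving a target peak signal-to-noise ratio
#'
#' Solves `A / sqrt((A + background)/gain + read_noise^2) = snr` for A under
#' the package's camera model.
#'
#' @param snr target peak SNR.
#' @param noise a [noise_config()].
#' @return amplitude in intensity units.
#' @export
amplitude_for_snr <- function(snr, noise) {
  g <- noise$photon_gain
  b <- noise$background_level / g + noise$read_noise_sd^2
  (snr^2 / g + sqrt(snr^4 / g^2 + 4 * snr^2 * b)) / 2
}

# Add point-sampled 2D Gaussians to a matrix (0-based spot coordinates).
render_spots_2d <- function(img, x, y, amp, sigma_px) {
  if (length(x) == 0) return(img)
  y <- rep_len(y, length(x)); amp <- rep_len(amp, length(x))
  h <- ceiling(4 * sigma_px)
  nr <- nrow(img); nc <- ncol(img)
  for (s in seq_along(x)) {
    if (amp[s] <= 0) next
    cx <- x[s]; cy <- y[s]
    j0 <- max(0, floor(cx) - h); j1 <- min(nc - 1, ceiling(cx) + h)
    i0 <- max(0, floor(cy) - h); i1 <- min(nr - 1, ceiling(cy) + h)
    if (j0 > j1 || i0 > i1) next
    gx <- exp(-((j0:j1) - cx)^2 / (2 * sigma_px^2))
    gy <- exp(-((i0:i1) - cy)^2 / (2 * sigma_px^2))
    img[(i0:i1) + 1, (j0:j1) + 1] <- img[(i0:i1) + 1, (j0:j1) + 1] +
      amp[s] * outer(gy, gx)
  }
  img
}

# Gaussian z amplitude envelope in plane units.
z_envelope <- function(dz_planes, optics) {
  sz <- optics$psf_sigma_z_um / optics$z_step_um
  exp(-dz_planes^2 / (2 * sz^2))
}

# Stamp a hard-edged disc of the given value at 0-based (x, y); callers blur
# once per plane with the PSF afterwards.
stamp_disc <- function(img, x, y, radius_px, value) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(radius_px)
  j0 <- max(0, floor(x) - r); j1 <- min(nc - 1, ceiling(x) + r)
  i0 <- max(0, floor(y) - r); i1 <- min(nr - 1, ceiling(y) + r)
  if (j0 > j1 || i0 > i1) return(img)
  jj <- j0:j1; ii <- i0:i1
  d2 <- outer((ii - y)^2, (jj - x)^2, `+`)
  img[ii + 1, jj + 1] <- img[ii + 1, jj + 1] + value * (d2 <= radius_px^2)
  img
}

# Rasterize a disc (antialiased by a blur with the PSF) at 0-based (x, y).
render_disc <- function(img, x, y, radius_px, intensity, psf_px) {
  img + blur_gaussian(stamp_disc(matrix(0, nrow(img), ncol(img)),
                                 x, y, radius_px, intensity), psf_px)
}

# Elliptical cell mask inset by margin pixels.
cell_mask_ellipse <- function(nr, nc, margin) {
  a <- (nc - 1) / 2 - margin; b <- (nr - 1) / 2 - margin
  jj <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  ii <- matrix(0:(nr - 1), nr, nc)
  ((jj - (nc - 1) / 2)^2 / a^2 + (ii - (nr - 1) / 2)^2 / b^2) <= 1
}

#' Synthetic two-channel smFISH z-stack with recruitment ground truth
#'
#' Generates a cell containing light-activated condensates (channel 1) and
#' diffraction-limited mRNA spots (channel 2). Each mRNA is recruited into a
#' uniformly chosen condensate with probability `recruitment_p`; otherwise it
#' is placed in the cell mask at a planar distance greater than twice the
#' recruitment radius from every condensate, so truth labels stay unambiguous
#' under the downstream distance classifier.
#'
#' @param n_condensates,n_mrnas object counts (>= 0).
#' @param recruitment_p probability of recruitment per mRNA, in [0, 1].
#' @param optics an [optics_config()].
#' @param noise a [noise_config()].
#' @param seed integer RNG seed (mandatory).
#' @param img_size c(rows, cols) in pixels.
#' @param n_planes number of z planes.
#' @param condensate_radius_nm physical condensate radius.
#' @param recruit_radius_nm the recruitment threshold the classifier will use;
#'   controls the exclusion zone for non-recruited placement.
#' @param condensate_intensity peak intensity of the condensate disc.
#' @param mrna_snr target peak SNR of mRNA spots.
#' @param amplitude_cv lognormal coefficient of variation of spot amplitudes.
#' @return list with `stack` (ImageStack, axes Y,X,Z,C) and `truth`
#'   (SceneTruth: condensate and mRNA tables, recruitment fraction, seed,
#'   cell mask).
#' @export
make_fish_scene <- function(n_condensates, n_mrnas, recruitment_p,
                            optics = optics_config(), noise = noise_config(),
                            seed, img_size = c(128, 128), n_planes = 7,
                            condensate_radius_nm = 250, recruit_radius_nm = 330,
                            condensate_intensity = 400, mrna_snr = 10,
                            amplitude_cv = 0.2) {
  stopifnot(n_condensates >= 0, n_mrnas >= 0,
            recruitment_p >= 0, recruitment_p <= 1)
  if (n_condensates == 0 && recruitment_p > 0 && n_mrnas > 0)
    stop("cannot recruit mRNAs into zero condensates")
  with_seed(seed, {
    nr <- img_size[1]; nc <- img_size[2]
    px <- optics$pixel_size_nm
    psf_px <- optics$psf_sigma_nm / px
    cond_r_px <- condensate_radius_nm / px
    excl_px <- 2 * recruit_radius_nm / px
    mask <- cell_mask_ellipse(nr, nc, margin = 6)

    # condensates: rejection-sampled with a minimum mutual separation so that
    # segmentation sees disjoint regions
    # condensates are resolved, well-separated objects; the separation keeps
    # their thresholded blobs disjoint for any reasonable threshold
    cond <- data.frame(x = numeric(0), y = numeric(0), z = integer(0))
    min_sep <- max(12, 2.5 * cond_r_px + 2)
    tries <- 0
    while (nrow(cond) < n_condensates && tries < 20000) {
      tries <- tries + 1
      x <- runif(1, 8, nc - 9); y <- runif(1, 8, nr - 9)
      if (!mask[round(y) + 1, round(x) + 1]) next
      if (nrow(cond) && min(sqrt((cond$x - x)^2 + (cond$y - y)^2)) < min_sep) next
      cond <- rbind(cond, data.frame(x = x, y = y,
                                     z = sample(2:(max(2, n_planes - 1)), 1)))
    }
    if (nrow(cond) < n_condensates)
      stop("could not place all condensates; reduce count or enlarge image")
    cond$radius_nm <- condensate_radius_nm
    cond$intensity <- condensate_intensity * rlnorm(nrow(cond), 0, 0.15)

    # mRNAs
    amp0 <- amplitude_for_snr(mrna_snr, noise)
    n <- n_mrnas
    recruited <- if (n > 0) runif(n) < recruitment_p else logical(0)
    mx <- my <- numeric(n); mz <- cond_id <- integer(n)
    for (s in seq_len(n)) {
      if (recruited[s]) {
        # inside the condensate core: a 250 nm condensate spans less than one
        # z step, so a recruited mRNA shares its condensate's plane
        k <- sample.int(nrow(cond), 1)
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * 0.6 * min(cond_r_px, recruit_radius_nm / px)
        mx[s] <- cond$x[k] + rad * cos(ang)
        my[s] <- cond$y[k] + rad * sin(ang)
        mz[s] <- cond$z[k]
        cond_id[s] <- k
      } else {
        ok <- FALSE
        for (t in 1:10000) {
          x <- runif(1, 5, nc - 6); y <- runif(1, 5, nr - 6)
          if (!mask[round(y) + 1, round(x) + 1]) next
          if (nrow(cond) && min(sqrt((cond$x - x)^2 + (cond$y - y)^2)) <= excl_px) next
          mx[s] <- x; my[s] <- y; mz[s] <- sample.int(n_planes, 1); ok <- TRUE
          break
        }
        if (!ok) stop("could not place non-recruited mRNA outside exclusion zones")
      }
    }
    amp <- amp0 * rlnorm(n, -log(1 + amplitude_cv^2) / 2, sqrt(log(1 + amplitude_cv^2)))
    mrnas <- data.frame(x = mx, y = my, z = mz, amplitude = amp,
                        recruited = recruited, condensate = cond_id)

    ff <- flatfield_matrix(nr, nc, noise$flatfield_amplitude)
    arr <- array(0, dim = c(nr, nc, n_planes, 2))
    off <- optics$channel_offset_px
    for (z in seq_len(n_planes)) {
      ch1 <- matrix(0, nr, nc)
      if (nrow(cond)) {
        env <- z_envelope(z - cond$z, optics)
        for (k in which(env > 1e-3))
          ch1 <- stamp_disc(ch1, cond$x[k], cond$y[k], cond_r_px,
                            cond$intensity[k] * env[k])
        ch1 <- blur_gaussian(ch1, psf_px)
      }
      ch2 <- matrix(0, nr, nc)
      if (n > 0) {
        env <- z_envelope(z - mrnas$z, optics)
        vis <- env > 1e-3
        ch2 <- render_spots_2d(ch2, mrnas$x[vis] + off[2], mrnas$y[vis] + off[1],
                               mrnas$amplitude[vis] * env[vis], psf_px)
      }
      arr[, , z, 1] <- apply_camera_noise(ch1, noise, ff)
      arr[, , z, 2] <- apply_camera_noise(ch2, noise, ff)
    }
    stack <- image_stack(arr, c("Y", "X", "Z", "C"),
                         pixel_size_nm = px, z_step_um = optics$z_step_um,
                         channels = c("condensate", "mrna"))
    truth <- structure(list(
      condensates = cond, mrnas = mrnas,
      recruitment_fraction_true = if (n > 0) mean(recruited) else NA_real_,
      cell_mask = mask, seed = seed,
      recruit_radius_nm = recruit_radius_nm
    ), class = "SceneTruth")
    list(stack = stack, truth = truth)
  })
}

#' Synthetic two-colour live movie of diffusing mRNAs and condensates
#'
#' mRNAs undergo Brownian motion; within `capture_radius` of a condensate
#' they bind at rate `k_on` and unbind at `k_off`, adopting the condensate's
#' motion while bound. The per-frame telegraph (bound) state is logged in the
#' truth.
#'
#' @param n_mrnas number of mRNA particles.
#' @param D_mrna,D_condensate diffusion coefficients (um^2/s, >= 0).
#' @param binding list with `k_on` (1/s), `k_off` (1/s), `capture_radius_nm`.
#' @param optics an [optics_config()]; `frame_interval_s` must be set.
#' @param noise a [noise_config()].
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param n_condensates number of condensates.
#' @param img_size c(rows, cols) pixels.
#' @param boundary "reflect" keeps particles in the field of view; "none"
#'   leaves the walk free (useful for step-statistics checks).
#' @param render if `FALSE`, skip rasterization and return truth only.
#' @param mrna_snr,condensate_intensity rendering intensities.
#' @return list with `stack` (ImageStack Y,X,T,C or NULL) and `truth`
#'   (per-frame positions in pixels, bound states, condensate tracks).
#' @export
make_live_movie <- function(n_mrnas, D_mrna, D_condensate,
                            binding = list(k_on = 0, k_off = 0, capture_radius_nm = 400),
                            optics = optics_config(), noise = noise_config(),
                            n_frames = 100, seed, n_condensates = 3,
                            img_size = c(64, 64), boundary = "reflect",
                            render = TRUE, mrna_snr = 10,
                            condensate_intensity = 400) {
  stopifnot(D_mrna >= 0, D_condensate >= 0, n_frames >= 1,
            binding$k_on >= 0, binding$k_off >= 0)
  if (is.null(optics$frame_interval_s) || !is.finite(optics$frame_interval_s))
    stop("frame_interval_s missing from optics")
  with_seed(seed, {
    nr <- img_size[1]; nc <- img_size[2]
    px <- optics$pixel_size_nm
    dt <- optics$frame_interval_s
    sd_m <- sqrt(2 * D_mrna * dt) * 1000 / px        # px / frame / axis
    sd_c <- sqrt(2 * D_condensate * dt) * 1000 / px
    cap_px <- binding$capture_radius_nm / px
    p_on <- 1 - exp(-binding$k_on * dt)
    p_off <- 1 - exp(-binding$k_off * dt)

    reflect <- function(v, lo, hi) {
      if (boundary != "reflect") return(v)
      rng <- hi - lo
      v <- (v - lo) %% (2 * rng)
      lo + ifelse(v > rng, 2 * rng - v, v)
    }
    cond_pos <- array(0, c(n_frames, max(n_condensates, 1), 2))
    if (n_condensates > 0) {
      cond_pos[1, , 1] <- runif(n_condensates, nc * 0.2, nc * 0.8)
      cond_pos[1, , 2] <- runif(n_condensates, nr * 0.2, nr * 0.8)
    }
    mpos <- array(0, c(n_frames, max(n_mrnas, 1), 2))
    if (n_mrnas > 0) {
      mpos[1, , 1] <- runif(n_mrnas, nc * 0.1, nc * 0.9)
      mpos[1, , 2] <- runif(n_mrnas, nr * 0.1, nr * 0.9)
    }
    bound <- matrix(FALSE, n_frames, max(n_mrnas, 1))
    anchor <- matrix(NA_integer_, 1, max(n_mrnas, 1)) # condensate id while bound
    rel_off <- matrix(0, max(n_mrnas, 1), 2)

    for (f in 2:max(n_frames, 2)) {
      if (f > n_frames) break
      if (n_condensates > 0) {
        step <- matrix(rnorm(n_condensates * 2, sd = sd_c), ncol = 2)
        cond_pos[f, seq_len(n_condensates), 1] <-
          reflect(cond_pos[f - 1, seq_len(n_condensates), 1] + step[, 1], 1, nc - 2)
        cond_pos[f, seq_len(n_condensates), 2] <-
          reflect(cond_pos[f - 1, seq_len(n_condensates), 2] + step[, 2], 1, nr - 2)
      }
      for (s in seq_len(n_mrnas)) {
        if (bound[f - 1, s]) {
          if (runif(1) < p_off) { # unbind
            bound[f, s] <- FALSE
            mpos[f, s, ] <- cond_pos[f, anchor[1, s], ] + rel_off[s, ]
            anchor[1, s] <- NA_integer_
          } else {
            bound[f, s] <- TRUE
            mpos[f, s, ] <- cond_pos[f, anchor[1, s], ] + rel_off[s, ]
          }
        } else {
          step <- rnorm(2, sd = sd_m)
          mpos[f, s, 1] <- reflect(mpos[f - 1, s, 1] + step[1], 1, nc - 2)
          mpos[f, s, 2] <- reflect(mpos[f - 1, s, 2] + step[2], 1, nr - 2)
          if (n_condensates > 0 && p_on > 0) {
            d <- sqrt((cond_pos[f, seq_len(n_condensates), 1] - mpos[f, s, 1])^2 +
                      (cond_pos[f, seq_len(n_condensates), 2] - mpos[f, s, 2])^2)
            k <- which.min(d)
            if (d[k] < cap_px && runif(1) < p_on) {
              bound[f, s] <- TRUE
              anchor[1, s] <- k
              rel_off[s, ] <- mpos[f, s, ] - cond_pos[f, k, ]
            }
          }
        }
      }
    }

    stack <- NULL
    if (render) {
      amp <- amplitude_for_snr(mrna_snr, noise)
      psf_px <- optics$psf_sigma_nm / px
      arr <- array(0, dim = c(nr, nc, n_frames, 2))
      off <- optics$channel_offset_px
      for (f in seq_len(n_frames)) {
        bl <- exp(-noise$bleach_rate_per_frame * (f - 1))
        ch1 <- matrix(0, nr, nc)
        if (n_condensates > 0)
          for (k in seq_len(n_condensates))
            ch1 <- render_disc(ch1, cond_pos[f, k, 1], cond_pos[f, k, 2],
                               2.2, condensate_intensity, psf_px)
        ch2 <- matrix(0, nr, nc)
        if (n_mrnas > 0)
          ch2 <- render_spots_2d(ch2, mpos[f, , 1] + off[2], mpos[f, , 2] + off[1],
                                 rep(amp, n_mrnas), psf_px)
        arr[, , f, 1] <- apply_camera_noise(ch1, noise, bleach_factor = bl)
        arr[, , f, 2] <- apply_camera_noise(ch2, noise, bleach_factor = bl)
      }
      stack <- image_stack(arr, c("Y", "X", "T", "C"), pixel_size_nm = px,
                           frame_interval_s = dt,
                           channels = c("condensate", "mrna"))
    }
    truth <- structure(list(
      mrna_xy_px = mpos[, seq_len(max(n_mrnas, 1)), , drop = FALSE],
      condensate_xy_px = cond_pos, bound = bound[, seq_len(max(n_mrnas, 1)), drop = FALSE],
      D_true = c(mrna = D_mrna, condensate = D_condensate),
      frame_interval_s = dt, pixel_size_nm = px, seed = seed
    ), class = "SceneTruth")
    list(stack = stack, truth = truth)
  })
}

#' Synthetic telegraph distance trace
#'
#' Two-state (bound/unbound) telegraph process with exponential dwell times,
#' sampled on the frame grid; the distance reads `d_on_nm` when bound and
#' `d_off_nm` when unbound, plus Gaussian noise. The truth logs every bound
#' interval (including those shorter than any detector's minimum).
#'
#' @param mean_on_s,mean_off_s mean bound/unbound dwell times (s).
#' @param n_frames trace length.
#' @param frame_interval_s sampling interval (s).
#' @param d_on_nm,d_off_nm distance levels.
#' @param noise_nm additive distance noise.
#' @param seed RNG seed.
#' @return list with `trace` (data.frame frame, dist_nm) and `truth`
#'   (data.frame start_frame, n_frames, duration_s per bound interval).
#' @export
make_telegraph_trace <- function(mean_on_s, mean_off_s, n_frames = 1000,
                                 frame_interval_s = 0.05, d_on_nm = 100,
                                 d_off_nm = 900, noise_nm = 30, seed) {
  stopifnot(mean_on_s > 0, mean_off_s > 0)
  with_seed(seed, {
    p_off <- 1 - exp(-frame_interval_s / mean_on_s)
    p_on <- 1 - exp(-frame_interval_s / mean_off_s)
    bound <- logical(n_frames)
    b <- FALSE
    for (f in seq_len(n_frames)) {
      b <- if (b) runif(1) >= p_off else runif(1) < p_on
      bound[f] <- b
    }
    d <- ifelse(bound, d_on_nm, d_off_nm) + rnorm(n_frames, sd = noise_nm)
    r <- rle(bound)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- data.frame(start_frame = starts[r$values],
                     n_frames = r$lengths[r$values])
    ev$duration_s <- ev$n_frames * frame_interval_s
    list(trace = data.frame(frame = seq_len(n_frames), dist_nm = pmax(d, 0)),
         truth = ev)
  })
}

#' Synthetic FRAP trace
#'
#' Pre-bleach plateau at 1, instantaneous bleach to depth `bleach_depth`,
#' then recovery `b + (1 - b) * M * (1 - exp(-t / tau))` with additive
#' Gaussian noise.
#'
#' @param mobile_fraction M in [0, 1].
#' @param tau_s recovery time constant (s).
#' @param pre_frames number of pre-bleach frames (> 0; the normalization
#'   reference).
#' @param noise_sd additive noise standard deviation.
#' @param seed RNG seed.
#' @param n_frames total frames.
#' @param frame_interval_s sampling interval.
#' @param bleach_depth post-bleach level b.
#' @return object of class `FRAPTrace`: times, values, pre-bleach window,
#'   bleach frame index, and the generating truth.
#' @export
make_frap_trace <- function(mobile_fraction, tau_s, pre_frames = 10,
                            noise_sd = 0.02, seed, n_frames = 120,
                            frame_interval_s = 1, bleach_depth = 0.3) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, tau_s > 0)
  if (pre_frames <= 0) stop("pre_frames must be positive (normalization undefined)")
  with_seed(seed, {
    times <- (seq_len(n_frames) - 1) * frame_interval_s
    b <- bleach_depth
    post <- times[-seq_len(pre_frames)] - times[pre_frames + 1]
    clean <- c(rep(1, pre_frames),
               b + (1 - b) * mobile_fraction * (1 - exp(-post / tau_s)))
    vals <- clean + rnorm(n_frames, sd = noise_sd)
    structure(list(times = times, values = vals, pre_frames = pre_frames,
                   bleach_frame = pre_frames + 1L,
                   truth = list(mobile_fraction = mobile_fraction, tau_s = tau_s,
                                bleach_depth = b, seed = seed)),
              class = "FRAPTrace")
  })
}

#' Synthetic translation-reporter time courses
#'
#' From a steady state at t = 0, the normalized reporter level follows
#' `P(t)/P(0) = (1 - alpha) + alpha * exp(-t * ln 2 / half_life)`, i.e. the
#' fraction `alpha` of synthesis lost at light-on decays away with the
#' protein's half-life. Per-cell `alpha` may be spread (`cfg$alpha_sd`).
#'
#' @param n_cells number of cells.
#' @param cfg a [reporter_config()].
#' @param duration_h total duration (hours, > 0).
#' @param seed RNG seed.
#' @param dt_h sampling interval (hours).
#' @param baseline_mean mean initial absolute intensity (lognormal across
#'   cells).
#' @return list with `traces` data.frame (cell, t_h, value) and `truth`
#'   (per-cell alpha and baseline).
#' @export
make_reporter_traces <- function(n_cells, cfg = reporter_config(), duration_h = 12,
                                 seed, dt_h = 0.5, baseline_mean = 200) {
  stopifnot(duration_h > 0, n_cells >= 1)
  with_seed(seed, {
    t_h <- seq(0, duration_h, by = dt_h)
    alpha <- pmin(pmax(rnorm(n_cells, cfg$inhibition_alpha, cfg$alpha_sd), 0), 1)
    if (cfg$alpha_sd == 0) alpha <- rep(cfg$inhibition_alpha, n_cells)
    p0 <- baseline_mean * rlnorm(n_cells, 0, 0.4)
    traces <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      frac <- (1 - alpha[i]) + alpha[i] * exp(-t_h * log(2) / cfg$half_life_h)
      v <- p0[i] * frac
      if (cfg$noise_sd > 0) v <- v * exp(rnorm(length(v), 0, cfg$noise_sd))
      data.frame(cell = i, t_h = t_h, value = v)
    }))
    list(traces = traces,
         truth = list(alpha = alpha, baseline = p0, cfg = cfg, seed = seed))
  })
}

#' Synthetic per-cell expression scan around a saturation concentration
#'
#' Cells draw a cytoplasmic intensity from a lognormal distribution; a cell
#' clusters (forms condensates) with probability given by a logistic soft
#' edge in log concentration around its saturation concentration, which is
#' reduced by `shift_with_mrna` for cells carrying the cognate mRNA.
#' Condensate integrated intensity grows linearly above threshold.
#'
#' @param n_cells number of cells.
#' @param csat saturation concentration (a.u., > 0).
#' @param expression_dist c(meanlog, sdlog) of the lognormal expression
#'   distribution; defaults centre the scan on `csat`.
#' @param shift_with_mrna relative csat reduction for mRNA-carrying cells
#'   (e.g. 0.2 for a 20 percent reduction).
#' @param seed RNG seed.
#' @param soft_width logistic width in log concentration.
#' @param with_mrna_fraction fraction of cells flagged as carrying the mRNA.
#' @param intensity_slope condensate intensity per unit of supersaturation.
#' @return list with `cells` data.frame (cell_id, c1, with_mrna, clustered,
#'   condensate_total_intensity) and `truth`.
#' @export
make_phase_scan <- function(n_cells, csat, expression_dist = NULL,
                            shift_with_mrna = 0, seed, soft_width = 0.08,
                            with_mrna_fraction = 0.5, intensity_slope = 50) {
  stopifnot(csat > 0, n_cells >= 1)
  if (is.null(expression_dist)) expression_dist <- c(log(csat), 0.5)
  with_seed(seed, {
    c1 <- rlnorm(n_cells, expression_dist[1], expression_dist[2])
    with_mrna <- runif(n_cells) < with_mrna_fraction
    csat_i <- csat * ifelse(with_mrna, 1 - shift_with_mrna, 1)
    p <- plogis((log(c1) - log(csat_i)) / soft_width)
    clustered <- runif(n_cells) < p
    ci <- ifelse(clustered, intensity_slope * pmax(c1 - csat_i, 0), 0) +
      abs(rnorm(n_cells, 0, 2))
    cells <- data.frame(cell_id = seq_len(n_cells), c1 = c1,
                        with_mrna = with_mrna, clustered = clustered,
                        condensate_total_intensity = ci)
    list(cells = cells,
         truth = list(csat = csat, shift_with_mrna = shift_with_mrna,
                      soft_width = soft_width, seed = seed))
  })
}

#' Synthetic dendrite with spines, before/after stimulated growth
#'
#' Spines are rendered as spheres attached to a dendrite cylinder in an
#' isotropic-voxel z-stack time series (z step is set equal to the pixel
#' size so a sphere of radius r occupies (4/3) pi r^3 voxels). After
#' `stim_frame`, true volumes scale by `growth_factor`.
#'
#' @param n_spines number of spines.
#' @param radii_px sphere radii in pixels (each >= 2), recycled to
#'   `n_spines`.
#' @param growth_factor volume scale factor after stimulation.
#' @param optics an [optics_config()] (pixel size and PSF only).
#' @param noise a [noise_config()].
#' @param seed RNG seed.
#' @param n_timepoints total time points.
#' @param stim_frame first post-stimulation frame (baseline frames precede).
#' @param spine_intensity peak intensity of the (unblurred) structures.
#' @param spacing_px centre-to-centre spine spacing; defaults to a
#'   non-overlapping layout, and overlapping placements raise an error.
#' @return list with `stack` (ImageStack Y,X,Z,T), `truth` (per-spine,
#'   per-time analytic volumes in voxels) and `roi_boxes` (one box per
#'   spine: y0, y1, x0, x1 0-based inclusive, all z).
#' @export
make_spine_series <- function(n_spines, radii_px, growth_factor,
                              optics = optics_config(pixel_size_nm = 250),
                              noise = noise_config(),
                              seed, n_timepoints = 6, stim_frame = 4,
                              spine_intensity = 300, spacing_px = NULL) {
  radii_px <- rep_len(radii_px, n_spines)
  if (any(radii_px < 2)) stop("spine radii must be >= 2 px")
  with_seed(seed, {
    rmax <- max(radii_px) * growth_factor^(1 / 3)
    gap <- if (is.null(spacing_px)) ceiling(2 * rmax + 8) else spacing_px
    nc <- as.integer(n_spines * gap + 2 * gap)
    nz <- as.integer(2 * ceiling(rmax) + 9)
    dend_r <- 2
    neck <- 4
    nr <- as.integer(ceiling(rmax) * 2 + dend_r * 2 + neck + 20)
    dend_y <- nr - 6 - dend_r            # dendrite near one edge
    zc <- (nz - 1) / 2
    cx <- gap * seq_len(n_spines) + gap / 2
    cy <- dend_y - dend_r - neck - radii_px * growth_factor^(1 / 3) - 1
    # overlap guard (error by contract)
    if (n_spines > 1 && any(diff(cx) < 2 * rmax + 2)) stop("overlapping spines")
    psf_px <- optics$psf_sigma_nm / optics$pixel_size_nm
    arr <- array(0, dim = c(nr, nc, nz, n_timepoints))
    truth_vol <- matrix(0, n_timepoints, n_spines)
    for (tp in seq_len(n_timepoints)) {
      gf <- if (tp >= stim_frame) growth_factor else 1
      r_t <- radii_px * gf^(1 / 3)
      truth_vol[tp, ] <- 4 / 3 * pi * r_t^3
      for (z in seq_len(nz)) {
        pl <- matrix(0, nr, nc)
        dz <- z - 1 - zc
        # dendrite cylinder (axis along x at y = dend_y, z = zc)
        if (abs(dz) <= dend_r) {
          half <- sqrt(dend_r^2 - dz^2)
          ii <- matrix(0:(nr - 1), nr, nc)
          pl <- pl + spine_intensity * (abs(ii - dend_y) <= half)
        }
        for (s in seq_len(n_spines)) {
          if (abs(dz) >= r_t[s]) next
          rs <- sqrt(r_t[s]^2 - dz^2)
          jj <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
          ii <- matrix(0:(nr - 1), nr, nc)
          pl <- pl + spine_intensity *
            (((jj - cx[s])^2 + (ii - cy[s])^2) <= rs^2)
          # neck: thin, sub-resolution (dim) bridge on the central plane
          if (abs(dz) <= 1) {
            ny0 <- round(cy[s] + r_t[s] - 1); ny1 <- round(dend_y)
            if (ny1 > ny0)
              pl[(ny0:ny1) + 1, round(cx[s]) + c(0, 1)] <- 0.4 * spine_intensity
          }
        }
        arr[, , z, tp] <- apply_camera_noise(blur_gaussian(pl, psf_px), noise)
      }
    }
    # ROI boxes hug the grown sphere; on the dendrite side they stop at the
    # sphere edge so the neck contributes at most one voxel row
    half_box <- ceiling(radii_px * growth_factor^(1 / 3)) + 3
    r_grown <- ceiling(radii_px * growth_factor^(1 / 3))
    roi_boxes <- data.frame(
      spine = seq_len(n_spines),
      y0 = pmax(0, round(cy) - half_box), y1 = pmin(nr - 1, round(cy) + r_grown),
      x0 = pmax(0, round(cx) - half_box), x1 = pmin(nc - 1, round(cx) + half_box))
    stack <- image_stack(arr, c("Y", "X", "Z", "T"),
                         pixel_size_nm = optics$pixel_size_nm,
                         z_step_um = optics$pixel_size_nm / 1000)
    list(stack = stack,
         truth = list(volumes_vox = truth_vol, radii_px = radii_px,
                      growth_factor = growth_factor, stim_frame = stim_frame,
                      seed = seed),
         roi_boxes = roi_boxes)
  })
}

#' Synthetic bead pair for channel registration
#'
#' The same random bead field rendered in two channels, the second shifted by
#' `offset_px`.
#'
#' @param n_beads number of beads (>= 3).
#' @param offset_px c(dy, dx) shift of the second channel in pixels.
#' @param optics an [optics_config()].
#' @param noise a [noise_config()].
#' @param seed RNG seed.
#' @param img_size c(rows, cols).
#' @param bead_snr peak SNR of bead spots.
#' @return list of two single-plane `ImageStack`s (`ref`, `moving`) and the
#'   truth bead table.
#' @export
make_bead_pair <- function(n_beads, offset_px, optics = optics_config(),
                           noise = noise_config(), seed, img_size = c(128, 128),
                           bead_snr = 30) {
  if (n_beads < 3) stop("need at least 3 beads for registration")
  with_seed(seed, {
    nr <- img_size[1]; nc <- img_size[2]
    psf_px <- optics$psf_sigma_nm / optics$pixel_size_nm
    # rejection sampling for a minimum separation
    xs <- ys <- numeric(0)
    while (length(xs) < n_beads) {
      x <- runif(1, 8, nc - 9); y <- runif(1, 8, nr - 9)
      if (length(xs) && min(sqrt((xs - x)^2 + (ys - y)^2)) < 10) next
      xs <- c(xs, x); ys <- c(ys, y)
    }
    amp <- amplitude_for_snr(bead_snr, noise)
    ref <- render_spots_2d(matrix(0, nr, nc), xs, ys, rep(amp, n_beads), psf_px)
    mov <- render_spots_2d(matrix(0, nr, nc), xs + offset_px[2], ys + offset_px[1],
                           rep(amp, n_beads), psf_px)
    mk <- function(m) image_stack(apply_camera_noise(m, noise), c("Y", "X"),
                                  pixel_size_nm = optics$pixel_size_nm)
    list(ref = mk(ref), moving = mk(mov),
         truth = list(x = xs, y = ys, offset_px = offset_px, seed = seed))
  })
}
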