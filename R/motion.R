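# Trajectory linking, MSD/diffusion estimation and binding-event analysis.

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame matching in global order of increasing displacement (each
#' track end and each detection used at most once), which resolves conflicts
#' without exceeding `max_disp_px`; gaps of up to `max_gap` missing frames
#' are closed.
#'
#' @param spot_frames list of per-frame data.frames with x_px, y_px (list
#'   index = frame number).
#' @param max_disp_px maximal displacement per frame step (> 0).
#' @param max_gap maximal number of consecutive missed frames.
#' @return list of trajectories, each a data.frame (frame, x_px, y_px) of
#'   class `Trajectory`.
#' @export
link_trajectories <- function(spot_frames, max_disp_px, max_gap = 1) {
  stopifnot(max_disp_px > 0, max_gap >= 0)
  tracks <- list()
  open <- integer(0)
  for (f in seq_along(spot_frames)) {
    df <- spot_frames[[f]]
    nd <- if (is.null(df)) 0L else nrow(df)
    # drop tracks whose last frame is too old
    if (length(open)) {
      lastf <- vapply(tracks[open], function(tr) tail(tr$frame, 1), 0)
      open <- open[f - lastf <= max_gap + 1]
    }
    used <- rep(FALSE, nd)
    if (nd > 0 && length(open)) {
      lastf <- vapply(tracks[open], function(tr) tail(tr$frame, 1), 0)
      lastx <- vapply(tracks[open], function(tr) tail(tr$x_px, 1), 0)
      lasty <- vapply(tracks[open], function(tr) tail(tr$y_px, 1), 0)
      gap <- f - lastf
      pairs <- expand.grid(ti = seq_along(open), si = seq_len(nd))
      pairs$d <- sqrt((lastx[pairs$ti] - df$x_px[pairs$si])^2 +
                      (lasty[pairs$ti] - df$y_px[pairs$si])^2)
      # displacement budget scales with the gap being closed
      pairs <- pairs[pairs$d <= max_disp_px * gap[pairs$ti], , drop = FALSE]
      pairs <- pairs[order(pairs$d), , drop = FALSE]
      tdone <- rep(FALSE, length(open))
      for (r in seq_len(nrow(pairs))) {
        ti <- pairs$ti[r]; si <- pairs$si[r]
        if (tdone[ti] || used[si]) next
        tdone[ti] <- TRUE; used[si] <- TRUE
        k <- open[ti]
        tracks[[k]] <- rbind(tracks[[k]],
                             data.frame(frame = f, x_px = df$x_px[si],
                                        y_px = df$y_px[si]))
      }
    }
    for (si in which(!used)) {
      tracks[[length(tracks) + 1L]] <-
        data.frame(frame = f, x_px = df$x_px[si], y_px = df$y_px[si])
      open <- c(open, length(tracks))
    }
  }
  lapply(tracks, function(tr) { class(tr) <- c("Trajectory", "data.frame"); tr })
}

#' Time-averaged mean squared displacement of one trajectory
#'
#' Overlapping-pair MSD per lag, up to a quarter of the trajectory length;
#' gaps contribute only to the lags their frame differences realize.
#'
#' @param traj data.frame (frame, x_px, y_px), length >= 5.
#' @param pixel_size_nm pixel size.
#' @param frame_interval_s frame interval.
#' @return data.frame of class `MSDProfile`: lag_s, msd_um2, n_pairs
#'   (lag 0 omitted; by construction MSD(0) = 0).
#' @export
compute_msd <- function(traj, pixel_size_nm, frame_interval_s) {
  if (nrow(traj) < 5) stop("trajectory too short for MSD (need >= 5 points)")
  span <- diff(range(traj$frame)) + 1
  max_lag <- max(1L, floor(span / 4))
  um <- pixel_size_nm / 1000
  lags <- seq_len(max_lag)
  msd <- numeric(max_lag); np <- integer(max_lag)
  n <- nrow(traj)
  for (i in seq_len(n - 1)) {
    dfr <- traj$frame[(i + 1):n] - traj$frame[i]
    sel <- which(dfr <= max_lag)
    if (!length(sel)) next
    dd <- ((traj$x_px[i + sel] - traj$x_px[i])^2 +
           (traj$y_px[i + sel] - traj$y_px[i])^2) * um^2
    for (s in seq_along(sel)) {
      L <- dfr[sel[s]]
      msd[L] <- msd[L] + dd[s]
      np[L] <- np[L] + 1L
    }
  }
  keep <- np > 0
  out <- data.frame(lag_s = lags[keep] * frame_interval_s,
                    msd_um2 = msd[keep] / np[keep], n_pairs = np[keep])
  class(out) <- c("MSDProfile", "data.frame")
  out
}

#' Diffusion coefficient from an MSD profile
#'
#' Ordinary least squares on the 2nd, 3rd and 4th MSD points with a free
#' intercept (the intercept absorbs static localization noise, the rationale
#' for excluding the first lag); `D = slope / 4` for 2D motion.
#'
#' @param msd an [compute_msd()] profile with at least 4 lags.
#' @return list (D_um2_s, intercept_um2, fit).
#' @export
fit_diffusion <- function(msd) {
  if (nrow(msd) < 4) stop("need at least 4 MSD lags")
  if (!all(is.finite(msd$msd_um2[2:4]))) stop("non-finite MSD values")
  pts <- msd[2:4, ]
  fit <- lm(msd_um2 ~ lag_s, data = pts)
  list(D_um2_s = unname(coef(fit)[2]) / 4,
       intercept_um2 = unname(coef(fit)[1]), fit = fit)
}

#' Distance from an mRNA trajectory to the nearest condensate over time
#'
#' @param mrna_traj data.frame (frame, x_px, y_px).
#' @param condensate_trajs list of condensate trajectories (same columns).
#' @param pixel_size_nm pixel size.
#' @return data.frame (frame, dist_nm); frames where no condensate is present
#'   carry `NA`.
#' @export
distance_trace <- function(mrna_traj, condensate_trajs, pixel_size_nm) {
  cond_frames <- unique(unlist(lapply(condensate_trajs, `[[`, "frame")))
  common <- intersect(mrna_traj$frame, cond_frames)
  if (!length(common)) stop("no overlapping frames between mRNA and condensates")
  out <- data.frame(frame = mrna_traj$frame, dist_nm = NA_real_)
  for (i in seq_len(nrow(mrna_traj))) {
    f <- mrna_traj$frame[i]
    ds <- unlist(lapply(condensate_trajs, function(tr) {
      j <- match(f, tr$frame)
      if (is.na(j)) return(NULL)
      sqrt((tr$x_px[j] - mrna_traj$x_px[i])^2 +
           (tr$y_px[j] - mrna_traj$y_px[i])^2) * pixel_size_nm
    }))
    if (length(ds)) out$dist_nm[i] <- min(ds)
  }
  out
}

#' Detect binding events on a distance trace
#'
#' Hysteresis state machine: the particle enters the bound state after
#' `min_frames` consecutive samples below `r_on_nm` and leaves it after
#' `min_frames` consecutive samples above `r_off_nm`. Event boundaries are
#' the first frames of the triggering runs. Missing samples freeze the state.
#'
#' @param trace data.frame (frame, dist_nm) from [distance_trace()].
#' @param r_on_nm,r_off_nm hysteresis radii, `r_on < r_off`.
#' @param min_frames run length required to switch state.
#' @param frame_interval_s frame interval (seconds).
#' @return list with `events` (data.frame start_s, end_s, duration_s) and
#'   `summary` (n_events, median_dwell_s, fraction_transient the share of
#'   events shorter than 1 s).
#' @export
detect_binding_events <- function(trace, r_on_nm = 400, r_off_nm = 600,
                                  min_frames = 2, frame_interval_s) {
  if (!(r_on_nm < r_off_nm)) stop("need r_on < r_off (hysteresis)")
  d <- trace$dist_nm
  fr <- trace$frame
  empty <- list(events = data.frame(start_s = numeric(0), end_s = numeric(0),
                                    duration_s = numeric(0)),
                summary = list(n_events = 0L, median_dwell_s = NA_real_,
                               fraction_transient = NA_real_))
  if (all(is.na(d))) return(empty)
  bound <- FALSE
  run <- 0L; run_start <- NA_integer_
  ev_start <- NA_integer_
  starts <- ends <- integer(0)
  for (i in seq_along(d)) {
    if (is.na(d[i])) next
    if (!bound) {
      if (d[i] < r_on_nm) {
        run <- run + 1L
        if (run == 1L) run_start <- fr[i]
        if (run >= min_frames) {
          bound <- TRUE; ev_start <- run_start; run <- 0L
        }
      } else run <- 0L
    } else {
      if (d[i] > r_off_nm) {
        run <- run + 1L
        if (run == 1L) run_start <- fr[i]
        if (run >= min_frames) {
          bound <- FALSE
          starts <- c(starts, ev_start); ends <- c(ends, run_start)
          run <- 0L
        }
      } else run <- 0L
    }
  }
  if (bound) { # trailing open event, closed at the last sample
    starts <- c(starts, ev_start); ends <- c(ends, fr[max(which(!is.na(d)))] + 1L)
  }
  if (!length(starts)) return(empty)
  ev <- data.frame(start_s = (starts - 1) * frame_interval_s,
                   end_s = (ends - 1) * frame_interval_s)
  ev$duration_s <- ev$end_s - ev$start_s
  list(events = ev,
       summary = list(n_events = nrow(ev),
                      median_dwell_s = median(ev$duration_s),
                      fraction_transient = mean(ev$duration_s < 1)))
}
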