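# mRNA-condensate recruitment classification and statistics. Distances are
# centroid-to-centroid; thresholds are stored in nanometres and converted
# through the pixel size, with z separation counted in planes.

#' Nearest condensate for each spot
#'
#' For each spot, the planar (XY) distance to the globally nearest condensate
#' centroid and their z-plane separation. Equivalent to an exhaustive
#' spot-by-condensate scan.
#'
#' @param spots data.frame with x_px, y_px, z_index.
#' @param condensates data.frame with x, y, z_index.
#' @param pixel_size_nm pixel size for nm conversion; if `NULL`, d_xy_nm is
#'   `NA` and only d_xy_px is filled.
#' @return data.frame of class `RecruitmentRecords`: spot, condensate,
#'   d_xy_px, d_xy_nm, dz_planes, recruited (initialized `FALSE`). With no
#'   condensates, distances are infinite.
#' @export
nearest_condensate <- function(spots, condensates, pixel_size_nm = NULL) {
  n <- nrow(spots)
  if (n == 0 || nrow(condensates) == 0) {
    out <- data.frame(spot = seq_len(n), condensate = NA_integer_,
                      d_xy_px = rep(Inf, n), d_xy_nm = rep(Inf, n),
                      dz_planes = rep(NA_integer_, n), recruited = rep(FALSE, n))
    class(out) <- c("RecruitmentRecords", "data.frame")
    attr(out, "pixel_size_nm") <- pixel_size_nm
    return(out)
  }
  d2 <- outer(spots$x_px, condensates$x, `-`)^2 +
        outer(spots$y_px, condensates$y, `-`)^2
  k <- max.col(-d2, ties.method = "first")
  dpx <- sqrt(d2[cbind(seq_len(n), k)])
  out <- data.frame(
    spot = seq_len(n), condensate = k, d_xy_px = dpx,
    d_xy_nm = if (is.null(pixel_size_nm)) NA_real_ else dpx * pixel_size_nm,
    dz_planes = abs(spots$z_index - condensates$z_index[k]),
    recruited = FALSE)
  class(out) <- c("RecruitmentRecords", "data.frame")
  attr(out, "pixel_size_nm") <- pixel_size_nm
  out
}

#' Classify spots as recruited
#'
#' A spot is recruited iff its planar distance is strictly below
#' `d_thresh_nm` and its z separation is at most `z_thresh_planes` planes.
#'
#' @param records output of [nearest_condensate()].
#' @param d_thresh_nm planar threshold (default 330 nm, about 3 pixels).
#' @param z_thresh_planes maximal z-plane separation (default 2).
#' @return records with the `recruited` flag set.
#' @export
classify_recruited <- function(records, d_thresh_nm = 330, z_thresh_planes = 2) {
  stopifnot(d_thresh_nm > 0, z_thresh_planes >= 0)
  if (nrow(records) && all(is.na(records$d_xy_nm) & is.finite(records$d_xy_px)))
    stop("distances carry no nm scale; pixel_size_nm was missing")
  records$recruited <- !is.na(records$d_xy_nm) &
    records$d_xy_nm < d_thresh_nm &
    !is.na(records$dz_planes) & records$dz_planes <= z_thresh_planes
  records
}

#' Recruitment fraction of a cell
#'
#' Count mode: recruited / total spots. Amplitude mode: sum of amplitudes of
#' recruited spots over the sum over all spots — the estimator of choice when
#' several mRNAs can merge into one punctum.
#'
#' @param records classified [nearest_condensate()] records.
#' @param spots the matching spot table (needs `amplitude` for amplitude
#'   mode).
#' @param weight "amplitude" (default) or "count".
#' @return fraction in [0, 1].
#' @export
recruitment_fraction <- function(records, spots, weight = c("amplitude", "count")) {
  weight <- match.arg(weight)
  if (nrow(spots) == 0) stop("recruitment fraction undefined for zero spots")
  if (weight == "count") return(mean(records$recruited))
  sum(spots$amplitude[records$recruited]) / sum(spots$amplitude)
}

#' Pixel-signal fraction within a radius of condensates
#'
#' Fraction of total (in-mask) image signal lying inside the union of discs
#' of radius `r_nm` around condensate centroids, counting planes within
#' `z_thresh` steps of each condensate's plane.
#'
#' @param fish_image (Y, X, Z) array or matrix (already band-passed).
#' @param condensates data.frame with x, y, z_index.
#' @param r_nm disc radius (default 750 nm, about 7 pixels).
#' @param z_thresh z-plane tolerance.
#' @param cell_mask logical (Y, X) matrix; nonempty.
#' @param pixel_size_nm pixel size.
#' @return fraction in [0, 1] (0 with no condensates).
#' @export
signal_fraction_within_radius <- function(fish_image, condensates, r_nm = 750,
                                          z_thresh = 2, cell_mask,
                                          pixel_size_nm) {
  if (is.matrix(fish_image)) fish_image <- array(fish_image, c(dim(fish_image), 1))
  stopifnot(length(dim(fish_image)) == 3, any(cell_mask))
  nr <- dim(fish_image)[1]; nc <- dim(fish_image)[2]; nz <- dim(fish_image)[3]
  total <- sum(vapply(seq_len(nz), function(z) sum(fish_image[, , z][cell_mask]), 0))
  if (total <= 0) stop("zero total signal within the mask")
  if (nrow(condensates) == 0) return(0)
  r_px <- r_nm / pixel_size_nm
  jj <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  ii <- matrix(0:(nr - 1), nr, nc)
  inside <- 0
  for (z in seq_len(nz)) {
    sel <- abs(condensates$z_index - z) <= z_thresh
    if (!any(sel)) next
    un <- matrix(FALSE, nr, nc)
    for (k in which(sel))
      un <- un | ((jj - condensates$x[k])^2 + (ii - condensates$y[k])^2 <= r_px^2)
    inside <- inside + sum(fish_image[, , z][un & cell_mask])
  }
  inside / total
}

#' Estimated mRNA count per condensate
#'
#' Rounds the summed recruited amplitude per condensate by a unit
#' (single-molecule) amplitude; any condensate with at least one recruited
#' spot reports at least one mRNA.
#'
#' @param spots spot table with amplitudes.
#' @param records classified records.
#' @param unit_amplitude single-spot amplitude (> 0), typically the median
#'   amplitude of isolated spots.
#' @return data.frame (condensate, n_mrna).
#' @export
mrnas_per_condensate <- function(spots, records, unit_amplitude) {
  stopifnot(unit_amplitude > 0)
  rec <- records[records$recruited, , drop = FALSE]
  if (!nrow(rec)) return(data.frame(condensate = integer(0), n_mrna = integer(0)))
  agg <- tapply(spots$amplitude[rec$spot], rec$condensate, sum)
  data.frame(condensate = as.integer(names(agg)),
             n_mrna = pmax(1L, as.integer(round(agg / unit_amplitude))))
}

#' Per-cell recruitment summary
#'
#' Convenience wrapper producing the summary row exported to CSV by the CLI.
#'
#' @param cell_id identifier.
#' @param spots spot table.
#' @param records classified records.
#' @return one-row data.frame: cell_id, n_spots, n_recruited, frac_count,
#'   frac_amplitude.
#' @export
recruitment_summary <- function(cell_id, spots, records) {
  data.frame(cell_id = cell_id, n_spots = nrow(spots),
             n_recruited = sum(records$recruited),
             frac_count = recruitment_fraction(records, spots, "count"),
             frac_amplitude = recruitment_fraction(records, spots, "amplitude"))
}
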