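# Saturation-concentration estimation, condensate composition and a ternary
# regular-solution (Flory-Huggins) coexistence calculator. Components are
# ordered (solute 1, solute 2, solvent); chi is symmetric with zero diagonal
# and N gives polymerization sizes (solvent size 1).

#' Regular-solution parameters
#'
#' @param chi12,chi1s,chi2s pairwise interaction parameters (kT units).
#' @param N1,N2 polymerization sizes of the two solutes (>= 1).
#' @return list of class `RSParams` with the 3x3 chi matrix and sizes.
#' @export
rs_params <- function(chi12 = 0, chi1s = 0, chi2s = 0, N1 = 1, N2 = 1) {
  stopifnot(N1 >= 1, N2 >= 1)
  chi <- matrix(0, 3, 3)
  chi[1, 2] <- chi[2, 1] <- chi12
  chi[1, 3] <- chi[3, 1] <- chi1s
  chi[2, 3] <- chi[3, 2] <- chi2s
  structure(list(chi = chi, N = c(N1, N2, 1)), class = "RSParams")
}

# Entropy term with the phi log phi -> 0 limit.
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Regular-solution free energy per lattice site
#'
#' `f = phi1/N1 log phi1 + phi2/N2 log phi2 + phis log phis
#'    + chi12 phi1 phi2 + chi1s phi1 phis + chi2s phi2 phis` (kT units),
#' with `phis = 1 - phi1 - phi2`.
#'
#' @param phi1,phi2 solute volume fractions (vectorized); must satisfy
#'   `phi >= 0` and `phi1 + phi2 <= 1`.
#' @param params an [rs_params()].
#' @return free energy per site in kT.
#' @export
rs_free_energy <- function(phi1, phi2, params) {
  phis <- 1 - phi1 - phi2
  if (any(phi1 < 0 | phi2 < 0 | phis < -1e-12))
    stop("composition outside the simplex")
  phis <- pmax(phis, 0)
  chi <- params$chi; N <- params$N
  xlogx(phi1) / N[1] + xlogx(phi2) / N[2] + xlogx(phis) +
    chi[1, 2] * phi1 * phi2 + chi[1, 3] * phi1 * phis + chi[2, 3] * phi2 * phis
}

# Lower convex hull of (x, f(x)) on a 1D grid (Andrew monotone chain).
# Returns indices of hull vertices in increasing x.
lower_hull_1d <- function(x, f) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      # drop b if it lies above segment a-i
      if ((f[b] - f[a]) * (x[i] - x[a]) >= (f[i] - f[a]) * (x[b] - x[a]))
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Coexisting phases of the ternary regular solution
#'
#' Builds the lower convex hull of the free-energy surface sampled on a
#' regular simplex grid; hull facets whose vertices are farther apart than a
#' merge tolerance define tie simplices. The facet containing the overall
#' composition yields the coexisting phases and their lever-rule fractions.
#' An overall composition with `phi2 = 0` (or `phi1 = 0`) is reduced exactly
#' to the corresponding binary subsystem, since mass conservation forbids the
#' absent component in any phase.
#'
#' @param params an [rs_params()].
#' @param overall_phi c(phi1, phi2) of the parent mixture.
#' @param grid_n grid points per axis (>= 51); spacing is `1/(grid_n - 1)`.
#' @param merge_tol vertices closer than this (in composition space) are one
#'   phase; default 3 grid spacings.
#' @return list of class `RSCoexistence`: `phases` (data.frame phi1, phi2,
#'   fraction), `n_phases`, `grid_n`, `merge_tol`.
#' @export
rs_coexistence <- function(params, overall_phi, grid_n = 201, merge_tol = NULL) {
  if (grid_n < 51) stop("grid_n must be >= 51")
  stopifnot(length(overall_phi) == 2, all(overall_phi >= 0),
            sum(overall_phi) <= 1)
  h <- 1 / (grid_n - 1)
  if (is.null(merge_tol)) merge_tol <- 3 * h

  done <- function(phases) {
    phases$fraction <- phases$fraction / sum(phases$fraction)
    structure(list(phases = phases, n_phases = nrow(phases),
                   grid_n = grid_n, merge_tol = merge_tol),
              class = "RSCoexistence")
  }

  # exact binary reduction when one solute is absent overall
  if (overall_phi[2] == 0 || overall_phi[1] == 0) {
    j <- if (overall_phi[2] == 0) 1L else 2L
    c0 <- overall_phi[j]
    phi <- seq(0, 1, length.out = grid_n)
    f <- if (j == 1L) rs_free_energy(phi, 0, params) else rs_free_energy(0, phi, params)
    hull <- lower_hull_1d(phi, f)
    seg <- findInterval(c0, phi[hull], rightmost.closed = TRUE)
    a <- hull[seg]; b <- hull[min(seg + 1, length(hull))]
    mk <- function(p1) if (j == 1L) c(p1, 0) else c(0, p1)
    if (a == b || phi[b] - phi[a] <= merge_tol) {
      ph <- as.data.frame(rbind(mk(c0)))
      names(ph) <- c("phi1", "phi2"); ph$fraction <- 1
      return(done(ph))
    }
    lam <- (c0 - phi[a]) / (phi[b] - phi[a])
    ph <- as.data.frame(rbind(mk(phi[a]), mk(phi[b])))
    names(ph) <- c("phi1", "phi2"); ph$fraction <- c(1 - lam, lam)
    return(done(ph))
  }

  # ternary simplex grid
  ij <- expand.grid(i = 0:(grid_n - 1), j = 0:(grid_n - 1))
  ij <- ij[ij$i + ij$j <= grid_n - 1, ]
  p1 <- ij$i * h; p2 <- ij$j * h
  f <- rs_free_energy(p1, p2, params)
  faces <- cpp_lower_hull3(cbind(p1, p2, f))
  if (nrow(faces) == 0) stop("degenerate free-energy surface")

  # locate the facet containing overall_phi (2D barycentric test)
  q1 <- overall_phi[1]; q2 <- overall_phi[2]
  a1 <- p1[faces[, 1]]; a2 <- p2[faces[, 1]]
  b1 <- p1[faces[, 2]]; b2 <- p2[faces[, 2]]
  c1 <- p1[faces[, 3]]; c2 <- p2[faces[, 3]]
  det0 <- (b1 - a1) * (c2 - a2) - (c1 - a1) * (b2 - a2)
  w1 <- ((b1 - q1) * (c2 - q2) - (c1 - q1) * (b2 - q2)) / det0
  w2 <- ((c1 - q1) * (a2 - q2) - (a1 - q1) * (c2 - q2)) / det0
  w3 <- 1 - w1 - w2
  tol <- 1e-9
  hit <- which(is.finite(det0) & abs(det0) > 1e-14 &
               w1 >= -tol & w2 >= -tol & w3 >= -tol)
  if (!length(hit)) stop("overall composition not covered by the hull")
  k <- hit[1]
  vid <- faces[k, ]
  vp <- cbind(p1[vid], p2[vid])
  wts <- pmax(c(w1[k], w2[k], w3[k]), 0)

  # cluster the facet's vertices into phases (single linkage on merge_tol)
  d <- as.matrix(dist(vp))
  grp <- seq_len(3)
  for (i in 1:2) for (j in (i + 1):3)
    if (d[i, j] <= merge_tol) grp[grp == grp[j]] <- grp[i]
  ug <- unique(grp)
  ph <- do.call(rbind, lapply(ug, function(g) {
    sel <- grp == g
    wsum <- sum(wts[sel])
    if (wsum <= 0) wsum <- 1e-12
    data.frame(phi1 = sum(vp[sel, 1] * wts[sel]) / wsum,
               phi2 = sum(vp[sel, 2] * wts[sel]) / wsum,
               fraction = sum(wts[sel]))
  }))
  ph <- ph[ph$fraction > 1e-9, , drop = FALSE]
  done(ph)
}

#' @export
print.RSCoexistence <- function(x, ...) {
  cat("Regular-solution coexistence:", x$n_phases, "phase(s)\n")
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Dense-phase composition ratio
#'
#' Ratio `phi2 / phi1` in the dense phase (the phase with the largest total
#' solute fraction) of a two-phase mixture.
#'
#' @param params an [rs_params()].
#' @param overall_phi c(phi1, phi2).
#' @param ... passed to [rs_coexistence()].
#' @return ratio (>= 0; `Inf` if the dense phase contains no component 1).
#' @export
predict_dense_composition <- function(params, overall_phi, ...) {
  cx <- rs_coexistence(params, overall_phi, ...)
  if (cx$n_phases < 2)
    stop("overall composition lies in a single-phase region")
  dense <- cx$phases[which.max(cx$phases$phi1 + cx$phases$phi2), ]
  dense$phi2 / dense$phi1
}

#' Classify cells as clustered by condensate intensity
#'
#' @param condensate_total_intensity per-cell total condensate intensity.
#' @param floor detection floor (>= 0), e.g. the 99th percentile of the
#'   segmentation output on blank scenes.
#' @return logical vector.
#' @export
classify_clustered <- function(condensate_total_intensity, floor) {
  stopifnot(floor >= 0)
  condensate_total_intensity > floor
}

#' Saturation concentration from a per-cell expression scan
#'
#' Maximum-likelihood logistic fit
#' `P(clustered) = 1 / (1 + exp(-(log c - log csat) / w))`; `csat` is the
#' concentration at P = 0.5, with a percentile bootstrap CI.
#'
#' @param records data.frame with `c1` (cytoplasmic intensity, > 0) and
#'   `clustered` (logical).
#' @param n_boot bootstrap resamples for the CI.
#' @return list (csat, width, ci, fit).
#' @export
estimate_csat <- function(records, n_boot = 1000) {
  stopifnot(nrow(records) >= 20)
  if (length(unique(records$clustered)) < 2)
    stop("both clustered and unclustered cells are required (no transition)")
  est <- function(df) {
    fit <- suppressWarnings(glm(clustered ~ log(c1), family = binomial(), data = df))
    b <- coef(fit)
    if (!is.finite(b[2]) || b[2] <= 0) return(c(NA_real_, NA_real_))
    c(exp(-b[1] / b[2]), 1 / b[2])
  }
  e0 <- est(records)
  if (!is.finite(e0[1])) stop("logistic fit failed (degenerate transition)")
  bs <- replicate(n_boot, {
    df <- records[sample.int(nrow(records), replace = TRUE), ]
    if (length(unique(df$clustered)) < 2) NA_real_ else est(df)[1]
  })
  list(csat = e0[1], width = e0[2],
       ci = unname(quantile(bs, c(0.025, 0.975), na.rm = TRUE)))
}

#' Relative saturation-concentration shift between two populations
#'
#' `(csat_B - csat_A) / csat_A` with a paired-bootstrap CI; negative when
#' population B phase-separates at lower concentration.
#'
#' @param records_A,records_B per-cell scans as in [estimate_csat()].
#' @param n_boot bootstrap resamples.
#' @return list (shift, ci, csat_A, csat_B).
#' @export
csat_shift <- function(records_A, records_B, n_boot = 1000) {
  eA <- estimate_csat(records_A, n_boot = 2)
  eB <- estimate_csat(records_B, n_boot = 2)
  one <- function(df) {
    d <- df[sample.int(nrow(df), replace = TRUE), ]
    if (length(unique(d$clustered)) < 2) return(NA_real_)
    fit <- suppressWarnings(glm(clustered ~ log(c1), family = binomial(), data = d))
    b <- coef(fit)
    if (!is.finite(b[2]) || b[2] <= 0) return(NA_real_)
    exp(-b[1] / b[2])
  }
  bs <- replicate(n_boot, {
    a <- one(records_A); b <- one(records_B)
    (b - a) / a
  })
  list(shift = (eB$csat - eA$csat) / eA$csat,
       ci = unname(quantile(bs, c(0.025, 0.975), na.rm = TRUE)),
       csat_A = eA$csat, csat_B = eB$csat)
}

#' Condensate composition ratio between two channels
#'
#' Per condensate, the ratio of background-subtracted integrated intensities
#' (channel 2 over channel 1); records with non-positive channel-1 integral
#' are flagged and excluded from the cell summary (the intensity-weighted
#' mean ratio).
#'
#' @param regions `CondensateRegions` segmented on channel 1.
#' @param image2 registered channel-2 image.
#' @param bg1,bg2 per-pixel local background levels for the two channels.
#' @return list with `records` (condensate, intensity1, intensity2, ratio,
#'   ok) and `summary` (weighted mean ratio, n used).
#' @export
composition_ratio <- function(regions, image2, bg1 = 0, bg2 = 0) {
  i1 <- regions$integrated_intensity - bg1 * regions$area_px
  i2 <- region_intensity(regions, image2) - bg2 * regions$area_px
  ok <- i1 > 0
  rec <- data.frame(condensate = regions$label, intensity1 = i1,
                    intensity2 = i2, ratio = ifelse(ok, i2 / i1, NA_real_),
                    ok = ok)
  w <- i1[ok]
  list(records = rec,
       summary = list(
         mean_ratio = if (any(ok)) sum(rec$ratio[ok] * w) / sum(w) else NA_real_,
         n = sum(ok)))
}
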