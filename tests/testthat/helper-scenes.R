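# Shared fixture builders; everything is generated in code at test time.

# A clean (noise-free) image with point-sampled Gaussian spots.
spot_image <- function(x, y, amp, sigma = 1.3, size = c(40, 40), offset = 0) {
  condquant:::render_spots_2d(matrix(offset, size[1], size[2]), x, y, amp, sigma)
}

# Run the full smFISH recruitment pipeline on a generated scene and return
# the amplitude-weighted recruitment estimate plus the generator truth.
recruitment_pipeline <- function(scene) {
  st <- scene$stack
  cond <- condensates_3d(st, channel = 1)
  planes <- lapply(seq_len(condquant:::n_planes(st)), function(z) {
    img <- stack_plane(st, 2, z, 1)
    cand <- detect_spots(img)
    if (!nrow(cand))
      return(data.frame(x_px = numeric(0), y_px = numeric(0),
                        amplitude = numeric(0)))
    data.frame(x_px = cand$x, y_px = cand$y,
               amplitude = as.numeric(amplitude_maxmin(img, cand$x, cand$y)))
  })
  sp <- assign_z(planes)
  rec <- classify_recruited(nearest_condensate(sp, cond, pixel_size_nm = 110))
  list(est = recruitment_fraction(rec, sp, "amplitude"),
       truth = scene$truth$recruitment_fraction_true,
       spots = sp, condensates = cond, records = rec)
}

# Truth trajectory s of a rendered-free live movie as a linking-style frame.
truth_traj <- function(truth, s) {
  data.frame(frame = seq_len(dim(truth$mrna_xy_px)[1]),
             x_px = truth$mrna_xy_px[, s, 1],
             y_px = truth$mrna_xy_px[, s, 2])
}
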