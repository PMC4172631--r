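# Shared builders for the suite. A "flat field" is a 1-angle sinogram of
# n_bins identical rays with line integral p_value: one acquisition then
# yields n_bins i.i.d. count samples at the same photon mean, which is how
# the Monte-Carlo moment oracles get 1e5 draws from a single call.

flat_geometry <- function(n_bins = 1e5) {
  ct_geometry(n_angles = 1, n_bins = n_bins, bin_spacing_mm = 1,
              fov_mm = min(100, n_bins / 2))
}

flat_field <- function(n_bins = 1e5, p_value = 0) {
  g <- flat_geometry(n_bins)
  structure(list(p = matrix(p_value, 1, n_bins), geometry = g),
            class = "line_integral_sinogram")
}

water_disk_phantom <- function(matrix_size = 256, fov_mm = 380,
                               radius_mm = 100) {
  build_phantom(
    data.frame(cx_mm = 0, cy_mm = 0, a_mm = radius_mm, b_mm = radius_mm,
               angle_deg = 0, hu = 0, tissue = "water"),
    matrix_size = matrix_size, fov_mm = fov_mm)
}

# disk-interior mask with a margin, for ROI statistics on reconstructions
disk_mask <- function(n, pixel_size_mm, radius_mm) {
  ctr <- (seq_len(n) - 0.5) * pixel_size_mm - n * pixel_size_mm / 2
  xg <- matrix(ctr, n, n, byrow = TRUE)
  yg <- matrix(rev(ctr), n, n)
  xg^2 + yg^2 <= radius_mm^2
}

# expand per-observer 2x2 counts into paired rating vectors (truth, rating)
ratings_from_counts <- function(oo, os, so, ss) {
  list(truth = rep(c(1L, 2L), c(oo + os, so + ss)),
       rating = c(rep(c(1L, 2L), c(oo, os)), rep(c(1L, 2L), c(so, ss))))
}
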