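#' Ramp filter frequency response
#'
#' Returns the FBP filter transfer function sampled on the FFT frequency
#' grid of length `n_fft` for detector pitch `bin_spacing_mm`. `"ramp"` is
#' the ideal `|f|` response (zero at DC); `"ramp-hann"` multiplies it by a
#' Hann window rolling off to zero at the Nyquist frequency — the smooth
#' reconstruction kernel used for both arms of a comparison so the arms
#' stay commensurable.
#'
#' @param n_fft FFT length.
#' @param bin_spacing_mm detector pitch (mm).
#' @param kernel `"ramp"` or `"ramp-hann"`.
#' @return numeric vector of length `n_fft` (cycles/mm response).
#' @export
fbp_filter <- function(n_fft, bin_spacing_mm, kernel = c("ramp-hann", "ramp")) {
  kernel <- match.arg(kernel)
  f <- c(0:(n_fft / 2), -(n_fft / 2 - 1):-1) / (n_fft * bin_spacing_mm)
  h <- abs(f)
  if (kernel == "ramp-hann") {
    f_nyq <- 1 / (2 * bin_spacing_mm)
    h <- h * 0.5 * (1 + cos(pi * f / f_nyq))
  }
  h
}

#' Filtered back projection
#'
#' Standard parallel-beam FBP: each projection is ramp-filtered in the
#' frequency domain (zero-padded to the next power of two at least twice
#' the detector length) and backprojected with linear interpolation onto
#' the reconstruction grid.
#'
#' @param p a `line_integral_sinogram`.
#' @param kernel `"ramp"` (sharp) or `"ramp-hann"` (smooth, default).
#' @param matrix_size reconstruction grid edge count (default 256).
#' @param fov_mm reconstruction field of view (default the geometry's).
#' @return mu-grid matrix (1/mm), `matrix_size` square.
#' @export
fbp_reconstruct <- function(p, kernel = c("ramp-hann", "ramp"),
                            matrix_size = 256, fov_mm = NULL) {
  if (is.character(kernel) && length(kernel) == 1 &&
      !kernel %in% c("ramp-hann", "ramp")) {
    rlang::abort(sprintf("unknown kernel '%s'", kernel))
  }
  kernel <- match.arg(kernel)
  stopifnot(inherits(p, "line_integral_sinogram"))
  if (!all(is.finite(p$p))) rlang::abort("sinogram must be finite")
  g <- p$geometry
  fov_mm <- fov_mm %||% g$fov_mm
  n_fft <- next_pow2(2L * g$n_bins)
  h <- fbp_filter(n_fft, g$bin_spacing_mm, kernel)
  pad <- matrix(0, nrow(p$p), n_fft)
  pad[, seq_len(g$n_bins)] <- p$p
  # row-wise FFT filter: mvfft works on columns, so transpose
  ft <- stats::mvfft(t(pad)) * h
  q <- t(Re(stats::mvfft(ft, inverse = TRUE))) / n_fft
  # with the filter in cycles/mm, the ds from the forward-FT approximation
  # cancels against the 1/(n_fft*ds) frequency step, leaving only 1/n_fft
  q <- q[, seq_len(g$n_bins), drop = FALSE]
  cpp_back_project(q, g$angles_rad, g$bin_offsets_mm, as.integer(matrix_size),
                   fov_mm / matrix_size)
}

#' Reconstruct a count sinogram to a HU image
#'
#' Convenience chain: log transform, FBP, HU calibration; carries kernel,
#' source mAs and provenance so simulated and original images stay
#' distinguishable downstream.
#'
#' @param x a `count_sinogram`.
#' @param kernel reconstruction kernel (see [fbp_reconstruct()]).
#' @param matrix_size output grid edge count.
#' @param fov_mm output field of view (defaults to the geometry's).
#' @param mu_water water attenuation (1/mm) for the HU scale.
#' @return object of class `recon_image` (fields `hu`, `pixel_size_mm`,
#'   `kernel`, `source_mas`, `provenance`).
#' @export
reconstruct_image <- function(x, kernel = "ramp-hann", matrix_size = 256,
                              fov_mm = NULL, mu_water = 0.0203) {
  stopifnot(inherits(x, "count_sinogram"))
  fov_mm <- fov_mm %||% x$geometry$fov_mm
  mu <- fbp_reconstruct(counts_to_line_integrals(x), kernel = kernel,
                        matrix_size = matrix_size, fov_mm = fov_mm)
  recon_image(mu_to_hu(mu, mu_water), fov_mm / matrix_size, kernel,
              x$mas, if (x$provenance == "simulated") "simulated" else "original")
}

#' @rdname reconstruct_image
#' @param hu_grid HU matrix.
#' @param pixel_size_mm pixel edge length (mm).
#' @param source_mas tube load of the underlying acquisition.
#' @param provenance `"original"` or `"simulated"`.
#' @export
recon_image <- function(hu_grid, pixel_size_mm, kernel = "ramp-hann",
                        source_mas = NA_real_, provenance = "original") {
  stopifnot(is.matrix(hu_grid), all(is.finite(hu_grid)))
  structure(list(hu = hu_grid, pixel_size_mm = pixel_size_mm,
                 fov_mm = pixel_size_mm * nrow(hu_grid), kernel = kernel,
                 source_mas = source_mas, provenance = provenance),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %d x %d, kernel %s, %.4g mAs (%s)\n",
              nrow(x$hu), ncol(x$hu), x$kernel, x$source_mas, x$provenance))
  invisible(x)
}
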