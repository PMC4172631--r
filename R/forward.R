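#' Parallel-beam acquisition geometry
#'
#' Desk-scale 2D stand-in for a clinical multi-slice scanner: `n_angles`
#' projections uniformly spaced over 180 degrees and `n_bins` detector bins
#' at pitch `bin_spacing_mm`. The detector span must cover the FOV diagonal
#' so no ray through the object is truncated.
#'
#' @param n_angles projection count over 180 degrees (default 180).
#' @param n_bins detector bin count (default 384, i.e. 1.5x a 256 matrix).
#' @param bin_spacing_mm detector pitch in mm.
#' @param fov_mm field of view the geometry must cover; checked against the
#'   diagonal.
#' @return object of class `ct_geometry`.
#' @export
ct_geometry <- function(n_angles = 180, n_bins = 384,
                        bin_spacing_mm = 1.5 * 380 / 384, fov_mm = 380) {
  stopifnot(n_angles >= 1, n_bins >= 1, bin_spacing_mm > 0)
  if (n_bins * bin_spacing_mm < fov_mm * sqrt(2)) {
    rlang::abort("detector span does not cover the FOV diagonal")
  }
  structure(
    list(n_angles = as.integer(n_angles), n_bins = as.integer(n_bins),
         bin_spacing_mm = bin_spacing_mm, fov_mm = fov_mm,
         angles_rad = seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)],
         bin_offsets_mm =
           (seq_len(n_bins) - (n_bins + 1) / 2) * bin_spacing_mm),
    class = "ct_geometry"
  )
}

# Geometry matched to a phantom grid: 1.5x oversampled detector.
default_geometry <- function(phantom, n_angles = 180) {
  n <- nrow(phantom$hu)
  nb <- as.integer(ceiling(1.5 * n))
  ct_geometry(n_angles = n_angles, n_bins = nb,
              bin_spacing_mm = 1.5 * phantom$fov_mm / nb,
              fov_mm = phantom$fov_mm)
}

#' Electronic detector noise pool
#'
#' Additive, signal-independent readout noise. The distribution of real
#' detector electronics is markedly non-Gaussian, so noise values are
#' resampled from a pool of measured (or synthetically generated) samples
#' rather than drawn from a normal law. The synthetic default is a mixture
#' of a centered normal (90%) and a zero-mean shifted exponential (10%),
#' which is right-skewed; the pool is centered exactly and rescaled so its
#' standard deviation equals `sigma_e` exactly.
#'
#' @param sigma_e target standard deviation in detector counts (default 15).
#' @param n_samples pool size (default 1e5, minimum 1e4).
#' @param seed integer seed; the same seed yields the identical pool.
#' @param samples optional numeric vector of measured samples; when given it
#'   is centered and used as-is (no rescaling) and `sigma_e` is taken from
#'   the data.
#' @return object of class `electronic_noise_pool` with fields `samples`
#'   and `sigma_e`.
#' @export
electronic_noise_pool <- function(sigma_e = 15, n_samples = 1e5, seed = 1,
                                  samples = NULL) {
  if (is.null(samples)) {
    stopifnot(sigma_e > 0, n_samples >= 1e4)
    samples <- with_seed(seed, {
      comp <- stats::runif(n_samples) < 0.1
      beta <- 2 * sigma_e
      x <- stats::rnorm(n_samples, 0, sigma_e)
      x[comp] <- stats::rexp(sum(comp), rate = 1 / beta) - beta
      x
    })
    samples <- samples - mean(samples)
    samples <- samples * (sigma_e / stats::sd(samples))
  } else {
    if (!length(samples)) rlang::abort("empty electronic noise pool")
    samples <- samples - mean(samples)
    sigma_e <- stats::sd(samples)
    if (!isTRUE(sigma_e > 0)) rlang::abort("pool has zero variance")
  }
  structure(list(samples = samples, sigma_e = sigma_e),
            class = "electronic_noise_pool")
}

#' Resample electronic noise from a pool
#'
#' Draws `n` values with replacement from the pool, reproducibly under
#' `rng_seed`.
#'
#' @param pool an [electronic_noise_pool()].
#' @param n number of draws.
#' @param rng_seed integer seed.
#' @return numeric vector of length `n`.
#' @export
draw_electronic_noise <- function(pool, n, rng_seed) {
  if (!length(pool$samples)) rlang::abort("empty electronic noise pool")
  stopifnot(n >= 0)
  if (n == 0) return(numeric(0))
  with_seed(rng_seed,
            pool$samples[sample.int(length(pool$samples), n, replace = TRUE)])
}

#' Detector calibration model
#'
#' Holds the mean incident photon count per detector bin per mAs and the
#' electronic noise pool. The expected detected signal behind attenuation
#' `p` at tube load `mas` is `lambda = n0_per_mas * mas * exp(-p)`.
#'
#' @param n0_per_mas mean incident counts per bin per mAs (default 2e3, so
#'   2e5 counts at the 100 mAs reference load).
#' @param pool an [electronic_noise_pool()].
#' @param kv tube voltage label; the chain is monoenergetic so this is
#'   provenance only (fixed 100 kV in the study design).
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(n0_per_mas = 2e3,
                              pool = electronic_noise_pool(), kv = 100) {
  stopifnot(n0_per_mas > 0)
  structure(list(n0_per_mas = n0_per_mas, pool = pool, kv = kv),
            class = "calibration_model")
}

new_count_sinogram <- function(counts, mas, calib, geometry, provenance) {
  stopifnot(nrow(counts) == geometry$n_angles,
            ncol(counts) == geometry$n_bins, mas > 0)
  structure(list(counts = counts, mas = mas, calib = calib,
                 geometry = geometry, provenance = provenance),
            class = "count_sinogram")
}

#' @export
print.count_sinogram <- function(x, ...) {
  cat(sprintf("<count_sinogram> %d angles x %d bins, %.4g mAs (%s)\n",
              nrow(x$counts), ncol(x$counts), x$mas, x$provenance))
  invisible(x)
}

new_line_integral_sinogram <- function(p, geometry) {
  if (!all(is.finite(p))) rlang::abort("line integrals must be finite")
  structure(list(p = p, geometry = geometry),
            class = "line_integral_sinogram")
}

#' Forward projection of a phantom
#'
#' Computes attenuation line integrals `p = integral of mu along each ray`
#' (unitless) over a parallel-beam geometry with a Joseph-style
#' interpolating ray driver (bilinear sampling at pixel-size steps).
#'
#' @param phantom a [phantom_image()] (HU are converted internally) or a
#'   bare mu-matrix in 1/mm via `mu_grid`.
#' @param geometry a [ct_geometry()]; default matches the phantom.
#' @param mu_water linear attenuation of water (1/mm) for the HU
#'   conversion.
#' @param mu_grid optional mu matrix overriding the phantom's HU.
#' @return object of class `line_integral_sinogram` (fields `p`,
#'   `geometry`).
#' @export
radon_project <- function(phantom, geometry = NULL, mu_water = 0.0203,
                          mu_grid = NULL) {
  if (is.null(mu_grid)) {
    mu_grid <- hu_to_mu(phantom$hu, mu_water)
    px <- phantom$pixel_size_mm
    fov <- phantom$fov_mm
  } else {
    px <- phantom$pixel_size_mm
    fov <- px * nrow(mu_grid)
  }
  if (any(mu_grid < 0)) rlang::abort("mu grid must be nonnegative")
  geometry <- geometry %||% default_geometry(phantom)
  if (geometry$n_bins * geometry$bin_spacing_mm < fov * sqrt(2) - 1e-9) {
    rlang::abort("geometry does not cover the FOV")
  }
  p <- cpp_forward_project(mu_grid, px, geometry$angles_rad,
                           geometry$bin_offsets_mm)
  new_line_integral_sinogram(p, geometry)
}

#' Acquire a count-domain sinogram
#'
#' Simulates detection at tube load `mas`: per bin, a Poisson draw with
#' mean `lambda = n0_per_mas * mas * exp(-p)` plus one additive electronic
#' noise sample from the calibration pool. With `noiseless = TRUE` the
#' expectation `lambda` is returned exactly.
#'
#' @param p a `line_integral_sinogram`.
#' @param mas tube current-time product (mAs), > 0.
#' @param calib a [calibration_model()].
#' @param rng_seed integer seed; the same seed reproduces the acquisition
#'   bit for bit.
#' @param noiseless logical; skip both noise sources.
#' @return a `count_sinogram` with provenance `"acquired"`.
#' @export
acquire_counts <- function(p, mas, calib, rng_seed = 1, noiseless = FALSE) {
  stopifnot(inherits(p, "line_integral_sinogram"), mas > 0)
  lambda <- calib$n0_per_mas * mas * exp(-p$p)
  if (any(!is.finite(lambda)) || any(lambda > .Machine$integer.max)) {
    rlang::abort("expected counts overflow; check n0_per_mas and mas")
  }
  if (noiseless) {
    counts <- lambda
  } else {
    seeds <- derive_seeds(rng_seed, 2)
    counts <- with_seed(seeds[1],
                        matrix(stats::rpois(length(lambda), lambda),
                               nrow(lambda), ncol(lambda)))
    counts <- counts + matrix(
      draw_electronic_noise(calib$pool, length(lambda), seeds[2]),
      nrow(lambda), ncol(lambda))
  }
  new_count_sinogram(counts, mas, calib, p$geometry, "acquired")
}

#' Log transform counts to line integrals
#'
#' `p_hat = -log(max(counts, eps) / (n0_per_mas * mas))`. Counts at or
#' below zero (possible after electronic noise) are clipped at `eps` so
#' the logarithm stays finite.
#'
#' @param x a `count_sinogram` with calibration attached.
#' @param eps clip level in counts (default 0.1).
#' @return a `line_integral_sinogram`.
#' @export
counts_to_line_integrals <- function(x, eps = 0.1) {
  if (is.null(x$calib)) rlang::abort("sinogram has no calibration attached")
  flux <- x$calib$n0_per_mas * x$mas
  new_line_integral_sinogram(-log(pmax(x$counts, eps) / flux), x$geometry)
}
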