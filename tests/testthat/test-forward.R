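test_that("projection of a zero attenuation grid is a zero sinogram", {
  ph <- build_phantom(data.frame(), matrix_size = 64, fov_mm = 64)
  ph$hu[] <- -1000  # exact air everywhere
  p <- radon_project(ph, ct_geometry(10, 128, 1, 64))
  expect_true(all(p$p == 0))
})

test_that("an axis-aligned ray through one pixel integrates to mu * px", {
  mu1 <- matrix(0, 64, 64)
  mu1[32, 32] <- 0.02
  ph <- build_phantom(data.frame(), matrix_size = 64, fov_mm = 64)
  g <- ct_geometry(n_angles = 1, n_bins = 96, bin_spacing_mm = 1, fov_mm = 64)
  p <- radon_project(ph, g, mu_grid = mu1)
  # partition of unity along the ray: the detector profile sums to the
  # closed-form chord integral, and the peak bin carries it entirely when
  # the bin grid aligns with the pixel center
  expect_equal(sum(p$p[1, ]), 0.02 * 1, tolerance = 1e-12)
  expect_equal(max(p$p[1, ]), 0.02 * 1, tolerance = 1e-12)
})

test_that("per-angle detector sums agree across angles (mass conservation)", {
  sw <- default_swine_phantom(matrix_size = 128)
  p <- radon_project(sw$phantom)
  sums <- rowSums(p$p)
  expect_lt((max(sums) - min(sums)) / mean(sums), 0.01)
})

test_that("a geometry that does not cover the FOV is rejected", {
  expect_error(ct_geometry(n_angles = 10, n_bins = 64, bin_spacing_mm = 1,
                           fov_mm = 380), "diagonal")
  sw <- default_swine_phantom(matrix_size = 64)
  g_small <- ct_geometry(10, 128, 1, fov_mm = 64)
  expect_error(radon_project(sw$phantom, g_small), "FOV")
})

test_that("noiseless counts equal the Beer-Lambert expectation and scale with mAs", {
  p <- flat_field(100, p_value = 0)
  calib <- calibration_model(n0_per_mas = 2e3)
  c100 <- acquire_counts(p, 100, calib, noiseless = TRUE)
  expect_true(all(c100$counts == 2e3 * 100))
  expect_identical(c100$provenance, "acquired")
  c50 <- acquire_counts(p, 50, calib, noiseless = TRUE)
  expect_equal(c50$counts * 2, c100$counts)
  p1 <- flat_field(100, p_value = 1.7)
  expect_equal(acquire_counts(p1, 10, calib, noiseless = TRUE)$counts[1, 1],
               2e3 * 10 * exp(-1.7))
})

test_that("acquisition is bit-reproducible under a fixed seed", {
  p <- flat_field(1000)
  calib <- calibration_model(pool = electronic_noise_pool(seed = 3))
  a <- acquire_counts(p, 20, calib, rng_seed = 11)
  b <- acquire_counts(p, 20, calib, rng_seed = 11)
  d <- acquire_counts(p, 20, calib, rng_seed = 12)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, d$counts))
})

test_that("acquired counts have mean lambda and variance lambda + sigma_e^2", {
  # Monte-Carlo moment oracle: 1e5 i.i.d. bins at lambda = 1e4, sigma_e = 20
  n <- 1e5
  pool <- electronic_noise_pool(sigma_e = 20, seed = 2)
  calib <- calibration_model(n0_per_mas = 1e3, pool = pool)
  x <- acquire_counts(flat_field(n), 10, calib, rng_seed = 1)$counts
  lam <- 1e4
  expect_lt(abs(mean(x) - lam), 3 * sqrt((lam + 400) / n))
  expect_lt(abs(stats::var(as.vector(x)) / (lam + 400) - 1), 0.03)
})

test_that("log transform inverts the noiseless acquisition to 1e-12", {
  sw <- default_swine_phantom(matrix_size = 64)
  p <- radon_project(sw$phantom, ct_geometry(20, 96, 1.5 * 380 / 96, 380))
  calib <- calibration_model()
  s <- acquire_counts(p, 100, calib, noiseless = TRUE)
  expect_lt(max(abs(counts_to_line_integrals(s)$p - p$p)), 1e-12)
})

test_that("log transform fixed points and clipping contract hold", {
  calib <- calibration_model(n0_per_mas = 2e3)
  g <- flat_geometry(4)
  flux <- 2e3 * 10
  counts <- matrix(c(flux, flux / exp(1), 0, -5), 1, 4)
  x <- structure(list(counts = counts, mas = 10, calib = calib, geometry = g,
                      provenance = "acquired"), class = "count_sinogram")
  p <- counts_to_line_integrals(x, eps = 0.1)
  expect_equal(p$p[1, 1], 0)
  expect_equal(p$p[1, 2], 1)
  expect_equal(p$p[1, 3], -log(0.1 / flux))
  expect_equal(p$p[1, 4], -log(0.1 / flux))
  expect_true(all(is.finite(p$p)))
  x$calib <- NULL
  expect_error(counts_to_line_integrals(x), "calibration")
})

test_that("the electronic pool is zero-mean, sized, and non-Gaussian", {
  pool <- electronic_noise_pool(sigma_e = 15, n_samples = 2e4, seed = 4)
  expect_lt(abs(mean(pool$samples)), 0.01 * pool$sigma_e)
  expect_equal(stats::sd(pool$samples), 15)
  expect_gte(length(pool$samples), 1e4)
  skewness <- mean((pool$samples / 15)^3)
  expect_gt(abs(skewness), 0.2)  # the exponential component skews the mix
  expect_error(electronic_noise_pool(n_samples = 100), "1e4|10000|>=")
})

test_that("draw_electronic_noise resamples reproducibly with the pool's variance", {
  pool <- electronic_noise_pool(sigma_e = 15, seed = 8)
  expect_length(draw_electronic_noise(pool, 0, 1), 0)
  a <- draw_electronic_noise(pool, 1000, 5)
  expect_identical(a, draw_electronic_noise(pool, 1000, 5))
  big <- draw_electronic_noise(pool, 1e6, 6)
  expect_lt(abs(stats::var(big) / pool$sigma_e^2 - 1), 0.02)
  expect_true(all(big %in% pool$samples))
  empty <- pool; empty$samples <- numeric(0)
  expect_error(draw_electronic_noise(empty, 5, 1), "empty")
})
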