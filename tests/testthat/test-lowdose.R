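test_that("dose fraction a = 1 returns the input bit-exactly", {
  pool <- electronic_noise_pool(seed = 2)
  calib <- calibration_model(pool = pool)
  x <- acquire_counts(flat_field(5000), 50, calib, rng_seed = 3)
  y <- simulate_low_dose(x, dose_reduction_plan(50, 50, pool, rng_seed = 9))
  expect_identical(y$counts, x$counts)
  expect_identical(y$provenance, "simulated")
  expect_equal(y$mas, 50)
})

test_that("dose increase and mismatched pools are rejected", {
  pool <- electronic_noise_pool(seed = 2)
  calib <- calibration_model(pool = pool)
  x <- acquire_counts(flat_field(100), 50, calib, rng_seed = 3)
  expect_error(dose_reduction_plan(50, 60, pool), "higher dose")
  other <- electronic_noise_pool(sigma_e = 40, seed = 2)
  expect_error(
    simulate_low_dose(x, dose_reduction_plan(50, 10, other)), "pool")
  expect_error(
    simulate_low_dose(x, dose_reduction_plan(40, 10, pool)), "mAs")
})

test_that("simulated moments match a direct acquisition at the target dose", {
  # conditional-variance identity, Monte-Carlo over 1e5 i.i.d. bins:
  # lambda = 1e4, sigma_e = 20, a = 0.1 -> E[Y] = 1e3, Var(Y) = 1e3 + 400
  n <- 1e5
  pool <- electronic_noise_pool(sigma_e = 20, seed = 5)
  calib <- calibration_model(n0_per_mas = 1e3, pool = pool)
  x <- acquire_counts(flat_field(n), 10, calib, rng_seed = 21)
  y <- simulate_low_dose(x, dose_reduction_plan(10, 1, pool, rng_seed = 22))
  d <- acquire_counts(flat_field(n), 1, calib, rng_seed = 23)
  expect_lt(abs(mean(y$counts) - 1e3), 3 * sqrt(1400 / n))
  expect_lt(abs(stats::var(as.vector(y$counts)) / 1400 - 1), 0.03)
  # and the direct acquisition agrees with the same oracle
  expect_lt(abs(mean(d$counts) - 1e3), 3 * sqrt(1400 / n))
  expect_lt(abs(stats::var(as.vector(d$counts)) / 1400 - 1), 0.03)
})

test_that("target moments do not depend on the source dose", {
  n <- 1e5
  pool <- electronic_noise_pool(sigma_e = 20, seed = 5)
  calib <- calibration_model(n0_per_mas = 1e3, pool = pool)
  x100 <- acquire_counts(flat_field(n), 10, calib, rng_seed = 31)
  x200 <- acquire_counts(flat_field(n), 20, calib, rng_seed = 32)
  y1 <- simulate_low_dose(x100, dose_reduction_plan(10, 1, pool, rng_seed = 33))
  y2 <- simulate_low_dose(x200, dose_reduction_plan(20, 1, pool, rng_seed = 34))
  for (y in list(y1, y2)) {
    expect_lt(abs(mean(y$counts) - 1e3), 3 * sqrt(1400 / n))
    expect_lt(abs(stats::var(as.vector(y$counts)) / 1400 - 1), 0.03)
  }
})

test_that("the binomial-thinning branch passes the same moment oracle", {
  # photon-starved regime: lambda = 12 so a*X sits below the default
  # threshold of 20 and the thinning branch is exercised
  n <- 1e5
  pool <- electronic_noise_pool(sigma_e = 2, seed = 6)
  calib <- calibration_model(n0_per_mas = 1.2, pool = pool)
  x <- acquire_counts(flat_field(n), 10, calib, rng_seed = 41)
  y <- simulate_low_dose(x, dose_reduction_plan(10, 5, pool, rng_seed = 42))
  target_var <- 6 + pool$sigma_e^2
  expect_lt(abs(mean(y$counts) - 6), 4 * sqrt(target_var / n))
  expect_lt(abs(stats::var(as.vector(y$counts)) / target_var - 1), 0.05)
})

test_that("electronic noise keeps simulated variance above the Poisson floor", {
  n <- 1e5
  pool <- electronic_noise_pool(sigma_e = 10, seed = 7)
  calib <- calibration_model(n0_per_mas = 2, pool = pool)
  x <- acquire_counts(flat_field(n), 10, calib, rng_seed = 51)
  y <- simulate_low_dose(x, dose_reduction_plan(10, 1, pool, rng_seed = 52))
  poisson_floor <- mean(y$counts)  # a*lambda
  expect_gt(stats::var(as.vector(y$counts)), poisson_floor + 0.5 * 100)
})

test_that("simulate_series yields one independent simulation per target", {
  pool <- electronic_noise_pool(seed = 2)
  calib <- calibration_model(pool = pool)
  x <- acquire_counts(flat_field(2000), 100, calib, rng_seed = 3)
  series <- simulate_series(x, c(80, 60, 40, 20, 10), seed = 4)
  expect_named(series, paste0("mas_", c(80, 60, 40, 20, 10)))
  expect_equal(unname(vapply(series, function(s) s$mas, numeric(1))),
               c(80, 60, 40, 20, 10))
  expect_true(all(vapply(series, function(s) s$provenance == "simulated",
                         logical(1))))
  # independent streams: sibling simulations differ
  expect_false(identical(series[[1]]$counts / 80, series[[2]]$counts / 60))
  # determinism under the master seed
  series2 <- simulate_series(x, c(80, 60, 40, 20, 10), seed = 4)
  expect_identical(series[[3]]$counts, series2[[3]]$counts)
  expect_length(simulate_series(x, numeric(0), seed = 1), 0)
  expect_error(simulate_series(x, c(50, 100), seed = 1), "below")
})
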