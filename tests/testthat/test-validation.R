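test_that("roi_stats returns mean and n-1 standard deviation over the mask", {
  hu <- matrix(50, 64, 64)
  im <- recon_image(hu, pixel_size_mm = 1, source_mas = 100)
  roi <- tibble::tibble(tissue = "muscle", roi_id = 1L, cx_mm = 0, cy_mm = 0,
                        area_mm2 = 50)
  st <- roi_stats(im, roi)
  expect_equal(st$mean_hu, 50)
  expect_equal(st$sd_hu, 0)
  expect_equal(st$dose_mas, 100)
  expect_equal(st$n_px, 50L)  # 1 mm pixels: 50 mm^2 is 50 pixels
})

test_that("roi noise recovers the generating sd on i.i.d. normal pixels", {
  set.seed(123)
  n <- 200
  hu <- matrix(stats::rnorm(n * n, 50, 30), n, n)
  im <- recon_image(hu, pixel_size_mm = 1)
  roi <- tibble::tibble(tissue = "muscle", roi_id = 1L, cx_mm = 0, cy_mm = 0,
                        area_mm2 = 1e4)  # ~1e4 pixels
  st <- roi_stats(im, roi)
  expect_lt(abs(st$sd_hu / 30 - 1), 0.03)
  expect_lt(abs(st$mean_hu - 50), 3 * 30 / sqrt(1e4))
})

test_that("degenerate ROIs are rejected", {
  im <- recon_image(matrix(0, 16, 16), pixel_size_mm = 1)
  out <- tibble::tibble(tissue = "x", roi_id = 1L, cx_mm = 7.9, cy_mm = 0,
                        area_mm2 = 50)
  expect_error(roi_stats(im, out), "inside")
  expect_error(roi_stats(im, out[0, ]), "no ROIs")
})

test_that("percent discrepancy matches the reported original/simulated pairs", {
  expect_equal(percent_discrepancy(5, 5), 0)
  # 10 mAs noise pair 68.4 (original) vs 68.7 (simulated)
  expect_equal(percent_discrepancy(68.7, 68.4), 0.4386, tolerance = 1e-4)
  # 80 mAs noise pair 21.0 vs 20.8
  expect_equal(percent_discrepancy(20.8, 21.0), -0.9524, tolerance = 1e-4)
  expect_error(percent_discrepancy(1, 0), "undefined")
  # the formula is asymmetric in its arguments by design
  expect_equal(percent_discrepancy(2, 4), -50)
  expect_equal(percent_discrepancy(4, 2), 100)
})

test_that("paired mean-difference CI matches the textbook t computation", {
  expect_equal(mean_difference_ci(c(3, 3, 3), c(3, 3, 3)),
               tibble::tibble(mean_diff = 0, ci_low = 0, ci_high = 0, n = 3L))
  sym <- mean_difference_ci(c(0, 0, 0), c(-1, 0, 1))
  expect_equal(sym$mean_diff, 0)
  expect_equal(sym$ci_low, -sym$ci_high)
  # 10 fixed pairs, hand-computed Student-t interval
  orig <- c(21.0, 24.2, 29.0, 42.9, 68.4, 36.4, 27.0, 20.4, 70.3, 108.3)
  sim <- c(20.8, 23.9, 28.3, 42.5, 68.7, 38.7, 27.1, 20.5, 68.7, 109.9)
  d <- sim - orig
  half <- stats::qt(0.975, 9) * stats::sd(d) / sqrt(10)
  ci <- mean_difference_ci(orig, sim)
  expect_equal(ci$mean_diff, mean(d))
  expect_equal(ci$ci_low, mean(d) - half, tolerance = 1e-12)
  expect_equal(ci$ci_high, mean(d) + half, tolerance = 1e-12)
  expect_error(mean_difference_ci(1, 1), "2 pairs")
  expect_error(mean_difference_ci(c(1, 2), 1), "lengths")
})

test_that("paired t-test matches the t CDF and is antisymmetric", {
  x <- c(1, 2, 3, 4)
  expect_equal(paired_t_test(x, x), tibble::tibble(t = 0, df = 3, p = 1))
  a <- c(12.1, 9.8, 15.3, 11.0, 13.7, 10.2)
  b <- c(11.4, 10.1, 14.2, 11.9, 12.8, 10.9)
  res <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (stats::sd(d) / sqrt(6))
  expect_equal(res$t, t_hand)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), 5))
  swapped <- paired_t_test(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  expect_error(paired_t_test(a, b[-1]), "equal length")
})

test_that("observer summary reproduces the four-radiologist totals", {
  tabs <- swine_observer_tables()
  s <- observer_summary(tabs)
  expect_equal(s$n_total, 640)
  expect_equal(s$n_correct, 323)
  expect_equal(s$n_orig_correct, 160)
  expect_equal(s$n_sim_correct, 163)
  expect_equal(s$n_incorrect, 317)
  expect_equal(s$n_sim_rated_orig, 157)
  expect_equal(s$n_orig_rated_sim, 160)
  expect_equal(s$p_correct, 323 / 640)
})

test_that("observer summary is permutation-invariant and additive", {
  tabs <- swine_observer_tables()
  perm <- tabs[c(3, 1, 4, 2), ]
  expect_equal(observer_summary(perm), observer_summary(tabs))
  part1 <- observer_summary(tabs[1:2, ])
  part2 <- observer_summary(tabs[3:4, ])
  whole <- observer_summary(tabs)
  for (col in c("n_total", "n_correct", "n_incorrect", "n_orig_correct",
                "n_sim_correct", "n_sim_rated_orig", "n_orig_rated_sim")) {
    expect_equal(part1[[col]] + part2[[col]], whole[[col]])
  }
  zero <- tibble::tibble(observer = 1L, oo = 0L, os = 0L, so = 0L, ss = 0L)
  zs <- observer_summary(zero)
  expect_equal(zs$n_correct, 0)
  expect_true(is.nan(zs$p_correct))
  bad <- zero; bad$oo <- -1L
  expect_error(observer_summary(bad), "negative")
})

test_that("Cohen's kappa matches brute-force p_o/p_e computations", {
  expect_equal(cohen_kappa(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  # one rater constant, the other balanced: p_o = 0.5 = p_e -> 0
  expect_equal(cohen_kappa(c(1, 2, 1, 2), c(1, 1, 1, 1)), 0)
  # agreement table {a=40, b=10, c=10, d=40}: p_o = 0.8, p_e = 0.5
  ra <- rep(c(1, 1, 2, 2), c(40, 10, 10, 40))
  rb <- rep(c(1, 2, 1, 2), c(40, 10, 10, 40))
  expect_equal(cohen_kappa(ra, rb), (0.8 - 0.5) / (1 - 0.5))
  expect_error(cohen_kappa(c(1, 2), c(1)), "equal length")
})

test_that("kappa stays in [-1, 1] and is invariant under relabeling", {
  set.seed(42)
  for (i in 1:25) {
    a <- sample(1:2, 30, replace = TRUE)
    b <- sample(1:2, 30, replace = TRUE)
    k <- cohen_kappa(a, b)
    expect_gte(k, -1)
    expect_lte(k, 1)
    expect_equal(cohen_kappa(3 - a, 3 - b), k)
    # brute force from the contingency counts
    n11 <- sum(a == 1 & b == 1); n22 <- sum(a == 2 & b == 2)
    p_o <- (n11 + n22) / 30
    p_e <- (sum(a == 1) * sum(b == 1) + sum(a == 2) * sum(b == 2)) / 900
    expect_equal(k, (p_o - p_e) / (1 - p_e))
  }
  expect_equal(cohen_kappa(rep(1, 5), rep(1, 5)), 1)  # p_e = 1, p_o = 1
})

test_that("chance-level binomial test matches the exact tail sum", {
  expect_equal(chance_level_test(5, 10), 1)
  p <- chance_level_test(323, 640)
  expect_gt(p, 0.05)
  # brute-force two-sided exact p: sum of all outcomes as or less likely
  pmf <- stats::dbinom(0:640, 640, 0.5)
  expect_equal(p, sum(pmf[pmf <= stats::dbinom(323, 640, 0.5) * (1 + 1e-7)]))
  expect_lt(chance_level_test(640, 640), 1e-9)
})

test_that("CTDI scales linearly in mAs", {
  expect_equal(ctdi_scale(4.4, 100, 10), 0.44)
  expect_equal(ctdi_scale(4.4, 100, 100), 4.4)
  expect_equal(ctdi_scale(4.4, 100, 50), 2.2)
  expect_error(ctdi_scale(-1, 100, 10), "positive")
  expect_error(ctdi_scale(4.4, 0, 10), "positive")
})
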