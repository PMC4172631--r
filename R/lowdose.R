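#' Dose reduction plan
#'
#' Captures the target of a sinogram-domain dose reduction: the dose
#' fraction `a = mas_target / mas_source` (photon fluence, and hence dose,
#' scales linearly with mAs at fixed kV), the electronic noise pool used
#' for the injected readout term, and the seed.
#'
#' @param mas_source source tube load (mAs).
#' @param mas_target target tube load, `0 < mas_target <= mas_source`.
#' @param pool an [electronic_noise_pool()]; must describe the same
#'   electronics as the source acquisition.
#' @param rng_seed integer seed.
#' @param thinning_threshold photon-count level below which the Gaussian
#'   photonic increment is replaced by binomial thinning (default 20; see
#'   [simulate_low_dose()]).
#' @return object of class `dose_reduction_plan` with the dose fraction in
#'   `$a`.
#' @export
dose_reduction_plan <- function(mas_source, mas_target,
                                pool = electronic_noise_pool(),
                                rng_seed = 1, thinning_threshold = 20) {
  a <- mas_target / mas_source
  if (!isTRUE(a > 0 && a <= 1)) {
    rlang::abort("cannot simulate a higher dose: need 0 < mas_target <= mas_source")
  }
  structure(list(a = a, mas_source = mas_source, mas_target = mas_target,
                 pool = pool, rng_seed = as.integer(rng_seed),
                 thinning_threshold = thinning_threshold),
            class = "dose_reduction_plan")
}

#' Simulate a lower-dose acquisition from a high-dose sinogram
#'
#' The core noise-insertion method. Per detector bin, the simulated
#' low-dose count is
#'
#' `Y = a*X + sqrt(a*(1-a)*max(X, 0)) * g + sqrt(1-a^2) * e`
#'
#' with `X` the measured high-dose count, `a` the dose fraction, `g` a
#' zero-mean unit-variance photonic increment and `e` resampled from the
#' electronic noise pool. By the conditional-variance identity (law of
#' total variance) the moments come out as `E[Y] = a*lambda` and
#' `Var(Y) = a*lambda + sigma_e^2` where `lambda` is the true photon mean
#' of the source scan — exactly the moments of a genuine acquisition at
#' `a * mas_source`, with no assumption that the source scan is noiseless
#' and no dependence on the source noise level. The electronic coefficient
#' `sqrt(1-a^2)` makes the carried-over source electronic variance
#' (`a^2 * sigma_e^2`) plus the injected term total `sigma_e^2` exactly.
#'
#' Where the expected low-dose photon count `a*X` falls below
#' `plan$thinning_threshold` the Gaussian increment is a poor model of
#' photon statistics and the photonic part is generated by binomial
#' thinning instead: `Y = Binomial(round(max(X, 0)), a) + sqrt(1-a^2)*e`,
#' which satisfies the same first and second moments. With `a = 1` both
#' noise coefficients vanish and `Y = X` bit-exactly.
#'
#' @param x a `count_sinogram` at `plan$mas_source`.
#' @param plan a [dose_reduction_plan()].
#' @return a `count_sinogram` at `plan$mas_target` with provenance
#'   `"simulated"`.
#' @export
simulate_low_dose <- function(x, plan) {
  stopifnot(inherits(x, "count_sinogram"),
            inherits(plan, "dose_reduction_plan"))
  if (!isTRUE(all.equal(plan$mas_source, x$mas))) {
    rlang::abort("plan.mas_source does not match the sinogram's mAs")
  }
  if (!is.null(x$calib) &&
      !isTRUE(all.equal(plan$pool$sigma_e, x$calib$pool$sigma_e))) {
    rlang::abort("electronic pool does not match the acquisition calibration")
  }
  a <- plan$a
  X <- x$counts
  if (a == 1) {
    return(new_count_sinogram(X, plan$mas_target, x$calib, x$geometry,
                              "simulated"))
  }
  Xc <- pmax(X, 0)
  seeds <- derive_seeds(plan$rng_seed, 3)
  thin <- a * Xc < plan$thinning_threshold
  Y <- numeric(length(X))
  with_seed(seeds[1], {
    ng <- sum(!thin)
    if (ng) {
      Y[!thin] <- a * X[!thin] +
        sqrt(a * (1 - a) * Xc[!thin]) * stats::rnorm(ng)
    }
  })
  with_seed(seeds[2], {
    nt <- sum(thin)
    if (nt) {
      # binomial thinning keeps counts integer-valued and nonnegative in the
      # photon-starved regime; moments match the Gaussian branch
      Y[thin] <- stats::rbinom(nt, round(Xc[thin]), a) +
        a * (X[thin] - round(Xc[thin]))
    }
  })
  e <- draw_electronic_noise(plan$pool, length(X), seeds[3])
  Y <- matrix(Y + sqrt(1 - a^2) * e, nrow(X), ncol(X))
  new_count_sinogram(Y, plan$mas_target, x$calib, x$geometry, "simulated")
}

#' Simulate a ladder of lower doses from one parent scan
#'
#' Mirrors the study design: a single high-dose parent acquisition is the
#' base for independent simulations at each target mAs, each with its own
#' seeded stream derived from `seed`.
#'
#' @param x a `count_sinogram` (the parent scan).
#' @param targets numeric vector of target mAs, all strictly below
#'   `x$mas` (the study ladder was 80, 60, 40, 20, 10 from a 100 mAs
#'   parent).
#' @param pool electronic noise pool (defaults to the acquisition's).
#' @param seed integer master seed.
#' @return named list of `count_sinogram`s, one per target.
#' @export
simulate_series <- function(x, targets, pool = NULL, seed = 1) {
  stopifnot(inherits(x, "count_sinogram"))
  if (!length(targets)) return(stats::setNames(list(), character()))
  if (any(targets >= x$mas)) {
    rlang::abort("all targets must be below the source mAs")
  }
  pool <- pool %||% x$calib$pool
  seeds <- derive_seeds(seed, length(targets))
  out <- purrr::map2(targets, seeds, function(tm, s) {
    simulate_low_dose(x, dose_reduction_plan(x$mas, tm, pool, rng_seed = s))
  })
  stats::setNames(out, paste0("mas_", targets))
}
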