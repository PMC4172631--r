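#' Observer-study confusion tables from the swine validation study
#'
#' Four radiologists each rated 160 images (80 original, 80 simulated) as
#' original or simulated. Cell convention as in [observer_summary()]:
#' `oo`/`os` originals rated original/simulated, `so`/`ss` simulations
#' rated original/simulated.
#'
#' @return tibble with one row per observer.
#' @export
swine_observer_tables <- function() {
  tibble::tribble(
    ~observer, ~oo, ~os, ~so, ~ss,
    1L, 37L, 43L, 42L, 38L,
    2L, 35L, 45L, 38L, 42L,
    3L, 42L, 38L, 39L, 41L,
    4L, 46L, 34L, 38L, 42L
  )
}

#' Regional image-noise table from the swine validation study
#'
#' ROI noise (HU standard deviation) by anatomical region, arm and dose
#' level, for the original scans and the simulations derived from the
#' 100 mAs parent scan.
#'
#' @return long tibble with columns `anatomy`, `arm`, `dose_mas`, `sd_hu`.
#' @export
swine_regional_noise <- function() {
  wide <- tibble::tribble(
    ~anatomy,           ~arm,         ~`80`, ~`60`, ~`40`, ~`20`, ~`10`,
    "shoulder girdle",  "original",   36.4,  38.2,  68.7,  117.6, 174.3,
    "shoulder girdle",  "simulation", 38.7,  40.2,  68.7,  115.0, 173.2,
    "dorsum",           "original",   27.0,  27.9,  36.6,  57.2,  108.3,
    "dorsum",           "simulation", 27.1,  28.8,  33.7,  58.8,  109.9,
    "abdominal wall",   "original",   20.4,  24.2,  29.5,  32.2,  66.3,
    "abdominal wall",   "simulation", 20.5,  25.5,  28.7,  36.2,  65.3,
    "pelvis",           "original",   70.3,  76.7,  94.1,  134.0, 206.3,
    "pelvis",           "simulation", 68.7,  77.5,  98.5,  130.4, 204.5
  )
  tidyr::pivot_longer(wide, cols = c("80", "60", "40", "20", "10"),
                      names_to = "dose_mas", values_to = "sd_hu") |>
    dplyr::mutate(dose_mas = as.numeric(.data$dose_mas))
}

#' Fabricate per-image rating vectors consistent with observer tables
#'
#' The published study reports only the per-observer 2x2 confusion counts,
#' not the image-by-image ratings, so pairwise agreement statistics cannot
#' be recovered exactly. This helper fabricates synthetic rating vectors
#' whose per-observer marginals match the tables exactly (each observer
#' assigns their rated-original quota to the first images of each truth
#' block); kappa computed on these vectors exercises the code path, it does
#' not reproduce the published pairwise kappas.
#'
#' @param tables observer tables as from [swine_observer_tables()].
#' @param n_orig,n_sim images of each truth class shown to every observer.
#' @return tibble with `image`, `truth` (1 = original, 2 = simulated) and
#'   one rating column per observer (`obs_<id>`).
#' @export
observer_rating_vectors <- function(tables = swine_observer_tables(),
                                    n_orig = 80, n_sim = 80) {
  tables <- as.data.frame(tables)
  stopifnot(all(tables$oo + tables$os == n_orig),
            all(tables$so + tables$ss == n_sim))
  out <- tibble::tibble(
    image = seq_len(n_orig + n_sim),
    truth = rep(c(1L, 2L), c(n_orig, n_sim))
  )
  for (i in seq_len(nrow(tables))) {
    r <- c(rep(c(1L, 2L), c(tables$oo[i], tables$os[i])),
           rep(c(1L, 2L), c(tables$so[i], tables$ss[i])))
    out[[paste0("obs_", tables$observer[i])]] <- r
  }
  out
}

#' Write the packaged validation fixtures to a directory
#'
#' Writes the observer confusion tables and the regional noise table as
#' CSV, a small synthetic electronic-noise pool, the default phantom (HU
#' and label grids as single-slice NIfTI with a JSON sidecar) and its ROI
#' table. Reruns overwrite deterministically.
#'
#' @param output_dir target directory (created if missing).
#' @param seed seed for the pool and phantom.
#' @return invisibly, the vector of files written.
#' @export
make_fixtures <- function(output_dir, seed = 1) {
  ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    rlang::abort(sprintf("cannot create directory '%s'", output_dir))
  }
  if (file.access(output_dir, 2) != 0) {
    rlang::abort(sprintf("directory '%s' is not writable", output_dir))
  }
  f1 <- file.path(output_dir, "observer_tables.csv")
  utils::write.csv(swine_observer_tables(), f1, row.names = FALSE)
  f2 <- file.path(output_dir, "regional_noise.csv")
  utils::write.csv(swine_regional_noise(), f2, row.names = FALSE)
  f3 <- file.path(output_dir, "electronic_pool.csv")
  pool <- electronic_noise_pool(sigma_e = 15, n_samples = 1e4, seed = seed)
  write_noise_pool(pool, f3)
  sw <- default_swine_phantom(seed)
  f4 <- write_phantom(sw$phantom, file.path(output_dir, "swine_phantom"))
  f5 <- file.path(output_dir, "swine_rois.csv")
  utils::write.csv(sw$rois, f5, row.names = FALSE)
  invisible(c(f1, f2, f3, f4, f5))
}
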