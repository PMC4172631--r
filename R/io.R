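#' Read and write phantoms as NIfTI with a JSON sidecar
#'
#' The HU grid and the tissue-label grid are written as single-slice NIfTI
#' files (`<stem>.nii.gz`, `<stem>_labels.nii.gz`); pixel size and the
#' tissue-name map go into `<stem>.json`.
#'
#' @param phantom a [phantom_image()].
#' @param stem output path without extension.
#' @return `write_phantom` invisibly returns the files written;
#'   `read_phantom` returns the [phantom_image()].
#' @export
write_phantom <- function(phantom, stem) {
  f_hu <- paste0(stem, ".nii.gz")
  f_lab <- paste0(stem, "_labels.nii.gz")
  f_js <- paste0(stem, ".json")
  RNifti::writeNifti(
    RNifti::asNifti(phantom$hu,
                    pixdim = rep(phantom$pixel_size_mm, 2)), f_hu)
  RNifti::writeNifti(
    RNifti::asNifti(phantom$labels + 0,
                    pixdim = rep(phantom$pixel_size_mm, 2)), f_lab)
  jsonlite::write_json(
    list(pixel_size_mm = phantom$pixel_size_mm, fov_mm = phantom$fov_mm,
         tissue_names = as.list(phantom$tissue_names)),
    f_js, auto_unbox = TRUE, digits = NA)
  invisible(c(f_hu, f_lab, f_js))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  img <- RNifti::readNifti(paste0(stem, ".nii.gz"))
  hu <- matrix(as.numeric(img), dim(img)[1], dim(img)[2])
  labimg <- RNifti::readNifti(paste0(stem, "_labels.nii.gz"))
  lab <- matrix(as.integer(round(as.numeric(labimg))),
                dim(labimg)[1], dim(labimg)[2])
  phantom_image(hu, meta$pixel_size_mm, lab,
                unlist(meta$tissue_names) %||% integer())
}

#' Read and write count sinograms as CSV with a JSON sidecar
#'
#' The count matrix (angle rows x bin columns) is written headerless to
#' `<stem>.csv`; acquisition metadata (mAs, n0_per_mas, sigma_e, geometry,
#' provenance) goes into `<stem>.json`. A pool read back from the sidecar
#' carries only `sigma_e`; attach a full pool for further simulation.
#'
#' @param x a `count_sinogram`.
#' @param stem output path without extension.
#' @param pool optional [electronic_noise_pool()] to attach on read.
#' @return `write_sinogram` invisibly returns the files written;
#'   `read_sinogram` returns the `count_sinogram`.
#' @export
write_sinogram <- function(x, stem) {
  f_csv <- paste0(stem, ".csv")
  f_js <- paste0(stem, ".json")
  utils::write.table(x$counts, f_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  g <- x$geometry
  jsonlite::write_json(
    list(mas = x$mas, provenance = x$provenance,
         n0_per_mas = x$calib$n0_per_mas, kv = x$calib$kv,
         sigma_e = x$calib$pool$sigma_e,
         geometry = list(n_angles = g$n_angles, n_bins = g$n_bins,
                         bin_spacing_mm = g$bin_spacing_mm,
                         fov_mm = g$fov_mm)),
    f_js, auto_unbox = TRUE, digits = NA)
  invisible(c(f_csv, f_js))
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(stem, pool = NULL) {
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  counts <- as.matrix(utils::read.csv(paste0(stem, ".csv"), header = FALSE))
  dimnames(counts) <- NULL
  g <- ct_geometry(meta$geometry$n_angles, meta$geometry$n_bins,
                   meta$geometry$bin_spacing_mm, meta$geometry$fov_mm)
  if (is.null(pool)) {
    # sidecar stores only sigma_e; rebuild a synthetic pool at that level
    pool <- electronic_noise_pool(sigma_e = meta$sigma_e)
  }
  calib <- calibration_model(meta$n0_per_mas, pool, meta$kv)
  new_count_sinogram(counts, meta$mas, calib, g, meta$provenance)
}

#' Read and write electronic noise pools as one-column CSV
#'
#' @param pool an [electronic_noise_pool()].
#' @param path CSV path (single column `noise_counts`, one sample per row).
#' @return `read_noise_pool` returns the pool (centered, `sigma_e` from
#'   the data).
#' @export
write_noise_pool <- function(pool, path) {
  utils::write.csv(data.frame(noise_counts = pool$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_noise_pool
#' @export
read_noise_pool <- function(path) {
  x <- utils::read.csv(path)[[1]]
  electronic_noise_pool(samples = x)
}

#' Read observer confusion tables from CSV
#'
#' Expects columns `observer, oo, os, so, ss` as written by
#' [make_fixtures()].
#'
#' @param path CSV path.
#' @return tibble suitable for [observer_summary()].
#' @export
read_observer_tables <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write a reconstructed image as NIfTI with a JSON sidecar
#'
#' @param image a `recon_image`.
#' @param stem output path without extension.
#' @return invisibly, the files written.
#' @export
write_recon <- function(image, stem) {
  f_nii <- paste0(stem, ".nii.gz")
  f_js <- paste0(stem, ".json")
  RNifti::writeNifti(
    RNifti::asNifti(image$hu, pixdim = rep(image$pixel_size_mm, 2)), f_nii)
  jsonlite::write_json(
    list(pixel_size_mm = image$pixel_size_mm, kernel = image$kernel,
         source_mas = image$source_mas, provenance = image$provenance),
    f_js, auto_unbox = TRUE, digits = NA)
  invisible(c(f_nii, f_js))
}
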