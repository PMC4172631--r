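#' Tissue-labeled digital CT phantom
#'
#' A `phantom_image` is a 2D Hounsfield-unit grid with an aligned integer
#' tissue-label grid and physical pixel size. It is the ground truth for the
#' simulation chain: HU are converted to linear attenuation, forward
#' projected, and the reconstructions of original and simulated acquisitions
#' are compared against each other over its ROIs.
#'
#' @param hu_grid square numeric matrix of Hounsfield units, in
#'   `[-1024, 3000]`.
#' @param pixel_size_mm physical edge length of one pixel (mm).
#' @param tissue_labels integer matrix of the same shape as `hu_grid`;
#'   0 is background/air.
#' @param tissue_names optional named integer vector mapping tissue names to
#'   label codes.
#' @return An object of class `phantom_image` with fields `hu`, `labels`,
#'   `pixel_size_mm`, `fov_mm`, `tissue_names`.
#' @export
phantom_image <- function(hu_grid, pixel_size_mm, tissue_labels = NULL,
                          tissue_names = integer()) {
  stopifnot(is.matrix(hu_grid), nrow(hu_grid) == ncol(hu_grid),
            pixel_size_mm > 0)
  if (is.null(tissue_labels)) {
    tissue_labels <- matrix(0L, nrow(hu_grid), ncol(hu_grid))
  }
  if (!identical(dim(hu_grid), dim(tissue_labels))) {
    rlang::abort("tissue_labels must have the same shape as hu_grid")
  }
  if (any(hu_grid < -1024 | hu_grid > 3000)) {
    rlang::abort("hu_grid values must lie in [-1024, 3000]")
  }
  structure(
    list(hu = hu_grid, labels = tissue_labels,
         pixel_size_mm = pixel_size_mm,
         fov_mm = pixel_size_mm * nrow(hu_grid),
         tissue_names = tissue_names),
    class = "phantom_image"
  )
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image> %d x %d, %.3f mm/px, FOV %.1f mm\n",
              nrow(x$hu), ncol(x$hu), x$pixel_size_mm, x$fov_mm))
  if (length(x$tissue_names)) {
    cat("  tissues:", paste(names(x$tissue_names), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rasterize ellipse descriptors into a phantom
#'
#' Paints a list of ellipses onto a uniform air background (-1000 HU).
#' Later ellipses overwrite earlier ones, so composite anatomy is built
#' outside-in (body, then lungs, organs, bone). Pixel centers sit at
#' `(i + 0.5) * pixel_size` from the grid origin; a pixel belongs to an
#' ellipse when its center falls inside.
#'
#' @param shapes data frame (or tibble) with one row per ellipse and columns
#'   `cx_mm`, `cy_mm` (center, mm, origin at image center, y up),
#'   `a_mm`, `b_mm` (semi-axes, mm), `angle_deg` (rotation), `hu`,
#'   `tissue` (label name). An empty frame yields a uniform air grid.
#' @param matrix_size grid edge count (default 256).
#' @param fov_mm field of view (default 380, the study geometry).
#' @return A [phantom_image()].
#' @export
build_phantom <- function(shapes, matrix_size = 256, fov_mm = 380) {
  px <- fov_mm / matrix_size
  hu <- matrix(-1000, matrix_size, matrix_size)
  lab <- matrix(0L, matrix_size, matrix_size)
  shapes <- as.data.frame(shapes)
  tissue_names <- integer()
  if (nrow(shapes)) {
    need <- c("cx_mm", "cy_mm", "a_mm", "b_mm", "hu", "tissue")
    if (!all(need %in% names(shapes))) {
      rlang::abort(paste("shapes needs columns:", paste(need, collapse = ", ")))
    }
    if (any(shapes$hu < -1024 | shapes$hu > 3000)) {
      rlang::abort("ellipse HU outside the valid range [-1024, 3000]")
    }
    half <- fov_mm / 2
    r_max <- pmax(shapes$a_mm, shapes$b_mm)
    if (any(abs(shapes$cx_mm) + r_max > half | abs(shapes$cy_mm) + r_max > half)) {
      rlang::abort("ellipse extends outside the field of view")
    }
    ctr <- (seq_len(matrix_size) - 0.5) * px - fov_mm / 2
    xg <- matrix(ctr, matrix_size, matrix_size, byrow = TRUE)   # x per column
    yg <- matrix(rev(ctr), matrix_size, matrix_size)            # y per row, up
    tissues <- unique(as.character(shapes$tissue))
    tissue_names <- stats::setNames(seq_along(tissues), tissues)
    for (i in seq_len(nrow(shapes))) {
      ang <- (shapes$angle_deg[i] %||% 0) * pi / 180
      if (is.na(ang)) ang <- 0
      dx <- xg - shapes$cx_mm[i]
      dy <- yg - shapes$cy_mm[i]
      u <- dx * cos(ang) + dy * sin(ang)
      v <- -dx * sin(ang) + dy * cos(ang)
      inside <- (u / shapes$a_mm[i])^2 + (v / shapes$b_mm[i])^2 <= 1
      hu[inside] <- shapes$hu[i]
      lab[inside] <- tissue_names[[as.character(shapes$tissue[i])]]
    }
  }
  phantom_image(hu, px, lab, tissue_names)
}

#' Hounsfield units to linear attenuation
#'
#' Standard HU definition: `mu = mu_water * (1 + hu / 1000)`, clipped at
#' zero (air at -1000 HU maps exactly to zero attenuation).
#'
#' @param hu numeric vector/matrix of Hounsfield units.
#' @param mu_water linear attenuation of water in 1/mm; the default 0.0203
#'   corresponds to a monoenergetic effective beam of ~60 keV (100 kV tube).
#' @return linear attenuation, same shape as `hu`, in 1/mm.
#' @export
hu_to_mu <- function(hu, mu_water = 0.0203) {
  stopifnot(mu_water > 0)
  pmax(mu_water * (1 + hu / 1000), 0)
}

#' Linear attenuation to Hounsfield units
#'
#' Inverse of [hu_to_mu()]: `hu = 1000 * (mu - mu_water) / mu_water`.
#'
#' @inheritParams hu_to_mu
#' @param mu numeric vector/matrix of linear attenuation (1/mm).
#' @return Hounsfield units, same shape as `mu`.
#' @export
mu_to_hu <- function(mu, mu_water = 0.0203) {
  stopifnot(mu_water > 0)
  1000 * (mu - mu_water) / mu_water
}

#' Circular regions of interest over a phantom
#'
#' ROI specs are tibbles with one row per ROI: physical center, area and the
#' tissue the ROI samples. Masks are rasterized disks: the
#' `round(area_mm2 / pixel_area)` pixel centers nearest the ROI center are
#' taken (equivalently, all centers inside a disk whose radius is adjusted
#' to the pixel raster; ties broken in row-major order), so the pixel count
#' times the pixel area matches the nominal area to within one pixel area.
#'
#' @param roi one row of an ROI tibble (`cx_mm`, `cy_mm`, `area_mm2`,
#'   `tissue`).
#' @param image a [phantom_image()] or `recon_image` supplying grid and
#'   pixel size.
#' @return logical matrix mask, same shape as the image grid.
#' @export
roi_mask <- function(roi, image) {
  n <- nrow(image$hu)
  px <- image$pixel_size_mm
  fov <- px * n
  stopifnot(roi$area_mm2 > 0)
  r <- sqrt(roi$area_mm2 / pi)
  if (abs(roi$cx_mm) + r > fov / 2 || abs(roi$cy_mm) + r > fov / 2) {
    rlang::abort("ROI does not lie fully inside the grid")
  }
  ctr <- (seq_len(n) - 0.5) * px - fov / 2
  xg <- matrix(ctr, n, n, byrow = TRUE)
  yg <- matrix(rev(ctr), n, n)
  d2 <- (xg - roi$cx_mm)^2 + (yg - roi$cy_mm)^2
  k <- max(1L, round(roi$area_mm2 / px^2))
  keep <- order(d2)[seq_len(min(k, length(d2)))]
  m <- matrix(FALSE, n, n)
  m[keep] <- TRUE
  m
}

# Deterministically place n_per_tissue non-overlapping 50 mm^2 disks inside
# each labeled tissue region: candidate centers are pixels whose whole disk
# (plus a 1 px margin) stays inside the label; evenly spaced candidates are
# taken so ROIs spread over the region.
place_rois <- function(phantom, area_mm2 = 50, n_per_tissue = 1) {
  px <- phantom$pixel_size_mm
  n <- nrow(phantom$hu)
  r_px <- sqrt(area_mm2 / pi) / px + 1
  ctr <- (seq_len(n) - 0.5) * px - phantom$fov_mm / 2
  out <- list()
  for (tn in names(phantom$tissue_names)) {
    code <- phantom$tissue_names[[tn]]
    ok <- matrix(FALSE, n, n)
    lab_is <- phantom$labels == code
    # erode the label mask by the ROI radius: center pixel is valid when all
    # pixels within r_px carry the label
    idx <- which(lab_is, arr.ind = TRUE)
    if (!nrow(idx)) next
    rad <- ceiling(r_px)
    offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    offs <- offs[offs$dr^2 + offs$dc^2 <= r_px^2, ]
    valid <- rep(TRUE, nrow(idx))
    for (k in seq_len(nrow(offs))) {
      rr <- idx[, 1] + offs$dr[k]
      cc <- idx[, 2] + offs$dc[k]
      inb <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      valid <- valid & inb
      valid[inb] <- valid[inb] & lab_is[cbind(rr[inb], cc[inb])]
    }
    cand <- idx[valid, , drop = FALSE]
    if (!nrow(cand)) {
      rlang::abort(sprintf("tissue '%s' region too small for a %g mm^2 ROI",
                           tn, area_mm2))
    }
    # farthest-point sampling: ROIs are distinct measurement sites, so
    # spread them as far apart as the region allows (overlap only when the
    # region cannot hold n_per_tissue disjoint disks)
    k <- min(n_per_tissue, nrow(cand))
    sel_i <- which.min(abs(cand[, 1] - mean(cand[, 1])) +
                         abs(cand[, 2] - mean(cand[, 2])))[1]
    d_min <- (cand[, 1] - cand[sel_i, 1])^2 + (cand[, 2] - cand[sel_i, 2])^2
    while (length(sel_i) < k) {
      nxt <- which.max(d_min)[1]
      sel_i <- c(sel_i, nxt)
      d_min <- pmin(d_min, (cand[, 1] - cand[nxt, 1])^2 +
                      (cand[, 2] - cand[nxt, 2])^2)
    }
    sel <- cand[sort(sel_i), , drop = FALSE]
    out[[tn]] <- tibble::tibble(
      tissue = tn,
      roi_id = seq_len(nrow(sel)),
      cx_mm = ctr[sel[, 2]],
      cy_mm = rev(ctr)[sel[, 1]],
      area_mm2 = area_mm2
    )
  }
  dplyr::bind_rows(out)
}

#' Default swine-study phantom
#'
#' Deterministic 2D stand-in for the scanned swine: an elliptical body of
#' muscle-equivalent soft tissue with a subcutaneous fat layer, two lungs,
#' a fluid-filled gallbladder and a vertebral body, on an air background.
#' Conventional textbook HU are used (lung -800, fat -100, fluid 0, muscle
#' 50, bone 700) since tissue HU for the animal are not part of the study
#' conditions; all are configurable through [build_phantom()].
#'
#' @param seed integer; the phantom is deterministic, the seed is recorded
#'   for provenance and reserved for future randomized anatomy.
#' @param matrix_size grid edge count (default 256).
#' @param fov_mm field of view in mm (default 380).
#' @param rois_per_tissue how many 50 mm^2 ROIs to place per tissue
#'   (default 1).
#' @return list with `phantom` ([phantom_image()]) and `rois` (tibble with
#'   one row per ROI: `tissue`, `roi_id`, `cx_mm`, `cy_mm`, `area_mm2`).
#' @export
default_swine_phantom <- function(seed = 1, matrix_size = 256, fov_mm = 380,
                                  rois_per_tissue = 1) {
  shapes <- tibble::tribble(
    ~cx_mm, ~cy_mm, ~a_mm, ~b_mm, ~angle_deg, ~hu,   ~tissue,
    0,      0,      155,   115,   0,          -100,  "fat",     # body outline (subcutaneous layer)
    0,      0,      138,   98,    0,          50,    "muscle",  # soft-tissue interior
    -62,    28,     52,    36,    20,         -800,  "lung",
    62,     28,     52,    36,   -20,         -800,  "lung",
    -38,    -48,    26,    18,    0,          0,     "fluid",   # gallbladder
    38,     -52,    30,    22,    0,          50,    "muscle",  # back muscle block
    0,      -66,    22,    18,    0,          700,   "bone"     # vertebral body
  )
  ph <- build_phantom(shapes, matrix_size = matrix_size, fov_mm = fov_mm)
  rois <- place_rois(ph, area_mm2 = 50, n_per_tissue = rois_per_tissue)
  list(phantom = ph, rois = rois, seed = as.integer(seed))
}
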