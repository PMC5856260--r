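#' Pick the pyramid level for the low-magnification exclusion map
#'
#' The exclusion map is computed on a level of around one megapixel; this
#' selects the level whose pixel count is closest to `target_pixels`.
#'
#' @param pyramid an `fq_pyramid`.
#' @param target_pixels desired pixel count (default 1e6).
#' @return list with `image` (the level's array), `level` (index) and `scale`.
#' @export
select_low_mag_level <- function(pyramid, target_pixels = 1e6) {
  if (!inherits(pyramid, "fq_pyramid") || length(pyramid$levels) == 0)
    fq_stop("fq_format_error", "empty or invalid pyramid")
  px <- vapply(pyramid$levels, function(l) prod(dim(l)[1:2]), 0)
  lev <- which.min(abs(px - target_pixels))
  list(image = pyramid$levels[[lev]], level = lev, scale = pyramid$scales[lev])
}

#' Compute the exclusion map (low-magnification 4-class classification)
#'
#' Classifies every pixel of the low-magnification image into background,
#' fibrotic mass, alveolar tissue or bronchus (with its constitutive
#' peri-bronchial collagen). The map partitions the image: no pixel is left
#' unclassified.
#'
#' @param low_mag_image `H x W x 3` array (the selected low-mag level).
#' @param clf_low classifier whose class list is exactly the 4 low-mag classes.
#' @param scale,pixel_size_um metadata recorded in the map.
#' @return an `fq_class_map`.
#' @export
compute_exclusion_map <- function(low_mag_image, clf_low, scale = 1,
                                  pixel_size_um = NA_real_) {
  if (!inherits(clf_low, "fq_tissue_classifier") ||
      !setequal(clf_low$classes, FQ_CLASSES_LOW))
    fq_stop("fq_config_error",
            "low-magnification classifier must have classes {%s}",
            paste(FQ_CLASSES_LOW, collapse = ", "))
  classify(low_mag_image, clf_low, mask = NULL, scale = scale,
           pixel_size_um = pixel_size_um)
}

#' Derive the alveolar region of interest from an exclusion map
#'
#' The ROI for collagen detection is the alveolar tissue, excluding bronchi
#' (and their surrounding collagen), fibrotic masses and background.
#'
#' @param map an exclusion map (`fq_class_map` with the 4 low-mag classes).
#' @return object of class `fq_roi_mask`: logical `mask` + `scale`.
#' @export
derive_roi <- function(map) {
  code <- match("alveolar_tissue", map$classes)
  if (is.na(code))
    fq_stop("fq_config_error", "map has no alveolar_tissue class")
  mask <- map$labels == code
  if (!any(mask))
    fq_warn("exclusion map contains no alveolar tissue; empty ROI (collapsed slide?)")
  structure(list(mask = mask, scale = map$scale), class = "fq_roi_mask")
}

#' Percent area of fibrotic masses
#'
#' `100 * fibrotic_mass / (fibrotic_mass + alveolar_tissue)`: bronchi are
#' excluded from the normalization, and so is background (the denominator is
#' parenchyma, making the readout independent of the scanned frame).
#'
#' @param map an exclusion map.
#' @return percentage in `[0, 100]`.
#' @export
fibrotic_mass_percent <- function(map) {
  cc <- class_counts(map)
  needed <- c("fibrotic_mass", "alveolar_tissue")
  if (!all(needed %in% names(cc)))
    fq_stop("fq_config_error", "map lacks the low-magnification classes")
  denom <- cc[["fibrotic_mass"]] + cc[["alveolar_tissue"]]
  if (denom == 0)
    fq_stop("fq_undefined_readout_error",
            "no parenchyma on the slide (collapsed or empty); readout undefined")
  100 * cc[["fibrotic_mass"]] / denom
}

#' Flag collapsed or empty slides
#'
#' Automated stand-in for the visual quality check that excluded collapsed
#' (non-instilled) lungs: a slide is flagged - not deleted - when its tissue
#' fraction (non-background) or its alveolar fraction falls below a threshold.
#' Flagged slides are excluded from group statistics by default; a manual
#' override list can force exclusion of named slides.
#'
#' @param map an exclusion map.
#' @param min_tissue_fraction minimum non-background fraction (default 0.1).
#' @param min_alveolar_fraction minimum alveolar fraction (default 0.02).
#' @return list with `flagged` (logical) and `reasons` (character vector).
#' @export
qc_flag_collapsed <- function(map, min_tissue_fraction = 0.1,
                              min_alveolar_fraction = 0.02) {
  cc <- class_counts(map)
  total <- sum(cc)
  tissue_frac <- if (total > 0) 1 - cc[["background"]] / total else 0
  alv_frac <- if (total > 0) cc[["alveolar_tissue"]] / total else 0
  reasons <- character(0)
  if (tissue_frac < min_tissue_fraction)
    reasons <- c(reasons, sprintf("tissue fraction %.3f < %.3f",
                                  tissue_frac, min_tissue_fraction))
  if (alv_frac < min_alveolar_fraction)
    reasons <- c(reasons, sprintf("alveolar fraction %.3f < %.3f",
                                  alv_frac, min_alveolar_fraction))
  list(flagged = length(reasons) > 0, reasons = reasons)
}

#' Export an exclusion map as an indexed image with a JSON legend
#'
#' Writes the label raster as a single-channel TIFF plus a JSON sidecar
#' mapping label integers to class names and the false-colour convention
#' (fibrotic mass / alveolar tissue / bronchi / background).
#'
#' @param map an `fq_class_map`.
#' @param path output TIFF path; the legend goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(map, path) {
  write_gray_tiff(map$labels, path)
  legend <- list(classes = c("unclassified", map$classes),
                 codes = 0:length(map$classes),
                 scale = map$scale, pixel_size_um = map$pixel_size_um)
  jsonlite::write_json(legend, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
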