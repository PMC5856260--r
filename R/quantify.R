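#' Tile grid over a full-resolution image
#'
#' Partitions the level-0 image into 512x512 tiles (edge tiles truncated).
#' Tile coordinates are 0-based, half-open, origin top-left.
#'
#' @param width,height image size at level 0.
#' @param tile_size tile edge (default 512).
#' @return list of tiles, each `list(id, x0, y0, width, height)`.
#' @export
tile_grid <- function(width, height, tile_size = 512L) {
  if (!is_count(width, 1) || !is_count(height, 1) || !is_count(tile_size, 1))
    fq_stop("fq_param_error", "width/height/tile_size must be positive integers")
  width <- as.integer(width); height <- as.integer(height)
  tile_size <- as.integer(tile_size)
  tiles <- list()
  id <- 0L
  for (y0 in seq(0L, height - 1L, by = tile_size))
    for (x0 in seq(0L, width - 1L, by = tile_size)) {
      id <- id + 1L
      tiles[[id]] <- list(id = id, x0 = x0, y0 = y0,
                          width = min(tile_size, width - x0),
                          height = min(tile_size, height - y0))
    }
  tiles
}

#' Upsample the low-magnification ROI to a level-0 tile
#'
#' Nearest-neighbour upsampling: a level-0 pixel is in the ROI iff the
#' low-magnification pixel containing it is.
#'
#' @param roi an `fq_roi_mask` (carries its scale).
#' @param tile a tile from [tile_grid()].
#' @return logical `height x width` matrix for the tile.
#' @export
upsample_roi <- function(roi, tile) {
  if (!inherits(roi, "fq_roi_mask")) fq_stop("fq_param_error", "roi must be an fq_roi_mask")
  s <- roi$scale
  H0 <- nrow(roi$mask) * s; W0 <- ncol(roi$mask) * s
  if (tile$x0 < 0 || tile$y0 < 0 || tile$x0 >= W0 + s || tile$y0 >= H0 + s)
    fq_stop("fq_bounds_error", "tile outside the image covered by the ROI")
  rows0 <- tile$y0 + seq_len(tile$height) - 1L   # 0-based level-0 rows
  cols0 <- tile$x0 + seq_len(tile$width) - 1L
  rows_lm <- clamp(rows0 %/% s + 1L, 1L, nrow(roi$mask))
  cols_lm <- clamp(cols0 %/% s + 1L, 1L, ncol(roi$mask))
  roi$mask[rows_lm, cols_lm, drop = FALSE]
}

#' Classify one tile within the ROI (map step)
#'
#' Crops the tile plus a halo of `floor(structure_size/2)` pixels, so window
#' features at tile borders are identical to an untiled computation, then
#' counts the high-magnification classes over the tile's ROI pixels.
#'
#' @param image full-resolution `H x W x 3` array.
#' @param tile a tile from [tile_grid()].
#' @param roi_tile logical `height x width` ROI mask for this tile
#'   (from [upsample_roi()]).
#' @param clf_high classifier with classes collagen / lung_tissue / background.
#' @return a `TileResult`: `list(tile_id, counts, roi_px)` with counts summing
#'   to `roi_px`.
#' @export
map_tile <- function(image, tile, roi_tile, clf_high) {
  if (!inherits(clf_high, "fq_tissue_classifier") ||
      !setequal(clf_high$classes, FQ_CLASSES_HIGH))
    fq_stop("fq_config_error",
            "high-magnification classifier must have classes {%s}",
            paste(FQ_CLASSES_HIGH, collapse = ", "))
  counts <- setNames(integer(length(clf_high$classes)), clf_high$classes)
  if (!any(roi_tile))
    return(list(tile_id = tile$id, counts = counts, roi_px = 0L))
  d <- dim(image)
  halo <- clf_high$cfg$structure_size %/% 2L
  r0 <- max(1L, tile$y0 + 1L - halo); r1 <- min(d[1], tile$y0 + tile$height + halo)
  c0 <- max(1L, tile$x0 + 1L - halo); c1 <- min(d[2], tile$x0 + tile$width + halo)
  crop <- image[r0:r1, c0:c1, , drop = FALSE]
  mask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  mask[tile$y0 + 1L - r0 + seq_len(tile$height),
       tile$x0 + 1L - c0 + seq_len(tile$width)] <- roi_tile
  cm <- classify(crop, clf_high, mask = mask)
  cc <- class_counts(cm)
  counts[names(cc)] <- counts[names(cc)] + cc
  list(tile_id = tile$id, counts = counts, roi_px = sum(roi_tile))
}

#' Combine tile results (reduce step)
#'
#' Element-wise sum of per-tile class counts; associative and order
#' independent, so tiles may be processed in any order or in parallel.
#'
#' @param results list of [map_tile()] results from one slide.
#' @return list with `counts` (summed) and `roi_px`.
#' @export
reduce_tiles <- function(results) {
  if (length(results) == 0) fq_stop("fq_param_error", "no tile results")
  ids <- vapply(results, `[[`, 0L, "tile_id")
  if (anyDuplicated(ids))
    fq_stop("fq_aggregation_error", "duplicate tile ids: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  counts <- Reduce(`+`, lapply(results, `[[`, "counts"))
  list(counts = counts, roi_px = sum(vapply(results, `[[`, 0L, "roi_px")))
}

#' Percent alveolar collagen
#'
#' `100 * collagen / (collagen + lung_tissue)` over the alveolar ROI.
#' Background - alveolar lumen air - is excluded from the denominator: alveoli
#' are mostly air, and only a tissue-area denominator yields the low
#' single-digit percentages seen in saline controls. Set
#' `denominator = "roi"` to divide by all ROI pixels instead.
#'
#' @param agg aggregated counts from [reduce_tiles()].
#' @param denominator `"tissue"` (default) or `"roi"`.
#' @return percentage in `[0, 100]`.
#' @export
alveolar_collagen_percent <- function(agg, denominator = c("tissue", "roi")) {
  denominator <- match.arg(denominator)
  cc <- agg$counts
  denom <- if (denominator == "tissue") cc[["collagen"]] + cc[["lung_tissue"]]
           else sum(cc)
  if (denom == 0)
    fq_stop("fq_undefined_readout_error",
            "no alveolar tissue in the ROI; collagen readout undefined")
  100 * cc[["collagen"]] / denom
}

#' Percent total collagen
#'
#' Additional readout combining both stages: collagen-bearing area (alveolar
#' collagen at full resolution plus the fibrotic-mass area, which is treated
#' as collagen-bearing remodelled tissue) over total parenchymal tissue area,
#' with bronchi and their constitutive collagen excluded throughout. The
#' exclusion-map counts are rescaled to level-0 pixel units. The exact
#' formula is declared here (and in output metadata) rather than asserted as
#' canonical.
#'
#' @param agg aggregated high-magnification counts from [reduce_tiles()].
#' @param exclusion_map the low-magnification `fq_class_map`.
#' @return percentage in `[0, 100]`.
#' @export
total_collagen_percent <- function(agg, exclusion_map) {
  if (is.null(agg$counts) || !inherits(exclusion_map, "fq_class_map"))
    fq_stop("fq_dependency_error",
            "total collagen needs both the tile aggregate and the exclusion map")
  cc_lm <- class_counts(exclusion_map)
  mass_l0 <- cc_lm[["fibrotic_mass"]] * exclusion_map$scale^2
  coll <- agg$counts[["collagen"]]
  tissue <- agg$counts[["lung_tissue"]]
  denom <- coll + tissue + mass_l0
  if (denom == 0)
    fq_stop("fq_undefined_readout_error", "no parenchyma; readout undefined")
  100 * (coll + mass_l0) / denom
}

#' Quantify one slide end to end
#'
#' Runs the full two-stage pipeline on a pyramid: low-magnification exclusion
#' map, QC flag, percent fibrotic masses, alveolar ROI, tiled (512x512,
#' map-reduce) high-magnification collagen classification, percent alveolar
#' and total collagen.
#'
#' @param pyramid an `fq_pyramid`.
#' @param clf_low,clf_high the two trained classifiers.
#' @param tile_size high-magnification tile edge (default 512).
#' @param target_pixels low-magnification level size target (default 1e6).
#' @param qc named list of [qc_flag_collapsed()] thresholds, or NULL.
#' @return object of class `fq_slide_quantification`: the three readouts,
#'   `roi_px`, `qc`, per-stage class counts, model hashes.
#' @export
quantify_slide <- function(pyramid, clf_low, clf_high, tile_size = 512L,
                           target_pixels = 1e6, qc = NULL) {
  low <- select_low_mag_level(pyramid, target_pixels)
  emap <- compute_exclusion_map(low$image, clf_low, scale = low$scale)
  qc_args <- c(list(map = emap), qc %||% list())
  flag <- do.call(qc_flag_collapsed, qc_args)
  mass_pct <- fibrotic_mass_percent(emap)
  roi <- derive_roi(emap)
  l0 <- pyramid$levels[[1]]
  tiles <- tile_grid(ncol(l0), nrow(l0), tile_size)
  results <- lapply(tiles, function(tl)
    map_tile(l0, tl, upsample_roi(roi, tl), clf_high))
  agg <- reduce_tiles(results)
  coll_pct <- if (agg$counts[["collagen"]] + agg$counts[["lung_tissue"]] > 0)
    alveolar_collagen_percent(agg) else NA_real_
  total_pct <- total_collagen_percent(agg, emap)
  structure(list(fibrotic_mass_percent = mass_pct,
                 alveolar_collagen_percent = coll_pct,
                 total_collagen_percent = total_pct,
                 roi_px = agg$roi_px,
                 qc = flag,
                 low_mag_counts = class_counts(emap),
                 high_mag_counts = agg$counts,
                 model_hashes = c(low = clf_low$training_hash,
                                  high = clf_high$training_hash),
                 total_collagen_formula =
                   "100*(collagen_l0 + mass_px_l0)/(collagen_l0 + lung_tissue_l0 + mass_px_l0); bronchi excluded"),
            class = "fq_slide_quantification")
}

#' @export
print.fq_slide_quantification <- function(x, ...) {
  cat(sprintf(paste0("<fq_slide_quantification>\n",
                     "  fibrotic masses:   %6.2f %%\n",
                     "  alveolar collagen: %6.2f %%\n",
                     "  total collagen:    %6.2f %%\n",
                     "  ROI: %d px | QC flagged: %s%s\n"),
              x$fibrotic_mass_percent, x$alveolar_collagen_percent,
              x$total_collagen_percent, x$roi_px, x$qc$flagged,
              if (x$qc$flagged) paste0(" (", paste(x$qc$reasons, collapse = "; "), ")")
              else ""))
  invisible(x)
}
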