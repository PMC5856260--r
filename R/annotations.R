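#' Annotation sets: labelled training polygons
#'
#' An annotation set is the digital equivalent of a rater drawing several
#' representative regions per tissue class on training images. Each entry ties
#' a simple polygon (in pixel coordinates of a stated pyramid scale, origin
#' top-left, x right / y down, half-open) to an image id and a class label.
#'
#' @param entries list of entries, each a list with `image_id` (character),
#'   `scale` (pyramid downsampling factor the coordinates refer to), `class`
#'   (character label) and `polygon` (n x 2 matrix of x,y vertices, open ring).
#' @return object of class `fq_annotation_set`.
#' @export
annotation_set <- function(entries) {
  for (e in entries) {
    if (!all(c("image_id", "scale", "class", "polygon") %in% names(e)))
      fq_stop("fq_param_error", "each annotation entry needs image_id, scale, class, polygon")
    if (!is.matrix(e$polygon) || ncol(e$polygon) != 2 || nrow(e$polygon) < 3)
      fq_stop("fq_param_error", "polygons must be n x 2 matrices with n >= 3")
  }
  structure(list(entries = entries), class = "fq_annotation_set")
}

#' @export
print.fq_annotation_set <- function(x, ...) {
  cls <- vapply(x$entries, `[[`, "", "class")
  cat(sprintf("<fq_annotation_set> %d polygons: %s\n", length(x$entries),
              paste(sprintf("%s (%d)", names(table(cls)), table(cls)), collapse = ", ")))
  invisible(x)
}

# Pixel centers are at (col - 0.5, row - 0.5). A pixel belongs to a polygon if
# its center is inside (even-odd rule). Returns (row, col) matrix, 1-based.
rasterize_polygon <- function(polygon, H, W) {
  px <- polygon[, 1]; py <- polygon[, 2]
  cols <- max(1L, ceiling(min(px) + 0.5)):min(W, floor(max(px) + 0.5))
  rows <- max(1L, ceiling(min(py) + 0.5)):min(H, floor(max(py) + 0.5))
  if (length(cols) == 0 || length(rows) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  cx <- rep(cols - 0.5, each = length(rows))
  cy <- rep(rows - 0.5, times = length(cols))
  inside <- rep(FALSE, length(cx))
  n <- length(px)
  j <- n
  for (i in seq_len(n)) {
    x1 <- px[j]; y1 <- py[j]; x2 <- px[i]; y2 <- py[i]
    crosses <- ((y1 > cy) != (y2 > cy)) &
      (cx < (x2 - x1) * (cy - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  out <- cbind(row = rep(rows, times = length(cols))[inside],
               col = rep(cols, each = length(rows))[inside])
  out
}

# Canonical class ordering: the two model class lists keep their documented
# order; anything else is sorted for determinism.
canonical_classes <- function(classes) {
  if (setequal(classes, FQ_CLASSES_LOW)) return(FQ_CLASSES_LOW)
  if (setequal(classes, FQ_CLASSES_HIGH)) return(FQ_CLASSES_HIGH)
  sort(unique(classes))
}

#' Auto-draw training annotations from ground truth (simulated rater)
#'
#' Places small square polygons strictly interior to each class's region: the
#' class mask is eroded by the feature window radius first, so every training
#' pixel's feature window sees only that class (the annotations a careful
#' rater would draw). For the low-magnification model the regions come from
#' the ground-truth label map at the stated scale; for the high-magnification
#' model from the material map (collagen / lung tissue / background). Bronchus
#' annotations are restricted to the wall and collagen collar (a rater does
#' not annotate lumen air as bronchus).
#'
#' @param gt an `fq_ground_truth`.
#' @param n_regions_per_class polygons per class.
#' @param min_area_px a class whose region (at the working scale) holds fewer
#'   pixels raises a missing-class error.
#' @param seed integer seed for polygon placement.
#' @param model `"low"` (4 tissue classes) or `"high"` (3 collagen classes).
#' @param scale pyramid scale the polygons refer to (the low-magnification
#'   level's scale; 1 for the high-magnification model).
#' @param window_radius erosion radius; default `floor(structure_size/2)` of
#'   the model's default feature configuration (7 low, 2 high).
#' @param image_id id recorded in the entries.
#' @return an [annotation_set()].
#' @export
generate_annotations <- function(gt, n_regions_per_class = 5L, min_area_px = 400L,
                                 seed = 1L, model = c("low", "high"), scale = 1L,
                                 window_radius = NULL, image_id = "slide") {
  model <- match.arg(model)
  if (!inherits(gt, "fq_ground_truth"))
    fq_stop("fq_param_error", "gt must be an fq_ground_truth")
  if (!is_count(n_regions_per_class, 1)) fq_stop("fq_param_error", "n_regions_per_class >= 1")
  window_radius <- window_radius %||%
    (if (model == "low") FQ_STRUCTURE_LOW else FQ_STRUCTURE_HIGH) %/% 2L
  classes <- if (model == "low") FQ_CLASSES_LOW else FQ_CLASSES_HIGH

  lab <- gt_low_mag_labels(gt, scale)
  mat <- if (scale == 1) gt$material_map
         else cpp_mode_downsample(gt$material_map, as.integer(scale))

  masks <- list(); restrict <- list()
  for (cl in classes) {
    masks[[cl]] <- if (model == "low") {
      # purity is with respect to the label map; the extra material restriction
      # for bronchi (applied after erosion) keeps the simulated rater on the
      # wall and collar instead of the lumen air
      m <- lab == FQ_GT_LABELS[[cl]]
      if (cl == "bronchus")
        restrict[[cl]] <- mat != FQ_MATERIALS[["background"]]
      m
    } else {
      code <- switch(cl, collagen = "collagen", lung_tissue = "tissue",
                     background = "background")
      mat == FQ_MATERIALS[[code]]
    }
    if (sum(masks[[cl]]) < min_area_px)
      fq_stop("fq_missing_class_error",
              "class '%s' occupies %d px (< min_area_px = %d) in the ground truth",
              cl, sum(masks[[cl]]), min_area_px)
  }

  with_seed(seed, {
    entries <- list()
    smax <- if (model == "low") 10L else 5L
    for (cl in classes) {
      E <- cpp_erode(masks[[cl]], as.integer(window_radius))
      if (!is.null(restrict[[cl]])) E <- E & restrict[[cl]]
      # a representative rater annotates every anatomical context a class
      # appears in (e.g. collagen: septa, fibrotic masses, bronchial collar;
      # background: free glass and alveolar lumina), not just the largest one:
      # round-robin over the label regions intersecting the class mask
      ctx <- list()
      ctx_codes <- sort(unique(as.vector(lab)))
      if (model == "high") {
        # the collagen model runs inside the alveolar ROI only, so its rater
        # annotates alveolar structures (septa, septal collagen, airspaces and
        # free glass), not fibrotic masses or peri-bronchial collagen
        ctx_codes <- intersect(ctx_codes, unname(FQ_GT_LABELS[
          c("background", "alveolar_tissue", "alveolar_collagen")]))
      }
      for (code in ctx_codes) {
        cm <- E & lab == code
        if (sum(cm) >= 9) ctx[[length(ctx) + 1]] <- which(cm)
      }
      if (length(ctx) == 0)
        fq_stop("fq_missing_class_error",
                "class '%s' vanishes after erosion by the window radius (%d px)",
                cl, window_radius)
      H <- nrow(E); W <- ncol(E)
      placed <- 0L
      s_ctx <- rep(smax, length(ctx))   # per-context polygon half-size
      tries <- rep(0L, length(ctx))
      while (placed < n_regions_per_class) {
        k <- placed %% length(ctx) + 1L
        s <- s_ctx[k]
        tries[k] <- tries[k] + 1L
        if (tries[k] > 60L) {
          if (s > 0L) { s_ctx[k] <- s - 1L; tries[k] <- 0L; next }
          if (length(ctx) > 1L) {   # give up on an unplaceable context
            ctx <- ctx[-k]; s_ctx <- s_ctx[-k]; tries <- tries[-k]; next
          }
          fq_stop("fq_missing_class_error",
                  "cannot place %d interior polygons for class '%s'",
                  n_regions_per_class, cl)
        }
        cand <- ctx[[k]]
        p <- cand[sample.int(length(cand), 1)]
        i <- (p - 1L) %% H + 1L; j <- (p - 1L) %/% H + 1L
        if (i - s < 1 || j - s < 1 || i + s > H || j + s > W) next
        if (s > 0L && !all(E[(i - s):(i + s), (j - s):(j + s)])) next
        poly <- cbind(x = c(j - s - 1, j + s, j + s, j - s - 1),
                      y = c(i - s - 1, i - s - 1, i + s, i + s))
        entries[[length(entries) + 1]] <-
          list(image_id = image_id, scale = as.integer(scale), class = cl,
               polygon = poly)
        placed <- placed + 1L
        tries[k] <- 0L
      }
    }
    annotation_set(entries)
  })
}

#' Write / read annotation sets as GeoJSON
#'
#' Polygons are stored as GeoJSON `Polygon` features with properties `class`,
#' `image_id` and `scale`; coordinates are pixel coordinates at the stated
#' scale (not geographic).
#'
#' @param aset an [annotation_set()].
#' @param path file path.
#' @return `write_annotations` returns `path` invisibly; `read_annotations`
#'   returns an [annotation_set()].
#' @export
write_annotations <- function(aset, path) {
  feats <- lapply(aset$entries, function(e) {
    ring <- rbind(e$polygon, e$polygon[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                            function(i) unname(ring[i, ])))),
         properties = list(class = e$class, image_id = e$image_id,
                           scale = e$scale))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection"))
    fq_stop("fq_format_error", "%s is not a GeoJSON FeatureCollection", path)
  entries <- lapply(g$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring <- ring[-nrow(ring), , drop = FALSE] # drop closing vertex
    colnames(ring) <- c("x", "y")
    list(image_id = f$properties$image_id,
         scale = as.integer(f$properties$scale),
         class = f$properties$class, polygon = ring)
  })
  annotation_set(entries)
}
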