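#' Feature configuration for the SVM pixel classifier
#'
#' Per-pixel features are computed over a square window of edge length
#' `structure_size` centred on the pixel (the "structure size"). Per colour
#' channel the available statistics are the window mean, min, max, variance and
#' the edge factor. The window includes the centre pixel; at image borders the
#' window is clipped and all formulas use the actual window size |W|.
#'
#' The edge factor of a window W centred on pixel p is
#' \deqn{\frac{1}{|W|-1} \sum_{p' \in W} (p' - p)^2,}
#' a local-contrast descriptor: zero on constant windows, large across tissue
#' boundaries. Variance uses the same |W|-1 divisor.
#'
#' @param structure_size odd integer >= 3, window edge length in pixels. Large
#'   at low magnification (default 25 there) to capture texture context, small
#'   at full resolution (default 5) for fine collagen detection.
#' @param channels ordered subset of `c("R","G","B")`.
#' @param stats ordered subset of
#'   `c("center","mean","min","max","variance","edge_factor")`; `center` is the
#'   pixel's own intensity (the single-pixel feature).
#' @return an object of class `fq_feature_config` with the derived
#'   `feature_names` (channel-major order, e.g. `"R.mean"`).
#' @export
feature_config <- function(structure_size = 5L,
                           channels = c("R", "G", "B"),
                           stats = c("center", "mean", "min", "max", "variance",
                                     "edge_factor")) {
  if (!is_count(structure_size, min = 3) || structure_size %% 2 == 0)
    fq_stop("fq_param_error", "structure_size must be an odd integer >= 3, got %s",
            format(structure_size))
  channels <- match.arg(channels, c("R", "G", "B"), several.ok = TRUE)
  stats <- match.arg(stats, c("center", "mean", "min", "max", "variance",
                              "edge_factor"), several.ok = TRUE)
  if (anyDuplicated(channels) || anyDuplicated(stats) || length(stats) == 0)
    fq_stop("fq_param_error", "channels/stats must be non-empty and duplicate-free")
  structure(list(structure_size = as.integer(structure_size),
                 channels = channels, stats = stats,
                 feature_names = as.vector(t(outer(channels, stats, paste, sep = ".")))),
            class = "fq_feature_config")
}

#' @export
print.fq_feature_config <- function(x, ...) {
  cat(sprintf("<fq_feature_config> structure_size=%d, %d features: %s\n",
              x$structure_size, length(x$feature_names),
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Edge factor of a pixel window
#'
#' Mean squared deviation of all window pixels from the centre pixel,
#' `sum((w - center)^2) / (|W| - 1)`. The centre pixel is part of the window
#' (its term is zero), so for a full `s x s` window `|W| = s^2`.
#'
#' @param window_values numeric vector, all pixel values of the window W
#'   (including the centre pixel).
#' @param center_value value of the centre pixel p.
#' @return non-negative scalar.
#' @examples
#' edge_factor(c(0, 0, 0, 0, 2, 0, 0, 0, 0), 2) # 8 * 4 / 8 = 4
#' @export
edge_factor <- function(window_values, center_value) {
  if (length(window_values) < 2)
    fq_stop("fq_degenerate_window_error",
            "edge factor needs |W| >= 2, got %d", length(window_values))
  if (!all(is.finite(window_values)) || !is.finite(center_value))
    fq_stop("fq_param_error", "edge_factor requires finite values")
  sum((window_values - center_value)^2) / (length(window_values) - 1)
}

#' Per-pixel feature vector (reference implementation)
#'
#' Computes the configured window statistics for a single pixel by direct
#' enumeration of the clipped window. This is the plain, loop-free-of-tricks
#' definition of the features; [feature_block()] is the fast path used by the
#' pipeline and must agree with this function exactly.
#'
#' @param image `H x W x C` numeric array (8-bit RGB values, 0-255).
#' @param x,y 1-based column (x) and row (y) of the pixel.
#' @param cfg a [feature_config()].
#' @return named numeric vector in `cfg$feature_names` order.
#' @export
pixel_features <- function(image, x, y, cfg) {
  d <- dim(image)
  if (length(d) != 3) fq_stop("fq_param_error", "image must be an H x W x C array")
  if (x < 1 || y < 1 || x > d[2] || y > d[1])
    fq_stop("fq_bounds_error", "pixel (%d,%d) outside %dx%d image", x, y, d[2], d[1])
  r <- cfg$structure_size %/% 2
  rows <- max(1, y - r):min(d[1], y + r)
  cols <- max(1, x - r):min(d[2], x + r)
  ch_index <- c(R = 1L, G = 2L, B = 3L)
  out <- numeric(0)
  for (ch in cfg$channels) {
    w <- as.vector(image[rows, cols, ch_index[[ch]]])
    c0 <- image[y, x, ch_index[[ch]]]
    n <- length(w)
    for (s in cfg$stats) {
      v <- switch(s,
        center = c0,
        mean = mean(w),
        min = min(w),
        max = max(w),
        variance = if (n > 1) sum((w - mean(w))^2) / (n - 1) else 0,
        edge_factor = if (n > 1) edge_factor(w, c0) else 0)
      out <- c(out, v)
    }
  }
  names(out) <- cfg$feature_names
  out
}

# Full-image feature maps: list (channel -> stat -> H x W matrix).
feature_maps <- function(image, cfg) {
  ch_index <- c(R = 1L, G = 2L, B = 3L)
  maps <- list()
  for (ch in cfg$channels) {
    m <- cpp_window_stats(image[, , ch_index[[ch]], drop = TRUE],
                          cfg$structure_size)
    m$center <- image[, , ch_index[[ch]], drop = TRUE]
    maps[[ch]] <- m
  }
  maps
}

#' Feature matrix over (masked) pixels
#'
#' Computes the feature vector of every pixel selected by `mask`, in row-major
#' scan order (top row left to right, then the next row). Uses integral-image
#' accumulation, so it is fast and agrees bit-for-bit with [pixel_features()]
#' on 8-bit input regardless of how the image was cropped.
#'
#' @inheritParams pixel_features
#' @param mask optional logical `H x W` matrix; `NULL` selects all pixels.
#' @return list with `features` (n x n_features matrix) and `pixels`
#'   (n x 2 matrix of 1-based (row, col) positions). An empty mask yields
#'   zero rows, not an error.
#' @export
feature_block <- function(image, cfg, mask = NULL) {
  d <- dim(image)
  if (length(d) != 3) fq_stop("fq_param_error", "image must be an H x W x C array")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2]))
    fq_stop("fq_param_error", "mask dimensions %s do not match image %dx%d",
            paste(dim(mask), collapse = "x"), d[1], d[2])
  px <- mask_pixels_rowmajor(mask)
  nf <- length(cfg$feature_names)
  if (nrow(px) == 0)
    return(list(features = matrix(numeric(0), 0, nf,
                                  dimnames = list(NULL, cfg$feature_names)),
                pixels = px))
  maps <- feature_maps(image, cfg)
  out <- matrix(NA_real_, nrow(px), nf, dimnames = list(NULL, cfg$feature_names))
  k <- 1L
  for (ch in cfg$channels) for (s in cfg$stats) {
    out[, k] <- maps[[ch]][[s]][px]
    k <- k + 1L
  }
  list(features = out, pixels = px)
}
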