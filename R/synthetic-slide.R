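#' Stain profile of a synthetic trichrome slide
#'
#' Masson's trichrome renders collagen blue, cytoplasm/muscle red-pink and
#' glass/airspace near-white. Stain drift across studies and years is modelled
#' as a global hue rotation plus per-slide channel gain, which qualitatively
#' covers the observed reddish/orange/bluish and blue-to-grey drift of
#' historical staining batches.
#'
#' @param collagen,cytoplasm,background RGB triples in `[0,255]`.
#' @param hue_shift_deg global HSV hue rotation in degrees (drift range used by
#'   the study generator: -15 to +15).
#' @param intensity_scale scalar channel gain (drift range 0.8 to 1.2).
#' @return object of class `fq_stain_profile`.
#' @export
stain_profile <- function(collagen = c(70, 85, 175),
                          cytoplasm = c(190, 80, 100),
                          background = c(246, 244, 246),
                          hue_shift_deg = 0,
                          intensity_scale = 1) {
  for (nm in c("collagen", "cytoplasm", "background")) {
    v <- get(nm)
    if (length(v) != 3 || !all(is.finite(v)) || any(v < 0) || any(v > 255))
      fq_stop("fq_param_error", "%s must be an RGB triple in [0,255]", nm)
  }
  if (!is.finite(hue_shift_deg) || !is.finite(intensity_scale) || intensity_scale <= 0)
    fq_stop("fq_param_error", "invalid stain drift parameters")
  structure(list(collagen = as.numeric(collagen),
                 cytoplasm = as.numeric(cytoplasm),
                 background = as.numeric(background),
                 hue_shift_deg = as.numeric(hue_shift_deg),
                 intensity_scale = as.numeric(intensity_scale)),
            class = "fq_stain_profile")
}

#' Parameters of the synthetic slide generator
#'
#' The generator draws a lung-shaped tissue blob with (i) a lacy alveolar
#' texture: a Voronoi ridge lattice of thin red septa around white airspaces,
#' (ii) dense fibrotic masses: blobs of mixed collagen/cell patches replacing
#' alveolar architecture, (iii) ring-shaped bronchi: red wall around a white
#' lumen, with a blue peri-bronchial collagen collar, and (iv) alveolar
#' collagen: blue segments painted on a fraction of septal pixels.
#'
#' @param width_px,height_px image size at full resolution, >= 64.
#' @param fibrotic_mass_fraction target fraction of parenchyma (fibrotic mass +
#'   alveolar tissue) occupied by fibrotic masses, in `[0,1]`. The realized
#'   fraction is within 2 percentage points of the target.
#' @param alveolar_collagen_fraction fraction of septal (alveolar wall) pixels
#'   rendered as collagen, in `[0,1]`.
#' @param n_bronchi number of bronchi.
#' @param stain_profile a [stain_profile()].
#' @param noise_sd per-channel additive Gaussian noise SD (8-bit scale).
#' @param pixel_size_um physical pixel size at full resolution. The source
#'   scanner's micrometre-per-pixel value is not asserted anywhere; this is a
#'   free metadata parameter (default 0.25, a typical 40x objective scan).
#' @param alveolus_px,septum_px mean alveolus diameter and septal wall
#'   thickness in pixels at full resolution.
#' @param seed integer seed; all structure and noise derive from it.
#' @return object of class `fq_slide_params`.
#' @export
synthetic_slide_params <- function(width_px = 1280L, height_px = 1280L,
                                   fibrotic_mass_fraction = 0.15,
                                   alveolar_collagen_fraction = 0.05,
                                   n_bronchi = 3L,
                                   stain_profile = NULL,
                                   noise_sd = 8,
                                   pixel_size_um = 0.25,
                                   alveolus_px = 42,
                                   septum_px = 12,
                                   seed = 1L) {
  if (!is_count(width_px, 64) || !is_count(height_px, 64))
    fq_stop("fq_param_error", "width_px/height_px must be integers >= 64")
  if (!is_fraction(fibrotic_mass_fraction) || !is_fraction(alveolar_collagen_fraction))
    fq_stop("fq_param_error", "fractions must lie in [0,1]")
  if (!is_count(n_bronchi)) fq_stop("fq_param_error", "n_bronchi must be a non-negative integer")
  if (is.null(stain_profile)) stain_profile <- stain_profile()
  if (!inherits(stain_profile, "fq_stain_profile"))
    fq_stop("fq_param_error", "stain_profile must be a stain_profile() object")
  if (!is.finite(noise_sd) || noise_sd < 0) fq_stop("fq_param_error", "noise_sd must be >= 0")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    fq_stop("fq_param_error", "pixel_size_um must be positive")
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 fibrotic_mass_fraction = fibrotic_mass_fraction,
                 alveolar_collagen_fraction = alveolar_collagen_fraction,
                 n_bronchi = as.integer(n_bronchi), stain_profile = stain_profile,
                 noise_sd = noise_sd, pixel_size_um = pixel_size_um,
                 alveolus_px = alveolus_px, septum_px = septum_px,
                 seed = as.integer(seed)),
            class = "fq_slide_params")
}

# ---- internal geometry helpers -------------------------------------------

# Filled ellipse mask.
ellipse_mask <- function(H, W, cy, cx, ry, rx) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

# Linear indices (column-major) of the pixels of a filled ellipse, computed on
# its bounding box only, so repeated blob placement stays cheap.
ellipse_indices <- function(H, W, cy, cx, ry, rx) {
  rows <- max(1, ceiling(cy - ry)):min(H, floor(cy + ry))
  cols <- max(1, ceiling(cx - rx)):min(W, floor(cx + rx))
  if (length(rows) == 0 || length(cols) == 0) return(integer(0))
  inside <- outer(((rows - cy) / ry)^2, ((cols - cx) / rx)^2, "+") <= 1
  hit <- which(inside, arr.ind = TRUE)
  (cols[hit[, 2]] - 1L) * H + rows[hit[, 1]]
}

# Lung-shaped blob: two overlapping ellipses with a waist, like a lobe section.
lung_mask <- function(H, W) {
  m1 <- ellipse_mask(H, W, 0.42 * H, 0.46 * W, 0.34 * H, 0.38 * W)
  m2 <- ellipse_mask(H, W, 0.62 * H, 0.55 * W, 0.30 * H, 0.34 * W)
  m1 | m2
}

# Coarse blocky random field in [0,1], block size `block` px (used to give
# painted regions contiguous patch structure).
block_noise <- function(H, W, block) {
  bh <- ceiling(H / block); bw <- ceiling(W / block)
  coarse <- matrix(runif(bh * bw), bh, bw)
  coarse[rep(seq_len(bh), each = block)[seq_len(H)],
         rep(seq_len(bw), each = block)[seq_len(W)], drop = FALSE]
}

# ---- generator -----------------------------------------------------------

#' Generate a synthetic trichrome slide with exact ground truth
#'
#' Deterministic given `params$seed`: the same parameters always produce
#' bit-identical pyramids and label maps. The stain profile only affects the
#' rendered colours, never the ground truth.
#'
#' @param params a [synthetic_slide_params()].
#' @return object of class `fq_slide`: a list with
#'   * `pyramid`: class `fq_pyramid`, RGB levels (each `H x W x 3`, 8-bit
#'     values), level 1 = full resolution, each further level 2x mean-pooled,
#'     down to a maximum dimension of 1024 px; `scales` gives the downsampling
#'     factor of each level;
#'   * `gt`: class `fq_ground_truth` with `label_map` (integer matrix, codes in
#'     `FQ_GT_LABELS`: background, fibrotic_mass, alveolar_tissue, bronchus,
#'     alveolar_collagen), `material_map` (codes in `FQ_MATERIALS`), the
#'     realized `mass_fraction` (fibrotic mass / parenchyma) and
#'     `collagen_fraction` (collagen / septal tissue within alveolar region),
#'     and `pixel_size_um`;
#'   * `params`.
#' @export
generate_slide <- function(params) {
  if (!inherits(params, "fq_slide_params"))
    fq_stop("fq_param_error", "params must come from synthetic_slide_params()")
  H <- params$height_px; W <- params$width_px
  with_seed(params$seed, {
    lung <- lung_mask(H, W)

    # alveolar septa: Voronoi ridge lattice
    n_seeds <- max(2L, round(H * W / params$alveolus_px^2))
    sy <- runif(n_seeds, 1, H); sx <- runif(n_seeds, 1, W)
    septa <- cpp_voronoi_ridge(H, W, sy, sx, params$alveolus_px, params$septum_px)

    material <- matrix(FQ_MATERIALS[["background"]], H, W)
    material[lung & septa] <- FQ_MATERIALS[["tissue"]]
    # pleural rim so the lobe boundary is tissue
    rim <- lung & !cpp_erode(lung, 3L)
    material[rim] <- FQ_MATERIALS[["tissue"]]
    # render-time shade: trichrome stains airway smooth muscle darker red than
    # alveolar walls, and compact peri-bronchial collagen deeper blue than
    # loose septal collagen; the shade map drives rendering only, never truth
    shade <- matrix(1L, H, W)

    label <- matrix(FQ_GT_LABELS[["background"]], H, W)
    label[lung] <- FQ_GT_LABELS[["alveolar_tissue"]]

    # bronchi: lumen (white) / wall (red) / collagen collar (blue)
    if (params$n_bronchi > 0) {
      # sized so the low-magnification feature window spans the whole ring:
      # the white lumen + red wall + blue collar signature is what separates a
      # bronchus from dense fibrosis locally
      r_lumen <- 10; r_wall <- 32; r_collar <- 80
      interior <- cpp_erode(lung, as.integer(r_collar + 6))
      cand <- which(interior, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        centers <- matrix(numeric(0), 0, 2)
        tries <- 0
        while (nrow(centers) < params$n_bronchi && tries < 200) {
          tries <- tries + 1
          p <- cand[sample.int(nrow(cand), 1), ]
          if (nrow(centers) == 0 ||
              min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) > (2.4 * r_collar)^2) {
            centers <- rbind(centers, p)
          }
        }
        for (i in seq_len(nrow(centers))) {
          cy <- centers[i, 1]; cx <- centers[i, 2]
          d_collar <- ellipse_mask(H, W, cy, cx, r_collar, r_collar)
          d_wall <- ellipse_mask(H, W, cy, cx, r_wall, r_wall)
          d_lumen <- ellipse_mask(H, W, cy, cx, r_lumen, r_lumen)
          label[d_collar] <- FQ_GT_LABELS[["bronchus"]]
          material[d_collar & !d_wall] <- FQ_MATERIALS[["collagen"]]
          material[d_wall & !d_lumen] <- FQ_MATERIALS[["tissue"]]
          material[d_lumen] <- FQ_MATERIALS[["background"]]
          shade[d_collar] <- 2L
        }
      }
    }

    # fibrotic masses: random ellipses inside the lung, avoiding bronchi,
    # until the realized mass fraction of parenchyma is within the target band
    parenchyma0 <- sum(label == FQ_GT_LABELS[["alveolar_tissue"]])
    target <- params$fibrotic_mass_fraction
    if (target > 0 && parenchyma0 > 0) {
      mass <- matrix(FALSE, H, W)
      allowed <- as.vector(lung & label != FQ_GT_LABELS[["bronchus"]])
      interior <- cpp_erode(lung, 10L)
      cand <- which(as.vector(interior) & allowed)
      n_mass_px <- 0L
      it <- 0
      # stop anywhere in the lower half of the +/-2-point band; proposals are
      # pre-shrunk to the remaining gap so late iterations stay cheap
      while (n_mass_px / parenchyma0 < target - 0.012 && it < 600 && length(cand) > 0) {
        it <- it + 1
        p <- cand[sample.int(length(cand), 1)]
        py <- (p - 1L) %% H + 1L; px <- (p - 1L) %/% H + 1L
        # masses are large relative to the low-magnification feature window,
        # as in real disease (mm-scale consolidation vs 50 um windows)
        rbase <- min(H, W)
        rx <- runif(1, 0.12, 0.2) * rbase; ry <- rx * runif(1, 0.6, 1.4)
        gap_px <- (target + 0.015) * parenchyma0 - n_mass_px
        rmax <- sqrt(gap_px / pi * (rx / ry))
        if (rmax < 4) break
        if (rx > rmax) { ry <- ry * rmax / rx; rx <- rmax }
        idx <- ellipse_indices(H, W, py, px, ry, rx)
        idx <- idx[allowed[idx] & !mass[idx]]
        if ((n_mass_px + length(idx)) / parenchyma0 > target + 0.015) next
        mass[idx] <- TRUE
        n_mass_px <- n_mass_px + length(idx)
      }
      label[mass] <- FQ_GT_LABELS[["fibrotic_mass"]]
      # internal structure: masses are cell-rich (fibroblasts, inflammatory
      # cells) with interspersed collagen strands, so they read dense red with
      # fine blue patches - distinct from the solid blue peri-bronchial collar
      patch <- block_noise(H, W, 8)
      material[mass] <- ifelse(patch[mass] < 0.4, FQ_MATERIALS[["collagen"]],
                               FQ_MATERIALS[["tissue"]])
      shade[mass] <- 3L
    }

    # alveolar (septal) collagen: clustered segments on septal pixels
    septal <- label == FQ_GT_LABELS[["alveolar_tissue"]] &
      material == FQ_MATERIALS[["tissue"]]
    gfrac <- params$alveolar_collagen_fraction
    if (gfrac > 0 && any(septal)) {
      # chunky contiguous segments: collagen deposits span stretches of wall
      # rather than scattered single pixels
      u <- block_noise(H, W, 24) + matrix(runif(H * W, 0, 0.1), H, W)
      thr <- quantile(u[septal], 1 - gfrac, names = FALSE)
      coll <- septal & u > thr
      label[coll] <- FQ_GT_LABELS[["alveolar_collagen"]]
      material[coll] <- FQ_MATERIALS[["collagen"]]
    }

    # realized ground-truth fractions
    n_mass <- sum(label == FQ_GT_LABELS[["fibrotic_mass"]])
    n_alv <- sum(label == FQ_GT_LABELS[["alveolar_tissue"]])
    n_acoll <- sum(label == FQ_GT_LABELS[["alveolar_collagen"]])
    n_septal_tissue <- sum(septal & label == FQ_GT_LABELS[["alveolar_tissue"]])
    mass_fraction <- n_mass / (n_mass + n_alv + n_acoll)
    collagen_fraction <- if (n_acoll + n_septal_tissue > 0)
      n_acoll / (n_acoll + n_septal_tissue) else 0

    img <- render_slide(material, shade, params$stain_profile, params$noise_sd)
    pyramid <- build_pyramid(img)

    gt <- structure(list(label_map = label, material_map = material,
                         pixel_size_um = params$pixel_size_um,
                         mass_fraction = mass_fraction,
                         collagen_fraction = collagen_fraction,
                         classes = names(FQ_GT_LABELS)),
                    class = "fq_ground_truth")
    structure(list(pyramid = pyramid, gt = gt, params = params), class = "fq_slide")
  })
}

# Render material map -> 8-bit RGB with stain drift and noise. A mild
# spatially-correlated brightness texture (staining inhomogeneity, section
# thickness variation) overlays all materials: without it every window of a
# flat-shaded world would have identical variance and the variance/edge
# features would be degenerate.
render_slide <- function(material, shade, profile, noise_sd) {
  H <- nrow(material); W <- ncol(material)
  base <- rbind(profile$background, profile$cytoplasm, profile$collagen)
  img <- array(0, dim = c(H, W, 3))
  idx <- as.vector(material) + 1L
  # per-shade brightness of the stained materials (1 alveolar septa, 2 airway
  # wall/peri-bronchial collagen, 3 fibrotic mass): darker, denser staining of
  # smooth muscle and mature collagen
  shade_gain <- c(1, 0.65, 0.9)[as.vector(shade)]
  shade_gain[material == FQ_MATERIALS[["background"]]] <- 1
  tex <- 1 + 0.15 * (2 * block_noise(H, W, 2) - 1) +
             0.08 * (2 * block_noise(H, W, 8) - 1)
  # sections are not uniformly stained: a smooth within-slide gradient of hue
  # (+/-3 deg) and intensity (+/-5%) rides on top of the slide-level profile
  gx <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  gy <- matrix(seq(-1, 1, length.out = H), H, W)
  ang <- runif(1, 0, 2 * pi)
  grad <- cos(ang) * gx + sin(ang) * gy
  tex <- tex * matrix(shade_gain, H, W) * (1 + 0.05 * grad)
  for (ch in 1:3) img[, , ch] <- clamp(matrix(base[idx, ch], H, W) * tex, 0, 255)
  img <- hue_rotate(img, profile$hue_shift_deg + 3 * grad)
  img <- img * profile$intensity_scale
  if (noise_sd > 0) img <- img + array(rnorm(H * W * 3, 0, noise_sd), dim = dim(img))
  img[] <- round(clamp(img, 0, 255))
  img
}

# Global HSV hue rotation of an RGB array (degrees).
hue_rotate <- function(img, deg) {
  if (all(deg == 0)) return(img)
  deg <- as.vector(deg)  # scalar or per-pixel (column-major) rotation
  d <- dim(img)
  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  h <- (hsv[1, ] + deg / 360) %% 1
  s <- hsv[2, ]; v <- hsv[3, ]
  # vectorized HSV -> RGB
  hh <- h * 6
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, dim = d)
  out[, , 1] <- matrix(r * 255, d[1], d[2])
  out[, , 2] <- matrix(g * 255, d[1], d[2])
  out[, , 3] <- matrix(b * 255, d[1], d[2])
  out
}

#' Build a 2x mean-pooled image pyramid
#'
#' Level 1 is full resolution; each further level halves the linear size by
#' 2x2 mean pooling, until the maximum dimension is at most 1024 px.
#' Half-open pixel coordinates, origin top-left.
#'
#' @param img `H x W x 3` numeric array.
#' @return object of class `fq_pyramid`: `levels` (list of arrays) and
#'   `scales` (downsampling factor of each level relative to level 1).
#' @export
build_pyramid <- function(img) {
  levels <- list(img)
  scales <- 1L
  while (max(dim(levels[[length(levels)]])[1:2]) > 1024) {
    prev <- levels[[length(levels)]]
    nxt <- array(0, dim = c(nrow(prev) %/% 2, ncol(prev) %/% 2, 3))
    for (ch in 1:3) nxt[, , ch] <- cpp_mean_downsample2(prev[, , ch, drop = TRUE])
    levels[[length(levels) + 1]] <- nxt
    scales <- c(scales, scales[length(scales)] * 2L)
  }
  structure(list(levels = levels, scales = scales), class = "fq_pyramid")
}

#' @export
print.fq_slide <- function(x, ...) {
  dims <- vapply(x$pyramid$levels, function(l) paste(dim(l)[1:2], collapse = "x"), "")
  cat(sprintf("<fq_slide> %s | levels: %s | mass %.3f, alveolar collagen %.3f\n",
              paste(dim(x$pyramid$levels[[1]])[1:2], collapse = "x"),
              paste(dims, collapse = ", "),
              x$gt$mass_fraction, x$gt$collagen_fraction))
  invisible(x)
}

# Ground-truth label map downsampled to a pyramid scale for low-magnification
# evaluation: alveolar_collagen is part of the alveolar region at low
# magnification, then majority vote per block.
gt_low_mag_labels <- function(gt, scale) {
  lab <- gt$label_map
  lab[lab == FQ_GT_LABELS[["alveolar_collagen"]]] <- FQ_GT_LABELS[["alveolar_tissue"]]
  if (scale == 1) return(lab)
  cpp_mode_downsample(lab, as.integer(scale))
}
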