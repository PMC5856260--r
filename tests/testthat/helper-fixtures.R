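# Shared fixtures, built in code and cached per test run. Slides are kept
# small where geometry permits; classifier fixtures use 1280 px slides so the
# low-magnification level (scale 2) matches the generator's stated world.

fq_test_env <- new.env(parent = emptyenv())

# memoise an expensive fixture within one test run
fixture <- function(name, expr) {
  if (is.null(fq_test_env[[name]])) fq_test_env[[name]] <- force(expr)
  fq_test_env[[name]]
}

random_rgb <- function(H, W, seed = 1) {
  fibroquant:::with_seed(seed, {
    array(sample(0:255, H * W * 3, replace = TRUE), dim = c(H, W, 3))
  })
}

# naive double-loop feature oracle, independent of the package's window-stat
# implementation (direct definition over the clipped window)
naive_features <- function(image, x, y, cfg) {
  r <- cfg$structure_size %/% 2
  d <- dim(image)
  rows <- max(1, y - r):min(d[1], y + r)
  cols <- max(1, x - r):min(d[2], x + r)
  ch_index <- c(R = 1, G = 2, B = 3)
  out <- numeric(0)
  for (ch in cfg$channels) {
    w <- c(image[rows, cols, ch_index[[ch]]])
    c0 <- image[y, x, ch_index[[ch]]]
    for (s in cfg$stats) {
      v <- switch(s,
        center = c0,
        mean = sum(w) / length(w),
        min = min(w),
        max = max(w),
        variance = stats::var(w),
        edge_factor = sum((w - c0)^2) / (length(w) - 1))
      out <- c(out, v)
    }
  }
  setNames(out, cfg$feature_names)
}

# standard disease-like test slide (scale-2 low magnification)
disease_slide <- function() {
  fixture("disease_slide", generate_slide(synthetic_slide_params(
    width_px = 1280L, height_px = 1280L, fibrotic_mass_fraction = 0.30,
    alveolar_collagen_fraction = 0.06, n_bronchi = 3L, seed = 11L)))
}

# trained low/high classifiers from four slides spanning the stain-drift range
trained_models <- function() {
  fixture("trained_models", {
    seeds <- c(21L, 22L, 23L, 24L, 25L, 26L)
    hues <- c(-15, -9, -3, 3, 9, 15)
    gains <- c(0.8, 1.2, 0.95, 1.1, 0.85, 1.05)
    slides <- lapply(seq_along(seeds), function(i) {
      generate_slide(synthetic_slide_params(
        width_px = 1280L, height_px = 1280L, fibrotic_mass_fraction = 0.25,
        alveolar_collagen_fraction = 0.06, n_bronchi = 3L,
        stain_profile = stain_profile(hue_shift_deg = hues[i],
                                      intensity_scale = gains[i]),
        seed = seeds[i]))
    })
    names(slides) <- paste0("fix", seq_along(slides))
    lows <- lapply(slides, function(s) select_low_mag_level(s$pyramid))
    scale_lm <- lows[[1]]$scale
    ann_low <- list(); ann_high <- list()
    for (i in seq_along(slides)) {
      al <- generate_annotations(slides[[i]]$gt, n_regions_per_class = 12L,
                                 seed = 30L + i, model = "low", scale = scale_lm,
                                 image_id = names(slides)[i])
      ah <- generate_annotations(slides[[i]]$gt, n_regions_per_class = 12L,
                                 seed = 60L + i, model = "high", scale = 1L,
                                 image_id = names(slides)[i])
      ann_low <- c(ann_low, al$entries)
      ann_high <- c(ann_high, ah$entries)
    }
    imgs_low <- lapply(lows, `[[`, "image")
    imgs_high <- lapply(slides, function(s) s$pyramid$levels[[1]])
    ts_low <- build_training_set(imgs_low, annotation_set(ann_low),
                                 feature_config(15L), 12000L, seed = 5L)
    ts_high <- build_training_set(imgs_high, annotation_set(ann_high),
                                  feature_config(5L), 12000L, seed = 6L)
    list(clf_low = train_classifier(ts_low),
         clf_high = train_classifier(ts_high),
         ts_low = ts_low, ts_high = ts_high,
         slides = slides, scale_lm = scale_lm)
  })
}

# small, perfectly separable 2-class training set (gaussian blobs)
blob_training_set <- function(n_per = 200L, sep = 8, seed = 1L) {
  fibroquant:::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * 4), n_per, 4),
               matrix(rnorm(n_per * 4, mean = sep), n_per, 4))
    colnames(X) <- paste0("f", 1:4)
    structure(list(features = X,
                   labels = factor(rep(c("a", "b"), each = n_per)),
                   provenance = data.frame(image_id = "synthetic-blobs",
                                           x = seq_len(2 * n_per), y = 1L),
                   sampling_seed = seed,
                   cfg = feature_config(3L)),
              class = "fq_training_set")
  })
}
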