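test_that("parameter validation rejects out-of-range values", {
  expect_error(synthetic_slide_params(width_px = 32L), class = "fq_param_error")
  expect_error(synthetic_slide_params(fibrotic_mass_fraction = 1.2),
               class = "fq_param_error")
  expect_error(synthetic_slide_params(noise_sd = -1), class = "fq_param_error")
  expect_error(stain_profile(collagen = c(0, 0, 300)), class = "fq_param_error")
  expect_error(synthetic_slide_params(n_bronchi = -1), class = "fq_param_error")
})

test_that("nothing requested, nothing drawn", {
  s <- generate_slide(synthetic_slide_params(
    width_px = 320L, height_px = 320L, fibrotic_mass_fraction = 0,
    alveolar_collagen_fraction = 0, n_bronchi = 0L, seed = 3L))
  labs <- sort(unique(as.vector(s$gt$label_map)))
  expect_identical(labs, c(0L, 2L)) # background + alveolar tissue only
})

test_that("realized mass fraction tracks the target within 2 points", {
  # brute-force pixel count on the emitted label map
  s <- generate_slide(synthetic_slide_params(
    width_px = 1280L, height_px = 1280L, fibrotic_mass_fraction = 0.30,
    alveolar_collagen_fraction = 0, n_bronchi = 2L, seed = 1L))
  lm <- s$gt$label_map
  frac <- sum(lm == 1L) / sum(lm %in% c(1L, 2L, 4L))
  expect_gte(frac, 0.28); expect_lte(frac, 0.32)
  expect_equal(frac, s$gt$mass_fraction)
})

test_that("generation is deterministic and stain drift never alters ground truth", {
  p <- synthetic_slide_params(width_px = 320L, height_px = 320L,
                              fibrotic_mass_fraction = 0.2,
                              alveolar_collagen_fraction = 0.05,
                              n_bronchi = 1L, seed = 9L)
  s1 <- generate_slide(p); s2 <- generate_slide(p)
  expect_identical(s1$pyramid$levels[[1]], s2$pyramid$levels[[1]])
  expect_identical(s1$gt$label_map, s2$gt$label_map)
  # different stain profile, same seed: identical labels, different pixels
  p_drift <- synthetic_slide_params(width_px = 320L, height_px = 320L,
                                    fibrotic_mass_fraction = 0.2,
                                    alveolar_collagen_fraction = 0.05,
                                    n_bronchi = 1L, seed = 9L,
                                    stain_profile = stain_profile(
                                      hue_shift_deg = 14, intensity_scale = 0.85))
  s3 <- generate_slide(p_drift)
  expect_identical(s1$gt$label_map, s3$gt$label_map)
  expect_identical(s1$gt$material_map, s3$gt$material_map)
  expect_false(identical(s1$pyramid$levels[[1]], s3$pyramid$levels[[1]]))
})

test_that("labels partition the image and collagen stays within alveolar walls", {
  s <- disease_slide()
  lm <- s$gt$label_map
  expect_identical(sum(tabulate(lm + 1L, 5)), length(lm)) # every pixel labelled
  expect_true(all(lm %in% 0:4))
  # alveolar collagen lies on septal pixels: material is collagen there and
  # those pixels sit inside the alveolar region (never masses/bronchi/background)
  coll <- lm == 4L
  expect_true(all(s$gt$material_map[coll] == 2L))
  # fractions over classes sum to one exactly
  expect_equal(sum(table(lm) / length(lm)), 1)
})

test_that("mass burden is monotone in the requested fraction (across seeds)", {
  mean_count <- function(target) {
    mean(vapply(1:5, function(seed) {
      s <- generate_slide(synthetic_slide_params(
        width_px = 320L, height_px = 320L, fibrotic_mass_fraction = target,
        alveolar_collagen_fraction = 0, n_bronchi = 0L, seed = seed))
      sum(s$gt$label_map == 1L)
    }, 0))
  }
  counts <- vapply(c(0.05, 0.15, 0.30, 0.45), mean_count, 0)
  expect_true(all(diff(counts) > 0))
})

test_that("pyramids halve by mean pooling down to <= 1024 px", {
  s <- disease_slide()
  expect_identical(dim(s$pyramid$levels[[1]])[1:2], c(1280L, 1280L))
  expect_identical(dim(s$pyramid$levels[[2]])[1:2], c(640L, 640L))
  expect_identical(s$pyramid$scales, c(1L, 2L))
  # mean pooling oracle on a corner block
  l0 <- s$pyramid$levels[[1]]; l1 <- s$pyramid$levels[[2]]
  expect_equal(l1[1, 1, 2], mean(l0[1:2, 1:2, 2]))
  expect_equal(l1[5, 9, 1], mean(l0[9:10, 17:18, 1]))
  # small images stay single-level
  s2 <- generate_slide(synthetic_slide_params(width_px = 320L, height_px = 320L,
                                              n_bronchi = 0L, seed = 2L))
  expect_length(s2$pyramid$levels, 1)
})

test_that("generate_annotations places pure interior polygons", {
  s <- disease_slide()
  low_scale <- select_low_mag_level(s$pyramid)$scale
  ann <- generate_annotations(s$gt, n_regions_per_class = 3L, seed = 5L,
                              model = "low", scale = low_scale)
  expect_length(ann$entries, 12) # 3 regions x 4 classes
  lab_lm <- fibroquant:::gt_low_mag_labels(s$gt, low_scale)
  for (e in ann$entries) {
    px <- fibroquant:::rasterize_polygon(e$polygon, nrow(lab_lm), ncol(lab_lm))
    expect_gt(nrow(px), 0)
    expect_true(all(lab_lm[px] == fibroquant:::FQ_GT_LABELS[[e$class]]))
  }
  # seeded determinism
  ann2 <- generate_annotations(s$gt, n_regions_per_class = 3L, seed = 5L,
                               model = "low", scale = low_scale)
  expect_identical(ann$entries, ann2$entries)
  # high-magnification annotations are pure in material terms
  annh <- generate_annotations(s$gt, n_regions_per_class = 3L, seed = 6L,
                               model = "high", scale = 1L)
  mat_codes <- c(collagen = 2L, lung_tissue = 1L, background = 0L)
  for (e in annh$entries) {
    px <- fibroquant:::rasterize_polygon(e$polygon, nrow(s$gt$material_map),
                                         ncol(s$gt$material_map))
    expect_true(all(s$gt$material_map[px] == mat_codes[[e$class]]))
  }
})

test_that("annotations on a class-free ground truth raise a missing-class error", {
  s <- generate_slide(synthetic_slide_params(
    width_px = 320L, height_px = 320L, fibrotic_mass_fraction = 0,
    alveolar_collagen_fraction = 0, n_bronchi = 0L, seed = 3L))
  expect_error(generate_annotations(s$gt, model = "low", scale = 1L),
               class = "fq_missing_class_error")
  expect_error(generate_annotations(s$gt, model = "high", scale = 1L),
               class = "fq_missing_class_error") # no collagen anywhere
})

test_that("generate_study emits consistent metadata and distinct groups", {
  base <- synthetic_slide_params(width_px = 256L, height_px = 256L, n_bronchi = 0L)
  study <- generate_study(list(
    group_spec("saline", 4L, mass_fraction = 0.02, collagen_fraction = 0.01),
    group_spec("bleomycin", 4L, mass_fraction = 0.40, collagen_fraction = 0.08)),
    seed = 2L, base_params = base)
  expect_identical(nrow(study$metadata), 8L)
  expect_identical(length(study$slides), 8L)
  m <- study$metadata
  expect_true(all(table(m$group) == 4))
  gm <- tapply(m$true_mass_fraction, m$group, mean)
  expect_gt(gm[["bleomycin"]] - gm[["saline"]], 0.3)
  # stain drift stays within the stated range
  expect_true(all(abs(m$hue_shift_deg) <= 15))
  expect_true(all(m$intensity_scale >= 0.8 & m$intensity_scale <= 1.2))
  # different study seeds give different slides and disjoint ids
  study2 <- generate_study(list(group_spec("saline", 1L, 0.02)), seed = 3L,
                           base_params = base)
  expect_false(any(study2$metadata$slide_id %in% m$slide_id))
  # minimal study
  expect_identical(nrow(study2$metadata), 1L)
  expect_error(generate_study(list()), class = "fq_param_error")
})
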