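test_that("tile_grid partitions the image exactly once", {
  tiles <- tile_grid(1024, 1024)
  expect_length(tiles, 4)
  expect_true(all(vapply(tiles, function(t) t$width == 512 && t$height == 512, NA)))
  # sub-tile image
  t1 <- tile_grid(100, 100)
  expect_length(t1, 1)
  expect_identical(c(t1[[1]]$width, t1[[1]]$height), c(100L, 100L))
  # remainder column
  t2 <- tile_grid(513, 512)
  expect_length(t2, 2)
  expect_identical(sort(vapply(t2, `[[`, 0L, "width")), c(1L, 512L))
  # exact cover, no overlap (pixel bookkeeping over an odd-size image)
  tiles <- tile_grid(700, 530)
  cover <- matrix(0L, 530, 700)
  for (t in tiles)
    cover[t$y0 + seq_len(t$height), t$x0 + seq_len(t$width)] <-
      cover[t$y0 + seq_len(t$height), t$x0 + seq_len(t$width)] + 1L
  expect_true(all(cover == 1L))
  expect_error(tile_grid(0, 10), class = "fq_param_error")
})

test_that("upsample_roi does nearest-neighbour index arithmetic", {
  # checkerboard ROI at scale 4 expands to 4x4 blocks
  roi <- structure(list(mask = outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0),
                        scale = 4L), class = "fq_roi_mask")
  tile <- list(id = 1L, x0 = 0L, y0 = 0L, width = 32L, height = 32L)
  up <- upsample_roi(roi, tile)
  # oracle: explicit floor-division lookup per level-0 pixel
  for (k in 1:50) {
    set.seed(k)
    y <- sample(0:31, 1); x <- sample(0:31, 1)
    expect_identical(up[y + 1, x + 1], roi$mask[y %/% 4 + 1, x %/% 4 + 1])
  }
  # all-true / all-false
  roi$mask[] <- TRUE
  expect_true(all(upsample_roi(roi, tile)))
  roi$mask[] <- FALSE
  expect_false(any(upsample_roi(roi, tile)))
  expect_error(upsample_roi(roi, list(id = 2L, x0 = 4000L, y0 = 0L,
                                      width = 8L, height = 8L)),
               class = "fq_bounds_error")
})

test_that("reduce_tiles is an order-independent element-wise sum", {
  mk <- function(id, coll, tis, bg)
    list(tile_id = id, counts = c(collagen = coll, lung_tissue = tis,
                                  background = bg), roi_px = coll + tis + bg)
  results <- list(mk(1L, 5L, 10L, 2L), mk(2L, 0L, 0L, 0L), mk(3L, 7L, 1L, 9L))
  agg <- reduce_tiles(results)
  expect_identical(agg$counts, c(collagen = 12L, lung_tissue = 11L, background = 11L))
  expect_identical(agg$roi_px, 34L)
  # single tile is the identity; shuffling does not change the aggregate
  expect_identical(reduce_tiles(results[1])$counts, results[[1]]$counts)
  expect_identical(reduce_tiles(rev(results)), agg)
  expect_error(reduce_tiles(list(mk(1L, 1L, 1L, 1L), mk(1L, 2L, 2L, 2L))),
               class = "fq_aggregation_error")
})

test_that("collagen percentages follow their declared formulas", {
  agg <- list(counts = c(collagen = 50, lung_tissue = 950, background = 4000),
              roi_px = 5000)
  # background (alveolar air) excluded from the tissue denominator
  expect_equal(alveolar_collagen_percent(agg), 5)
  expect_equal(alveolar_collagen_percent(agg, denominator = "roi"), 1)
  agg0 <- list(counts = c(collagen = 0, lung_tissue = 100, background = 0))
  expect_equal(alveolar_collagen_percent(agg0), 0)
  agg1 <- list(counts = c(collagen = 70, lung_tissue = 0, background = 30))
  expect_equal(alveolar_collagen_percent(agg1), 100)
  expect_error(alveolar_collagen_percent(
    list(counts = c(collagen = 0, lung_tissue = 0, background = 5))),
    class = "fq_undefined_readout_error")
})

test_that("total collagen combines both stages as declared", {
  emap <- fibroquant:::class_map(
    labels = matrix(rep(1:4, c(100, 30, 60, 10)), 10, 20),
    classes = c("background", "fibrotic_mass", "alveolar_tissue", "bronchus"),
    scale = 2L)
  # hand-computed: mass at level 0 = 30 * 4 = 120
  agg <- list(counts = c(collagen = 40, lung_tissue = 360, background = 100))
  expect_equal(total_collagen_percent(agg, emap),
               100 * (40 + 120) / (40 + 360 + 120))
  # zero mass, zero collagen
  emap0 <- fibroquant:::class_map(matrix(3L, 5, 5), emap$classes, 1L)
  agg0 <- list(counts = c(collagen = 0, lung_tissue = 10, background = 0))
  expect_equal(total_collagen_percent(agg0, emap0), 0)
  # lower bound: >= alveolar share times alveolar collagen percent
  expect_gte(total_collagen_percent(agg, emap),
             alveolar_collagen_percent(agg) *
               (agg$counts[["lung_tissue"]] + agg$counts[["collagen"]]) /
               (agg$counts[["lung_tissue"]] + agg$counts[["collagen"]] + 120))
  expect_error(total_collagen_percent(list(), emap),
               class = "fq_dependency_error")
})

test_that("readouts and QC on constructed exclusion maps", {
  classes <- c("background", "fibrotic_mass", "alveolar_tissue", "bronchus")
  # 300 mass / 700 alveolar / 500 bronchus / rest background
  lab <- matrix(1L, 50, 50)
  lab[1:300 + 100] <- 2L
  lab[1000 + 1:700] <- 3L
  lab[1900 + 1:500] <- 4L
  map <- fibroquant:::class_map(lab, classes, 1L)
  expect_equal(fibrotic_mass_percent(map), 30)
  # zero mass
  lab2 <- lab; lab2[lab2 == 2L] <- 3L
  expect_equal(fibrotic_mass_percent(fibroquant:::class_map(lab2, classes, 1L)), 0)
  # all-mass tissue
  lab3 <- lab; lab3[lab3 == 3L] <- 2L
  expect_equal(fibrotic_mass_percent(fibroquant:::class_map(lab3, classes, 1L)), 100)
  # collapsed slide: only background
  blank <- fibroquant:::class_map(matrix(1L, 20, 20), classes, 1L)
  expect_error(fibrotic_mass_percent(blank), class = "fq_undefined_readout_error")
  expect_true(qc_flag_collapsed(blank)$flagged)
  expect_false(qc_flag_collapsed(map)$flagged)
  # vacuous thresholds never flag
  expect_false(qc_flag_collapsed(blank, min_tissue_fraction = 0,
                                 min_alveolar_fraction = 0)$flagged)
})

test_that("derive_roi selects exactly the alveolar pixels", {
  classes <- c("background", "fibrotic_mass", "alveolar_tissue", "bronchus")
  set.seed(3)
  lab <- matrix(sample(1:4, 400, replace = TRUE), 20, 20)
  map <- fibroquant:::class_map(lab, classes, 2L)
  roi <- derive_roi(map)
  expect_identical(sum(roi$mask), sum(lab == 3L))
  expect_false(any(roi$mask & lab != 3L))
  # empty ROI warns
  expect_warning(derive_roi(fibroquant:::class_map(matrix(1L, 5, 5), classes, 1L)),
                 "no alveolar tissue")
})
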