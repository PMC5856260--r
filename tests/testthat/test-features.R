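test_that("edge_factor matches direct summation and its algebraic properties", {
  # constructed 3x3 example: center 2 surrounded by zeros
  w <- c(0, 0, 0, 0, 2, 0, 0, 0, 0)
  expect_identical(edge_factor(w, 2), 8 * 4 / 8) # = 4 exactly
  # constant windows vanish
  for (c0 in c(0, 17, 255)) expect_identical(edge_factor(rep(c0, 25), c0), 0)
  # homogeneity: scaling values by k scales the result by k^2
  set.seed(1)
  w <- runif(49, 0, 255); c0 <- w[25]
  expect_equal(edge_factor(3 * w, 3 * c0), 9 * edge_factor(w, c0))
  # degenerate window
  expect_error(edge_factor(5, 5), class = "fq_degenerate_window_error")
})

test_that("feature_config validates structure size and feature lists", {
  cfg <- feature_config(5L)
  expect_length(cfg$feature_names, 18)
  expect_identical(cfg$feature_names[1:6],
                   c("R.center", "R.mean", "R.min", "R.max", "R.variance",
                     "R.edge_factor"))
  expect_error(feature_config(4L), class = "fq_param_error")
  expect_error(feature_config(1L), class = "fq_param_error")
})

test_that("pixel_features equals the naive oracle, including clipped borders", {
  img <- random_rgb(9, 9, seed = 7)
  cfg <- feature_config(5L)
  # center, corner (clipped window), edge
  for (pt in list(c(5, 5), c(1, 1), c(9, 2), c(3, 9))) {
    got <- pixel_features(img, x = pt[1], y = pt[2], cfg)
    want <- naive_features(img, x = pt[1], y = pt[2], cfg)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # uniform image: mean=min=max=value, variance=edge=0
  uni <- array(93, dim = c(8, 8, 3))
  f <- pixel_features(uni, 4, 4, cfg)
  expect_equal(unname(f[c("G.mean", "G.min", "G.max")]), rep(93, 3))
  expect_identical(unname(f[c("G.variance", "G.edge_factor")]), c(0, 0))
  expect_error(pixel_features(img, 10, 1, cfg), class = "fq_bounds_error")
})

test_that("feature_block equals the per-pixel oracle on random images", {
  # oracle equivalence on full 32x32 images, several seeds and window sizes
  for (seed in 1:3) {
    img <- random_rgb(32, 32, seed = seed)
    for (ss in c(3L, 5L, 9L)) {
      cfg <- feature_config(ss)
      fb <- feature_block(img, cfg)
      expect_identical(nrow(fb$features), 32L * 32L)
      # row order is the row-major scan
      expect_identical(fb$pixels[1:3, 2], c(1L, 2L, 3L))
      expect_identical(fb$pixels[1:3, 1], c(1L, 1L, 1L))
      naive <- t(vapply(seq_len(nrow(fb$pixels)), function(i)
        naive_features(img, fb$pixels[i, 2], fb$pixels[i, 1], cfg),
        numeric(length(cfg$feature_names))))
      rel <- abs(fb$features - naive) / pmax(1, abs(naive))
      expect_lt(max(rel), 1e-9)
    }
  }
})

test_that("feature_block respects masks and handles empty masks", {
  img <- random_rgb(16, 16, seed = 2)
  cfg <- feature_config(5L)
  # singleton mask equals the per-pixel call
  m <- matrix(FALSE, 16, 16); m[6, 11] <- TRUE
  fb <- feature_block(img, cfg, m)
  expect_identical(nrow(fb$features), 1L)
  expect_equal(fb$features[1, ], pixel_features(img, 11, 6, cfg), tolerance = 1e-12)
  # empty mask: zero rows, not an error
  fb0 <- feature_block(img, cfg, matrix(FALSE, 16, 16))
  expect_identical(nrow(fb0$features), 0L)
  # full mask count
  expect_identical(nrow(feature_block(img, cfg)$features), 256L)
  expect_error(feature_block(img, cfg, matrix(TRUE, 4, 4)), class = "fq_param_error")
})

test_that("feature maps are translation-equivariant away from borders", {
  base <- random_rgb(40, 40, seed = 9)
  shift <- 5L
  shifted <- base[, c((shift + 1):40, 1:shift), , drop = FALSE]
  cfg <- feature_config(5L)
  fb_a <- feature_block(base, cfg)
  fb_b <- feature_block(shifted, cfg)
  A <- array(fb_a$features[, "B.edge_factor"], dim = c(40, 40))
  # row-major rows: reshape accordingly
  A <- matrix(fb_a$features[, "B.edge_factor"], 40, 40, byrow = TRUE)
  B <- matrix(fb_b$features[, "B.edge_factor"], 40, 40, byrow = TRUE)
  expect_equal(B[10:30, 10:30], A[10:30, (10 + shift):(30 + shift)])
})
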