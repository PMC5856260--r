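test_that("build_training_set samples uniformly from annotated pixels", {
  img <- random_rgb(64, 64, seed = 1)
  sq <- function(x0, y0, s) cbind(x = c(x0, x0 + s, x0 + s, x0),
                                  y = c(y0, y0, y0 + s, y0 + s))
  ann <- annotation_set(list(
    list(image_id = "a", scale = 1L, class = "dark", polygon = sq(2, 2, 20)),
    list(image_id = "a", scale = 1L, class = "light", polygon = sq(30, 30, 20))))
  cfg <- feature_config(3L)
  # ample pixels: exact requested count
  ts <- build_training_set(list(a = img), ann, cfg, n_samples = 100L, seed = 3L)
  expect_identical(nrow(ts$features), 100L)
  expect_identical(levels(ts$labels), c("dark", "light"))
  # every provenance pixel, re-rasterized, carries its stored label
  dark_px <- fibroquant:::rasterize_polygon(sq(2, 2, 20), 64, 64)
  in_dark <- paste(ts$provenance$y, ts$provenance$x) %in%
    paste(dark_px[, 1], dark_px[, 2])
  expect_identical(in_dark, ts$labels == "dark")
  # undersupply: all pixels used, with a warning
  expect_warning(
    ts_all <- build_training_set(list(a = img), ann, cfg, n_samples = 5000L),
    "using all")
  expect_identical(nrow(ts_all$features), 2L * 20L * 20L)
  # reproducibility
  ts2 <- build_training_set(list(a = img), ann, cfg, n_samples = 100L, seed = 3L)
  expect_identical(ts$provenance, ts2$provenance)
  # features match direct per-pixel computation
  i <- 17L
  expect_equal(ts$features[i, ],
               pixel_features(img, ts$provenance$x[i], ts$provenance$y[i], cfg),
               tolerance = 1e-12)
})

test_that("build_training_set rejects conflicts, missing classes, stray polygons", {
  img <- random_rgb(32, 32, seed = 2)
  sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
                                  c(y0, y0, y0 + s, y0 + s))
  cfg <- feature_config(3L)
  overlap <- annotation_set(list(
    list(image_id = "a", scale = 1L, class = "x", polygon = sq(2, 2, 10)),
    list(image_id = "a", scale = 1L, class = "y", polygon = sq(8, 8, 10))))
  expect_error(build_training_set(list(a = img), overlap, cfg, 10L),
               class = "fq_conflict_error")
  outside <- annotation_set(list(
    list(image_id = "a", scale = 1L, class = "x", polygon = sq(2, 2, 10)),
    list(image_id = "a", scale = 1L, class = "y", polygon = sq(28, 28, 10))))
  expect_error(build_training_set(list(a = img), outside, cfg, 10L),
               class = "fq_param_error")
  single <- annotation_set(list(
    list(image_id = "a", scale = 1L, class = "x", polygon = sq(2, 2, 10))))
  expect_error(build_training_set(list(a = img), single, cfg, 10L),
               class = "fq_degenerate_training_error")
})

test_that("training separates Gaussian blobs and is deterministic", {
  ts <- blob_training_set()
  clf <- train_classifier(ts, svm_config(n_rff = 64L))
  expect_identical(clf$resub_accuracy, 1)
  probe <- blob_training_set(seed = 42L)$features
  p1 <- fibroquant:::fq_svm_predict(clf$svm, probe)
  clf2 <- train_classifier(ts, svm_config(n_rff = 64L))
  expect_identical(p1, fibroquant:::fq_svm_predict(clf2$svm, probe))
  # single class is degenerate
  ts1 <- ts; ts1$labels <- factor(rep("a", nrow(ts$features)))
  expect_error(train_classifier(ts1), class = "fq_degenerate_training_error")
})

test_that("standardization constants are stored and finite", {
  ts <- blob_training_set()
  clf <- train_classifier(ts, svm_config(n_rff = 32L))
  expect_true(all(is.finite(clf$svm$center)))
  expect_true(all(is.finite(clf$svm$spread)) && all(clf$svm$spread > 0))
  # round-trip invariance: shifting/scaling inputs with compensated constants
  # leaves predictions unchanged
  shift <- c(10, -5, 3, 0); scl <- c(2, 0.5, 1, 4)
  X2 <- sweep(sweep(ts$features, 2, scl, "*"), 2, shift, "+")
  clf_manual <- clf
  clf_manual$svm$center <- clf$svm$center * scl + shift
  clf_manual$svm$spread <- clf$svm$spread * scl
  probe <- blob_training_set(seed = 5L)$features
  probe2 <- sweep(sweep(probe, 2, scl, "*"), 2, shift, "+")
  expect_equal(fibroquant:::fq_svm_scores(clf_manual$svm, probe2),
               fibroquant:::fq_svm_scores(clf$svm, probe), tolerance = 1e-9)
})

test_that("cross-validation partitions are valid and stratified", {
  ts <- blob_training_set(n_per = 53L)
  rep <- cross_validate(ts, k = 5L, config = svm_config(n_rff = 32L), seed = 2L)
  expect_length(rep$fold_accuracy, 5)
  expect_equal(rep$mean_accuracy, mean(rep$fold_accuracy))
  # every sample tested exactly once; per-class fold sizes differ by <= 1
  expect_identical(sort(unique(rep$folds)), 1:5)
  for (cl in levels(ts$labels)) {
    sizes <- table(rep$folds[ts$labels == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # confusion conserves the sample count and row sums equal class counts
  expect_identical(sum(rep$confusion), nrow(ts$features))
  expect_equal(unname(rowSums(rep$confusion)), unname(c(table(ts$labels))),
               ignore_attr = TRUE)
  # separable blobs: perfect mean accuracy
  expect_identical(rep$mean_accuracy, 1)
  # class smaller than k
  ts_small <- ts
  ts_small$labels[ts_small$labels == "b"] <- "a"
  ts_small$labels[1:3] <- "b"
  expect_error(cross_validate(ts_small, k = 5L), class = "fq_stratification_error")
})

test_that("shuffled labels drive CV accuracy to chance", {
  # permutation null: balanced 2-class set, labels shuffled; mean CV accuracy
  # averaged over repeats should approach 0.5
  accs <- vapply(1:8, function(r) {
    ts <- blob_training_set(n_per = 60L, sep = 8, seed = r)
    ts$labels <- fibroquant:::with_seed(100L + r, sample(ts$labels))
    cross_validate(ts, k = 5L, config = svm_config(n_rff = 32L),
                   seed = r)$mean_accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("classify honours masks and reports unclassified pixels", {
  ts <- blob_training_set()
  clf <- train_classifier(ts, svm_config(n_rff = 32L))
  clf$cfg <- feature_config(3L, channels = c("R", "G", "B"),
                            stats = c("mean", "min", "max", "variance", "edge_factor"))
  # build a trivially separable image classifier instead: two-tone image
  img <- array(0, dim = c(20, 20, 3)); img[, 11:20, ] <- 200
  sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
                                  c(y0, y0, y0 + s, y0 + s))
  ann <- annotation_set(list(
    list(image_id = "a", scale = 1L, class = "dark", polygon = sq(1, 1, 6)),
    list(image_id = "a", scale = 1L, class = "light", polygon = sq(13, 13, 6))))
  ts2 <- suppressWarnings(build_training_set(list(a = img), ann,
                                             feature_config(3L), 50L))
  clf2 <- train_classifier(ts2, svm_config(n_rff = 32L))
  cm <- classify(img, clf2)
  expect_identical(sort(unique(as.vector(cm$labels))), c(1L, 2L))
  expect_true(all(cm$labels[, 1:8] == match("dark", clf2$classes)))
  expect_true(all(cm$labels[, 13:20] == match("light", clf2$classes)))
  # empty mask: all unclassified
  cm0 <- classify(img, clf2, mask = matrix(FALSE, 20, 20))
  expect_true(all(cm0$labels == 0L))
  expect_identical(class_counts(cm0, drop_unclassified = FALSE)[["unclassified"]],
                   400L)
})
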