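#' Build the pixel training set from annotated images
#'
#' Rasterizes every annotation polygon, pools the annotated pixels over all
#' classes and images, and draws `n_samples` pixels uniformly at random
#' without replacement (all pixels, with a warning, if fewer are available).
#' Features are computed per pixel with the given configuration; sampling is
#' uniform over the pooled pixels, not stratified, matching random picking
#' "over every class and picture".
#'
#' @param images named list of `H x W x 3` arrays; names are image ids, each
#'   image given at the scale its annotations refer to.
#' @param annotations an [annotation_set()]; every entry's `image_id` must
#'   appear in `images`.
#' @param cfg a [feature_config()].
#' @param n_samples training-set size cap (default 40000).
#' @param seed sampling seed.
#' @return object of class `fq_training_set`: `features` (n x n_features),
#'   `labels` (factor), `provenance` (data.frame image_id, x, y),
#'   `sampling_seed`, `cfg`.
#' @export
build_training_set <- function(images, annotations, cfg, n_samples = 40000L,
                               seed = 1L) {
  if (!inherits(annotations, "fq_annotation_set"))
    fq_stop("fq_param_error", "annotations must be an annotation_set()")
  if (is.null(names(images)) || any(names(images) == ""))
    fq_stop("fq_param_error", "images must be a named list")
  ids <- vapply(annotations$entries, `[[`, "", "image_id")
  if (!all(ids %in% names(images)))
    fq_stop("fq_param_error", "annotations reference unknown images: %s",
            paste(setdiff(ids, names(images)), collapse = ", "))

  all_classes <- unique(vapply(annotations$entries, `[[`, "", "class"))
  if (length(all_classes) < 2)
    fq_stop("fq_degenerate_training_error", "need annotations for >= 2 classes")

  recs <- list()
  for (id in unique(ids)) {
    img <- images[[id]]
    d <- dim(img)
    # class id per pixel; 0 = unannotated, -1 = conflict
    owner <- matrix(0L, d[1], d[2])
    owner_cls <- character(0)
    conflicts <- character(0)
    for (e in annotations$entries[ids == id]) {
      if (min(e$polygon[, 1]) < 0 || min(e$polygon[, 2]) < 0 ||
          max(e$polygon[, 1]) > d[2] || max(e$polygon[, 2]) > d[1])
        fq_stop("fq_param_error",
                "a '%s' polygon on image '%s' lies outside the %dx%d image",
                e$class, id, d[2], d[1])
      px <- rasterize_polygon(e$polygon, d[1], d[2])
      if (nrow(px) == 0) next
      cid <- match(e$class, owner_cls)
      if (is.na(cid)) { owner_cls <- c(owner_cls, e$class); cid <- length(owner_cls) }
      prev <- owner[px]
      clash <- prev != 0L & prev != cid
      if (any(clash))
        conflicts <- union(conflicts,
                           paste(sort(c(e$class, owner_cls[unique(prev[clash])])),
                                 collapse = " vs "))
      owner[px] <- cid
    }
    if (length(conflicts) > 0)
      fq_stop("fq_conflict_error",
              "overlapping polygons of different classes on image '%s': %s",
              id, paste(conflicts, collapse = "; "))
    sel <- which(owner > 0L, arr.ind = TRUE)
    if (nrow(sel) > 0)
      recs[[id]] <- data.frame(image_id = id, row = sel[, 1], col = sel[, 2],
                               class = owner_cls[owner[sel]],
                               stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, recs)
  missing <- setdiff(all_classes, unique(pool$class))
  if (length(missing) > 0)
    fq_stop("fq_missing_class_error", "class(es) with zero annotated pixels: %s",
            paste(missing, collapse = ", "))

  n_total <- nrow(pool)
  take <- with_seed(seed, {
    if (n_total >= n_samples) sample.int(n_total, n_samples)
    else {
      fq_warn("only %d annotated pixels available (< n_samples = %d); using all",
              n_total, n_samples)
      seq_len(n_total)
    }
  })
  pool <- pool[take, , drop = FALSE]

  classes <- canonical_classes(unique(pool$class))
  feats <- matrix(NA_real_, nrow(pool), length(cfg$feature_names),
                  dimnames = list(NULL, cfg$feature_names))
  for (id in unique(pool$image_id)) {
    sel <- pool$image_id == id
    maps <- feature_maps(images[[id]], cfg)
    idx <- cbind(pool$row[sel], pool$col[sel])
    k <- 1L
    for (ch in cfg$channels) for (s in cfg$stats) {
      feats[sel, k] <- maps[[ch]][[s]][idx]
      k <- k + 1L
    }
  }
  structure(list(features = feats,
                 labels = factor(pool$class, levels = classes),
                 provenance = data.frame(image_id = pool$image_id,
                                         x = pool$col, y = pool$row),
                 sampling_seed = as.integer(seed), cfg = cfg),
            class = "fq_training_set")
}

#' @export
print.fq_training_set <- function(x, ...) {
  cat(sprintf("<fq_training_set> %d pixels x %d features; classes: %s\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s (%d)", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Train the SVM tissue classifier
#'
#' Features are standardized (constants stored with the model) and a
#' one-vs-rest RBF SVM is fitted. Training is deterministic given `seed`.
#'
#' @param ts an [build_training_set()] result.
#' @param config an [svm_config()].
#' @param seed training seed (random Fourier draw + solver order); defaults to
#'   the training set's sampling seed.
#' @return object of class `fq_tissue_classifier` with the fitted SVM, class
#'   list, feature configuration and resubstitution accuracy.
#' @export
train_classifier <- function(ts, config = svm_config(), seed = NULL) {
  if (!inherits(ts, "fq_training_set"))
    fq_stop("fq_param_error", "ts must be an fq_training_set")
  if (nlevels(ts$labels) < 2 || length(unique(ts$labels)) < 2)
    fq_stop("fq_degenerate_training_error", "training set has a single class")
  seed <- as.integer(seed %||% ts$sampling_seed)
  model <- fq_svm_fit(ts$features, ts$labels, config, seed)
  pred <- fq_svm_predict(model, ts$features)
  resub <- mean(model$classes[pred] == as.character(ts$labels))
  structure(list(svm = model, classes = model$classes, cfg = ts$cfg,
                 svm_config = config, resub_accuracy = resub, seed = seed,
                 training_hash = fq_hash(list(ts$provenance, ts$sampling_seed))),
            class = "fq_tissue_classifier")
}

#' @export
print.fq_tissue_classifier <- function(x, ...) {
  cat(sprintf("<fq_tissue_classifier> classes: %s | structure_size=%d | resub acc %.4f\n",
              paste(x$classes, collapse = ", "), x$cfg$structure_size,
              x$resub_accuracy))
  invisible(x)
}

#' Stratified k-fold cross-validation of the pixel classifier
#'
#' Samples are partitioned into k folds, stratified by class (per-class fold
#' sizes differ by at most one); each fold is held out once while the model is
#' trained on the remaining 9/10 (for k = 10), so every sample is tested
#' exactly once on a model that never saw it.
#'
#' @inheritParams train_classifier
#' @param k number of folds (default 10).
#' @param seed fold-assignment and training seed.
#' @return object of class `fq_cv_report`: `fold_accuracy` (k values),
#'   `mean_accuracy`, `confusion` (true x predicted, summed over folds),
#'   `folds` (per-sample fold id).
#' @export
cross_validate <- function(ts, k = 10L, config = svm_config(), seed = 1L) {
  if (!inherits(ts, "fq_training_set"))
    fq_stop("fq_param_error", "ts must be an fq_training_set")
  counts <- table(ts$labels)
  if (any(counts < k))
    fq_stop("fq_stratification_error",
            "class(es) with fewer samples than k=%d folds: %s", k,
            paste(names(counts)[counts < k], collapse = ", "))
  n <- nrow(ts$features)
  folds <- integer(n)
  with_seed(derive_seed(seed, 7L), {
    for (cl in levels(ts$labels)) {
      idx <- which(ts$labels == cl)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  classes <- levels(ts$labels)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- fq_svm_fit(ts$features[tr, , drop = FALSE],
                        droplevels(ts$labels[tr]),
                        config, derive_seed(seed, 1000L + f))
    pred <- model$classes[fq_svm_predict(model, ts$features[!tr, , drop = FALSE])]
    truth <- as.character(ts$labels[!tr])
    acc[f] <- mean(pred == truth)
    tab <- table(factor(truth, classes), factor(pred, classes))
    confusion <- confusion + tab
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 confusion = confusion, folds = folds, k = k),
            class = "fq_cv_report")
}

#' @export
print.fq_cv_report <- function(x, ...) {
  cat(sprintf("<fq_cv_report> %d-fold CV: mean accuracy %.4f (folds %.4f-%.4f)\n",
              x$k, x$mean_accuracy, min(x$fold_accuracy), max(x$fold_accuracy)))
  print(x$confusion)
  invisible(x)
}

#' Classify the pixels of an image
#'
#' Applies a trained classifier to every pixel (or every masked pixel) of an
#' image; pixels outside the mask are labelled "unclassified" (code 0).
#'
#' @param image `H x W x 3` array; channels must match the classifier's
#'   feature configuration.
#' @param clf an `fq_tissue_classifier`.
#' @param mask optional logical matrix restricting classification.
#' @param scale pyramid scale of `image` (recorded in the result).
#' @param pixel_size_um physical pixel size at this scale (metadata).
#' @return object of class `fq_class_map`: `labels` (integer matrix, 0 =
#'   unclassified, i = i-th entry of `classes`), `classes`, `scale`,
#'   `pixel_size_um`.
#' @export
classify <- function(image, clf, mask = NULL, scale = 1, pixel_size_um = NA_real_) {
  if (!inherits(clf, "fq_tissue_classifier"))
    fq_stop("fq_param_error", "clf must be an fq_tissue_classifier")
  d <- dim(image)
  if (length(d) != 3 || d[3] < length(clf$cfg$channels))
    fq_stop("fq_config_error", "image channels do not match the feature configuration")
  fb <- feature_block(image, clf$cfg, mask)
  labels <- matrix(0L, d[1], d[2])
  if (nrow(fb$features) > 0)
    labels[fb$pixels] <- fq_svm_predict(clf$svm, fb$features)
  class_map(labels, clf$classes, scale, pixel_size_um)
}

# TissueClassMap constructor (shared by classify and the ROI pipeline).
class_map <- function(labels, classes, scale = 1, pixel_size_um = NA_real_) {
  structure(list(labels = labels, classes = classes, scale = scale,
                 pixel_size_um = pixel_size_um),
            class = "fq_class_map")
}

#' Per-class pixel counts of a class map
#'
#' @param map an `fq_class_map`.
#' @param drop_unclassified if `FALSE`, an `unclassified` count is included.
#' @return named integer vector in class-list order.
#' @export
class_counts <- function(map, drop_unclassified = TRUE) {
  tab <- tabulate(map$labels + 1L, nbins = length(map$classes) + 1L)
  out <- setNames(tab[-1], map$classes)
  if (!drop_unclassified) out <- c(out, unclassified = tab[1])
  out
}

#' @export
print.fq_class_map <- function(x, ...) {
  cc <- class_counts(x, drop_unclassified = FALSE)
  cat(sprintf("<fq_class_map> %dx%d at scale %s | %s\n",
              nrow(x$labels), ncol(x$labels), format(x$scale),
              paste(sprintf("%s: %d", names(cc), cc), collapse = ", ")))
  invisible(x)
}
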