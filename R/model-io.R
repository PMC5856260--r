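#' Save / load a trained tissue classifier
#'
#' The model is persisted as a single self-describing JSON file: a header
#' (class list, feature configuration, standardization constants, SVM
#' configuration, training provenance hash) plus the coefficient blocks
#' (random Fourier projection and per-class weight vectors) at full precision.
#'
#' @param clf an `fq_tissue_classifier`.
#' @param path file path (conventionally `.json`).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the classifier.
#' @export
save_classifier <- function(clf, path) {
  svm <- clf$svm
  obj <- list(
    format = "fibroquant_classifier",
    version = 1L,
    header = list(classes = clf$classes,
                  feature_config = list(structure_size = clf$cfg$structure_size,
                                        channels = clf$cfg$channels,
                                        stats = clf$cfg$stats),
                  standardization = list(center = svm$center, spread = svm$spread),
                  svm_config = unclass(clf$svm_config),
                  gamma = svm$gamma,
                  seed = clf$seed,
                  resub_accuracy = clf$resub_accuracy,
                  training_hash = clf$training_hash),
    coefficients = list(Omega = as.vector(svm$rff$Omega), Omega_dim = dim(svm$rff$Omega),
                        b = svm$rff$b, W = as.vector(svm$W), W_dim = dim(svm$W)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fibroquant_classifier"))
    fq_stop("fq_format_error", "%s is not a fibroquant classifier file", path)
  h <- obj$header
  cfg <- feature_config(h$feature_config$structure_size,
                        h$feature_config$channels, h$feature_config$stats)
  sc <- do.call(svm_config, h$svm_config[c("C", "n_rff", "class_weights",
                                           "max_epoch", "tol")])
  W <- matrix(obj$coefficients$W, obj$coefficients$W_dim[1], obj$coefficients$W_dim[2])
  colnames(W) <- h$classes
  svm <- structure(list(classes = h$classes,
                        center = h$standardization$center,
                        spread = h$standardization$spread,
                        gamma = h$gamma,
                        rff = list(Omega = matrix(obj$coefficients$Omega,
                                                  obj$coefficients$Omega_dim[1],
                                                  obj$coefficients$Omega_dim[2]),
                                   b = obj$coefficients$b),
                        W = W, config = sc, seed = h$seed),
                   class = "fq_svm_model")
  structure(list(svm = svm, classes = h$classes, cfg = cfg, svm_config = sc,
                 resub_accuracy = h$resub_accuracy, seed = h$seed,
                 training_hash = h$training_hash),
            class = "fq_tissue_classifier")
}
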