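# RBF-kernel SVM backend.
#
# No SVM solver ships with the supported package set, and the pixel classifier
# is the heart of this package, so the SVM is implemented here: the RBF kernel
# k(x,y) = exp(-gamma ||x-y||^2) is approximated by random Fourier features
# (Rahimi & Recht 2007), z(x) = sqrt(2/D) cos(Omega' x + b) with
# Omega ~ N(0, 2*gamma I), b ~ U(0, 2*pi); on top of z(x) a linear SVM is
# trained per class (one-vs-rest) by dual coordinate descent (Hsieh et al.
# 2008, implemented in C++). This keeps training on tens of thousands of
# pixels and prediction on megapixel images linear in n while retaining the
# non-linear decision boundary of the RBF machine.

#' SVM configuration
#'
#' @param C regularization (soft-margin cost).
#' @param gamma RBF kernel scale; `NULL` = `1 / n_features` at fit time.
#' @param n_rff number of random Fourier features approximating the RBF kernel.
#' @param class_weights if `TRUE`, per-class costs are scaled inversely to
#'   class frequency, so dominant classes (e.g. heavily annotated fibrotic
#'   masses) do not swamp rare ones.
#' @param max_epoch,tol coordinate-descent stopping controls.
#' @return object of class `fq_svm_config`.
#' @export
svm_config <- function(C = 1, gamma = NULL, n_rff = 256L, class_weights = TRUE,
                       max_epoch = 60L, tol = 1e-3) {
  if (!is.finite(C) || C <= 0) fq_stop("fq_param_error", "C must be positive")
  if (!is.null(gamma) && (!is.finite(gamma) || gamma <= 0))
    fq_stop("fq_param_error", "gamma must be positive or NULL")
  if (!is_count(n_rff, 8)) fq_stop("fq_param_error", "n_rff must be an integer >= 8")
  structure(list(C = C, gamma = gamma, n_rff = as.integer(n_rff),
                 class_weights = isTRUE(class_weights),
                 max_epoch = as.integer(max_epoch), tol = tol),
            class = "fq_svm_config")
}

# Fit the multiclass (one-vs-rest) approximate-RBF SVM.
# X: n x d raw feature matrix; y: factor. Returns the fitted backend model.
fq_svm_fit <- function(X, y, config, seed) {
  classes <- levels(y)
  n <- nrow(X); d <- ncol(X)
  gamma <- config$gamma %||% (1 / d)

  center <- colMeans(X)
  spread <- apply(X, 2, sd)
  spread[!is.finite(spread) | spread < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, spread, "/")

  D <- config$n_rff
  rff <- with_seed(derive_seed(seed, 1L), {
    list(Omega = matrix(rnorm(d * D, 0, sqrt(2 * gamma)), d, D),
         b = runif(D, 0, 2 * pi))
  })
  Z <- rff_transform(Xs, rff, D)

  counts <- table(y)
  wclass <- if (config$class_weights) as.numeric(n / (length(classes) * counts[classes]))
            else rep(1, length(classes))
  names(wclass) <- classes

  W <- matrix(0, D + 1, length(classes), dimnames = list(NULL, classes))
  for (k in seq_along(classes)) {
    yk <- ifelse(y == classes[k], 1, -1)
    # positive class gets its inverse-frequency cost, the rest pool keeps base C
    Ci <- ifelse(yk > 0, config$C * wclass[k], config$C)
    W[, k] <- cpp_svm_dcd(Z, yk, Ci, config$max_epoch, config$tol,
                          derive_seed(seed, 100L + k))
  }
  structure(list(classes = classes, center = center, spread = spread,
                 gamma = gamma, rff = rff, W = W, config = config, seed = seed),
            class = "fq_svm_model")
}

# Random Fourier feature map plus bias column.
rff_transform <- function(Xs, rff, D) {
  M <- Xs %*% rff$Omega
  M <- sweep(M, 2, rff$b, "+")
  cbind(sqrt(2 / D) * cos(M), 1)
}

# Decision scores (n x K), computed in row chunks to bound memory on
# megapixel inputs.
fq_svm_scores <- function(model, X, chunk = 100000L) {
  n <- nrow(X); D <- ncol(model$rff$Omega)
  out <- matrix(NA_real_, n, length(model$classes),
                dimnames = list(NULL, model$classes))
  for (start in seq(1, max(n, 1), by = chunk)) {
    if (n == 0) break
    i <- start:min(n, start + chunk - 1)
    Xs <- sweep(sweep(X[i, , drop = FALSE], 2, model$center), 2, model$spread, "/")
    out[i, ] <- rff_transform(Xs, model$rff, D) %*% model$W
  }
  out
}

# Winner-take-all over one-vs-rest margins; ties break to the lowest class
# index (deterministic).
fq_svm_predict <- function(model, X) {
  if (nrow(X) == 0) return(integer(0))
  max.col(fq_svm_scores(model, X), ties.method = "first")
}
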