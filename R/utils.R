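# Internal helpers: classed conditions, seeded evaluation, misc.

fq_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "fq_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

fq_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying within
# the 32-bit signed integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 2654435761 + stream * 97003) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x, min = 0) {
  length(x) == 1 && is.finite(x) && x >= min && x == as.integer(x)
}

is_fraction <- function(x) length(x) == 1 && is.finite(x) && x >= 0 && x <= 1

# Row-major (y outer, x inner) indices of TRUE pixels of a mask.
# Returns a 2-column matrix (row, col), 1-based.
mask_pixels_rowmajor <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(idx)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# FNV-1a fingerprint of an arbitrary R object (used for model hashes in logs).
fq_hash <- function(obj) {
  cpp_fnv1a(serialize(obj, NULL, version = 2))
}
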