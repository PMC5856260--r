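#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test with midranks for ties. The exact null distribution is used
#' when `min(n, m) <= 8` and there are no ties; otherwise the normal
#' approximation with tie correction. U is reported for the first sample
#' (`U + U' = n * m`).
#'
#' @param a,b numeric vectors (each non-empty).
#' @return list with `U`, `p_value`, `n`, `m`, `method`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n <- length(a); m <- length(b)
  if (n < 1 || m < 1) fq_stop("fq_param_error", "both groups must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  if (min(n, m) <= 8 && !has_ties) {
    # exact: P(U <= u) from the Wilcoxon rank-sum distribution
    lower <- stats::pwilcox(min(U, n * m - U), n, m)
    p <- min(1, 2 * lower)
    method <- "exact"
  } else {
    mu <- n * m / 2
    N <- n + m
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n * m / 12 * (N + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sigma  # continuity correction
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = p, n = n, m = m, method = method)
}

#' Pairwise group comparisons of study readouts
#'
#' For each readout and each pair of groups (within each timepoint, if
#' present), reports group sizes, means, SEMs and the two-sided Mann-Whitney
#' p-value. QC-excluded slides are dropped first. An unpaired Welch t-test
#' can be requested instead; no multiple-testing correction is applied by
#' default (`p_adjust = "holm"` enables one).
#'
#' @param table a study table (data.frame) with columns `group`, the readout
#'   columns, optionally `timepoint` and `qc_excluded`.
#' @param readouts readout column names (defaults to the three standard ones,
#'   intersected with what is present).
#' @param test `"mann_whitney"` (default) or `"t_test"`.
#' @param p_adjust `"none"` (default) or a method of [stats::p.adjust()].
#' @return data.frame, one row per (timepoint, readout, group pair).
#' @export
compare_groups <- function(table, readouts = NULL,
                           test = c("mann_whitney", "t_test"),
                           p_adjust = "none") {
  test <- match.arg(test)
  readouts <- readouts %||% intersect(
    c("fibrotic_mass_percent", "alveolar_collagen_percent",
      "total_collagen_percent"), names(table))
  if (length(readouts) == 0) fq_stop("fq_param_error", "no readout columns found")
  if (!"group" %in% names(table)) fq_stop("fq_param_error", "table needs a 'group' column")
  if ("qc_excluded" %in% names(table)) table <- table[!table$qc_excluded, , drop = FALSE]
  tps <- if ("timepoint" %in% names(table)) unique(table$timepoint) else NA
  rows <- list()
  for (tp in tps) {
    sub <- if (is.na(tp[1])) table else table[table$timepoint == tp, , drop = FALSE]
    groups <- unique(sub$group)
    if (length(groups) < 2)
      fq_stop("fq_param_error", "need >= 2 groups after QC exclusion")
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (ro in readouts) for (pr in pairs) {
      va <- sub[sub$group == pr[1], ro]; vb <- sub[sub$group == pr[2], ro]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      res <- if (test == "mann_whitney") {
        mw <- mann_whitney(va, vb)
        list(U = mw$U, p = mw$p_value)
      } else {
        tt <- stats::t.test(va, vb)
        list(U = NA_real_, p = tt$p.value)
      }
      rows[[length(rows) + 1]] <- data.frame(
        timepoint = tp, readout = ro, group_a = pr[1], group_b = pr[2],
        n_a = length(va), n_b = length(vb),
        mean_a = mean(va), mean_b = mean(vb),
        sem_a = sd(va) / sqrt(length(va)), sem_b = sd(vb) / sqrt(length(vb)),
        U = res$U, p_value = res$p, test = test,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_adjusted <- stats::p.adjust(out$p_value, p_adjust)
  out
}
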