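#' Wilcoxon rank-sum test with U statistic and Cliff's delta
#'
#' Two-sample rank-sum comparison as used for the device contrasts. The
#' U statistic is computed from midranks (half-integer under cross-group
#' ties), the p-value is two-sided: exact when both samples are small and
#' tie-free (`exact = NULL` chooses exact for `m + n <= 12`), otherwise a
#' normal approximation with tie correction and no continuity correction.
#' Cliff's delta is attached as the effect size.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`)/suppress (`FALSE`) the exact p-value;
#'   `NULL` decides by sample size and ties.
#' @return Object of class `"rank_sum_test"`: `U` (for `x`), `p_value`,
#'   `delta`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample", call. = FALSE)
  n_x <- length(x); n_y <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- (n_x + n_y <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  structure(list(U = U, p_value = wt$p.value, delta = cliffs_delta(x, y),
                 method = if (exact && !ties) "exact rank-sum"
                          else "normal approximation, tie-corrected"),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("rank-sum test: U = %g, p = %.4g, Cliff's delta = %.3g (%s)\n",
              x$U, x$p_value, x$delta, x$method))
  invisible(x)
}

#' Cliff's delta effect size
#'
#' Normalized difference between pairwise win and loss counts:
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| |y|)`, in `[-1, 1]`.
#' `delta = 1` when every `x` exceeds every `y`.
#'
#' @param x,y Numeric samples.
#' @return Cliff's delta.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample", call. = FALSE)
  mean(sign(outer(x, y, "-")))
}

#' Fisher's exact test for r x c contingency tables
#'
#' Two-sided exact test under fixed margins, summing the probabilities of
#' all tables no more probable than the observed one (the classical
#' definition, with a small relative tolerance against floating-point tie
#' misclassification). A table with a zero row or column margin carries no
#' information and returns p = 1.
#'
#' @param counts Integer matrix of non-negative counts (e.g. migration
#'   category x device).
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  counts <- counts[keep_r, keep_c, drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L) return(1)
  stats::fisher.test(counts, workspace = 2e6)$p.value
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact interval for a binomial proportion,
#' as used for the per-category migration shares. The lower bound is 0
#' when `x = 0` and the upper bound 1 when `x = n`.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(lo, hi)`.
#' @export
binomial_ci <- function(x, n, level = 0.95) {
  if (n < 1L || x < 0L || x > n) stop("need 0 <= x <= n, n >= 1", call. = FALSE)
  a <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lo = lo, hi = hi)
}

#' z-based half-width of a mean confidence interval
#'
#' `z_{1-(1-level)/2} * sd / sqrt(n)`: the normal-quantile convention used
#' in the summary tables.
#'
#' @param sd Sample standard deviation.
#' @param n Sample size.
#' @param level Confidence level (default 0.95).
#' @return The half-width.
#' @export
mean_ci_halfwidth <- function(sd, n, level = 0.95) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  stats::qnorm(1 - (1 - level) / 2) * sd / sqrt(n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving in the input.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]",
                                             call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Covariate (ANCOVA-style) regression per device group
#'
#' Ordinary least-squares fit of a retrieval metric on clot length within
#' each device group, with the two-sided t-test on the length slope. Used
#' to check that deformation and contour change are independent of clot
#' size (and hence of device size).
#'
#' @param y Metric values (e.g. D or CC).
#' @param length_mm Clot lengths in mm.
#' @param group Device labels, same length as `y`.
#' @return Data frame with one row per group: `group`, `n`, `slope`,
#'   `p_value`.
#' @export
covariate_regression <- function(y, length_mm, group) {
  if (length(y) != length(length_mm) || length(y) != length(group)) {
    stop("y, length_mm and group must have equal length", call. = FALSE)
  }
  out <- lapply(split(seq_along(y), group), function(idx) {
    if (length(idx) < 3L) stop("need >= 3 observations per group", call. = FALSE)
    xg <- length_mm[idx]
    if (stats::sd(xg) == 0) stop("degenerate design: constant clot length",
                                 call. = FALSE)
    fit <- stats::lm(y[idx] ~ xg)
    cf <- summary(fit)$coefficients
    data.frame(group = as.character(group[idx[1L]]), n = length(idx),
               slope = cf["xg", "Estimate"], p_value = cf["xg", "Pr(>|t|)"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Migration contingency table
#'
#' Cross-tabulates migration categories against device labels in the fixed
#' category order, for [fisher_exact()] and per-cell [binomial_ci()]s.
#'
#' @param category Character vector of migration categories.
#' @param device Device labels, same length.
#' @return Integer matrix, rows = categories (minimal..extensive),
#'   columns = devices.
#' @export
migration_contingency <- function(category, device) {
  category <- factor(category, levels = MIGRATION_LEVELS)
  if (anyNA(category)) stop("unknown migration category", call. = FALSE)
  as.matrix(table(category, device))
}
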