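#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test of the null that two samples come from the
#' same distribution. Two modes are provided: `"exact"` enumerates the full
#' permutation distribution of the rank-sum of `x` (feasible for
#' `length(x) + length(y) <= 12`, ties handled naturally through midranks),
#' and `"normal"` uses the tie-corrected normal approximation with a
#' continuity correction — the workhorse for the per-gene tests where group
#' sizes are in the hundreds.
#'
#' The exact two-sided p-value is defined symmetrically around the null
#' expectation: `P(|W - E[W]| >= |w - E[W]|)` over all equally likely
#' assignments of the pooled midranks to the first group.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param mode `"exact"` or `"normal"`.
#' @return A list with `statistic` (the rank-sum of `x`) and `p`
#'   (two-sided, in (0, 1]).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  assert_that(length(x) >= 1 && length(y) >= 1,
              "wilcoxon_rank_sum: both samples must be non-empty")
  assert_that(is.numeric(x) && is.numeric(y) && !anyNA(x) && !anyNA(y),
              "wilcoxon_rank_sum: samples must be numeric without NA")
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2

  if (mode == "exact") {
    if (n > 12) {
      stop("exact mode is limited to a pooled sample size of 12", call. = FALSE)
    }
    sums <- colSums(utils::combn(r, nx))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    return(list(statistic = w, p = p))
  }

  # tie-corrected variance of the rank-sum
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = w, p = 1))  # all observations tied
  }
  dev <- abs(w - mu)
  z <- max(0, dev - 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-z))
  list(statistic = w, p = max(p, .Machine$double.xmin))
}

# Vectorized tie-corrected normal-mode Wilcoxon across the columns of a
# cells-x-genes matrix; `grp` is a logical vector marking group 1 rows.
# Returns a data.frame with statistic and two-sided p per column. Shared by
# the single-cell and bulk differential tests.
wilcoxon_matrix <- function(mat, grp) {
  stopifnot(is.logical(grp), length(grp) == nrow(mat))
  nx <- sum(grp)
  ny <- sum(!grp)
  assert_that(nx >= 1 && ny >= 1, "both groups must be non-empty")
  n <- nx + ny
  mu <- nx * (n + 1) / 2
  base_var <- nx * ny / 12
  out <- apply(mat, 2, function(v) {
    r <- rank(v)
    w <- sum(r[grp])
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- base_var * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(c(w, 1))
    z <- max(0, abs(w - mu) - 0.5) / sqrt(sigma2)
    c(w, min(1, 2 * stats::pnorm(-z)))
  })
  data.frame(statistic = out[1, ], p = pmax(out[2, ], .Machine$double.xmin),
             row.names = colnames(mat))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (same length and order).
#' @export
bh_adjust <- function(pvals) {
  assert_that(is.numeric(pvals), "bh_adjust: pvals must be numeric")
  assert_that(!anyNA(pvals) && all(pvals >= 0 & pvals <= 1),
              "bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Combine p-values by Fisher's method
#'
#' The "sumlog" combination: `X2 = -2 * sum(log(p))` referred to a
#' chi-square distribution with `2k` degrees of freedom, where `k` is the
#' number of p-values. Exact zeros are clamped to 1e-300 (with a warning)
#' since `log(0)` is undefined.
#'
#' @param pvals Numeric vector of p-values in (0, 1]; length >= 1.
#' @return Combined p-value.
#' @examples
#' fisher_combine(0.05)        # k = 1 returns the input
#' fisher_combine(c(0.5, 0.5)) # ~0.59657
#' @export
fisher_combine <- function(pvals) {
  assert_that(length(pvals) >= 1, "fisher_combine: empty p-value list")
  assert_that(is.numeric(pvals) && !anyNA(pvals) && all(pvals >= 0 & pvals <= 1),
              "fisher_combine: p-values must lie in [0, 1]")
  if (any(pvals == 0)) {
    warning("zero p-values clamped to 1e-300 before Fisher combination")
    pvals <- pmax(pvals, 1e-300)
  }
  x2 <- -2 * sum(log(pvals))
  stats::pchisq(x2, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Log2 fold change of two group means
#'
#' `log2(mean_exh + eps) - log2(mean_other + eps)`; the epsilon guards
#' zero means.
#'
#' @param mean_exh,mean_other Non-negative group means.
#' @param eps Positive pseudocount, default `1e-9`.
#' @return Signed log2 fold change (exhausted minus other).
#' @export
log2_fold_change <- function(mean_exh, mean_other, eps = 1e-9) {
  assert_that(all(mean_exh >= 0) && all(mean_other >= 0),
              "log2_fold_change: means must be non-negative")
  assert_that(is_scalar_number(eps) && eps > 0,
              "log2_fold_change: eps must be a positive scalar")
  log2(mean_exh + eps) - log2(mean_other + eps)
}
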