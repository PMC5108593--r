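#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Two-sided rank-sum test (exact when sample sizes permit and there are
#' no ties, normal approximation otherwise) for each requested pair of
#' groups; raw p values are multiplied by the family size (number of
#' comparisons) and capped at 1. Stars follow the 0.05/0.01/0.001
#' convention.
#'
#' @param groups named list of numeric samples.
#' @param comparisons list of length-2 character vectors naming the
#'   pairs to compare; defaults to all pairs.
#' @return data.frame with `group1`, `group2`, `statistic`, `p_raw`,
#'   `p_adjusted`, `stars`.
#' @export
ranksum_bonferroni <- function(groups, comparisons = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (any(vapply(groups, length, 0L) < 1)) stop("empty sample")
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- utils::combn(nm, 2, simplify = FALSE)
  }
  m <- length(comparisons)
  rows <- lapply(comparisons, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    p_adj <- min(1, m * wt$p.value)
    data.frame(group1 = pr[1], group2 = pr[2],
               statistic = unname(wt$statistic),
               p_raw = wt$p.value, p_adjusted = p_adj,
               stars = p_stars(p_adj))
  })
  do.call(rbind, rows)
}

p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Fisher's exact test with modified-Wald proportion intervals
#'
#' Two-sided Fisher exact p for a 2x2 table, reported together with a
#' modified-Wald (Agresti-Coull add-2) confidence interval for each
#' row's proportion. The exact test and the interval method are distinct
#' procedures reported side by side.
#'
#' @param counts 2x2 matrix of nonnegative integers; rows are groups,
#'   columns are outcome yes/no.
#' @param conf_level confidence level for the proportion intervals.
#' @return list with `p`, and `proportions` (data.frame with `estimate`,
#'   `lower`, `upper` per row).
#' @export
fisher_modified_wald <- function(counts, conf_level = 0.95) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0),
            all(counts == round(counts)))
  if (sum(counts) == 0) stop("all-zero table")
  p <- stats::fisher.test(counts)$p.value
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  props <- t(apply(counts, 1, function(r) {
    x <- r[1]; n <- sum(r)
    pt <- (x + 2) / (n + 4)
    half <- z * sqrt(pt * (1 - pt) / (n + 4))
    c(estimate = if (n > 0) x / n else NA_real_,
      lower = max(0, pt - half), upper = min(1, pt + half))
  }))
  list(p = p, proportions = as.data.frame(props))
}

#' Bootstrap confidence interval for a difference of group medians
#'
#' Resamples each group with replacement, takes the difference of
#' medians (`a` minus `b`) per replicate, and reports the 5% and 95%
#' percentile bounds. Two such intervals not overlapping is the
#' significance criterion used for median-difference bar plots.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed (results are reproducible given
#'   `n_boot` and `seed`).
#' @param probs percentile bounds.
#' @return list with `estimate` (difference of observed medians),
#'   `lower`, `upper`, `n_boot`, `seed`.
#' @export
bootstrap_median_diff <- function(a, b, n_boot = 10000, seed = 20160422,
                                  probs = c(0.05, 0.95)) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  na <- length(a); nb <- length(b)
  ra <- matrix(sample.int(na, na * n_boot, replace = TRUE), nrow = n_boot)
  rb <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = n_boot)
  diffs <- apply(ra, 1, function(i) stats::median(a[i])) -
           apply(rb, 1, function(i) stats::median(b[i]))
  q <- unname(stats::quantile(diffs, probs, type = 7))
  list(estimate = stats::median(a) - stats::median(b),
       lower = q[1], upper = q[2], n_boot = n_boot, seed = seed)
}

#' Do two bootstrap intervals overlap?
#'
#' @param ci1,ci2 results of [bootstrap_median_diff()].
#' @return `TRUE` when the intervals overlap (not significant under the
#'   non-overlap criterion).
#' @export
ci_overlap <- function(ci1, ci2) {
  ci1$lower <= ci2$upper && ci2$lower <= ci1$upper
}
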