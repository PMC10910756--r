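#' @useDynLib spatialtma, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef complete.cases kmeans median p.adjust pchisq prcomp
#'   predict quantile rbinom rexp rlnorm rnorm runif sd t.test setNames glm
#'   binomial as.formula
#' @importFrom utils head packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two labellings
#'
#' Pair-counting agreement between two partitions of the same cells, corrected
#' for chance. 1 means identical partitions (up to relabelling), 0 is the
#' expectation for independent labellings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# z-score a vector; all-constant input maps to 0 rather than NaN
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Welch t-test that honours the degenerate contracts used throughout:
# both groups constant and equal -> p = 1 (flagged); constant but different
# -> p = 0 (flagged).
welch_test <- function(x, y) {
  vx <- if (length(x) > 1) sd(x) else 0
  vy <- if (length(y) > 1) sd(y) else 0
  if ((is.na(vx) || vx == 0) && (is.na(vy) || vy == 0)) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = 0, p = if (same) 1 else 0, flag = "zero_variance"))
  }
  ht <- t.test(x, y)
  list(t = unname(ht$statistic), p = ht$p.value, flag = NA_character_)
}

# rank-based AUC of `score` for predicting `label` (logical/0-1),
# identical to the Mann-Whitney U statistic scaled to [0, 1]
rank_auc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
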