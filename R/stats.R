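#' Fold difference between early and senescent means
#'
#' The per-donor effect size used throughout the benchmarking layer: the
#' ratio of the senescent-passage mean to the early-passage mean of a metric.
#' Ratios below 1 (a reversed effect) are legal and reported as such.
#'
#' @param e_mean early-passage mean, must be > 0.
#' @param s_mean senescent-passage mean.
#' @return `s_mean / e_mean`.
#' @export
fold_difference <- function(e_mean, s_mean) {
  if (any(e_mean <= 0)) stop("early-passage mean must be positive")
  s_mean / e_mean
}

#' @rdname fold_difference
#' @param ratios per-donor fold differences.
#' @return `fold_range()`: named numeric `c(min, max)` over donors.
#' @export
fold_range <- function(ratios) {
  if (!length(ratios)) stop("no fold differences supplied")
  c(min = min(ratios), max = max(ratios))
}

#' One-tailed unequal-variance (Welch) t-test
#'
#' Tests whether the senescent group mean exceeds the early group mean
#' without assuming equal variances:
#' \deqn{t = \frac{\bar{x}_S - \bar{x}_E}{\sqrt{s_S^2/n_S + s_E^2/n_E}}}
#' with Welch-Satterthwaite degrees of freedom and an upper-tail p-value.
#' The direction (S greater) is fixed a priori for every metric, so a
#' reversed observed effect yields p > 0.5 and "ns". Significance stars
#' follow the usual mapping: `***` p <= 0.001, `**` p <= 0.01, `*` p <= 0.05,
#' `ns` otherwise.
#'
#' @param e_values,s_values raw per-cell/event values for the early and
#'   senescent group, each of length >= 2.
#' @return A list with `t`, `df`, `p` (one-tailed) and `stars`.
#' @examples
#' welch_one_tailed(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_one_tailed <- function(e_values, s_values) {
  nE <- length(e_values); nS <- length(s_values)
  if (nE < 2L || nS < 2L)
    stop("each group needs at least 2 observations")
  vE <- stats::var(e_values); vS <- stats::var(s_values)
  se2 <- vS / nS + vE / nE
  dmean <- mean(s_values) - mean(e_values)
  if (se2 == 0) {
    # degenerate: both groups constant
    t <- if (dmean == 0) 0 else sign(dmean) * Inf
    df <- nE + nS - 2
  } else {
    t <- dmean / sqrt(se2)
    df <- se2^2 / ((vS / nS)^2 / (nS - 1) + (vE / nE)^2 / (nE - 1))
  }
  p <- stats::pt(t, df, lower.tail = FALSE)
  list(t = t, df = df, p = p, stars = p_stars(p))
}

#' @rdname welch_one_tailed
#' @param p p-value(s).
#' @return `p_stars()`: the star label(s).
#' @export
p_stars <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "ns")))
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Spearman's correlation — the Pearson correlation of mid-ranks (ties
#' averaged) — measures the strength of a monotonic association and is the
#' benchmarking statistic used to compare each candidate senescence metric
#' against the beta-galactosidase standard. For n <= `exact_max` the
#' two-sided p-value is computed exactly by enumerating all n! rank
#' permutations (the t approximation is poor there); otherwise the usual
#' t approximation with n - 2 degrees of freedom is used.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @param exact_max largest n for which the permutation p is enumerated
#'   exactly (default 9).
#' @return A list with `r`, `p`, `n` and `method` (`"exact"` or
#'   `"t-approximation"`). When either input is constant, `r` and `p` are
#'   `NA` and a warning flags the degenerate input.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_cor <- function(x, y, exact_max = 9L) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  r <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    X <- matrix(rx[perms], nrow(perms))   # rx under every permutation
    rxc <- sweep(X, 1L, rowMeans(X))      # rowMeans are all mean(rx)
    ryc <- ry - mean(ry)
    rs <- as.numeric(rxc %*% ryc) /
      (sqrt(rowSums(rxc^2)) * sqrt(sum(ryc^2)))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
    method <- "exact"
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t-approximation"
  }
  list(r = r, p = p, n = n, method = method)
}

# all permutations of 1..n as an (n! x n) integer matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  rows <- nrow(sub)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[(i - 1L) * rows + seq_len(rows), ] <-
      cbind(i, matrix(rest[sub], rows))
  }
  out
}
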