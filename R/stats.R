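#' Exact Mann-Whitney U test with mid-rank ties
#'
#' U statistic from mid-ranks with a two-tailed p-value obtained from the
#' exact permutation distribution of the rank sum (all `choose(n1+n2, n1)`
#' group labelings, counted by dynamic programming over the — possibly
#' tied — rank multiset). The two-tailed p doubles the smaller tail
#' probability, capped at 1. Beyond `exact_max_n` combined observations the
#' normal approximation with tie correction and continuity correction is
#' used instead (reported in the result).
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_max_n Largest combined sample size for which the exact
#'   distribution is enumerated (default 25).
#' @return Object of class `mannwhitney_test` (and tibble-compatible via
#'   [tidy()]): list with `u` (U of `x`), `u_other`, `p_value`, `method`,
#'   `n1`, `n2`.
#' @examples
#' mannwhitney_exact(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
mannwhitney_exact <- function(x, y, exact_max_n = 25L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be non-empty")
  assert_finite(c(x, y), "sample")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))                      # mid-ranks
  r1 <- sum(r[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  u_other <- n1 * n2 - u
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))        # half-integer ranks -> integers
    s_obs <- as.integer(round(2 * r1))
    dist <- subset_sum_counts(r2, n1)     # counts over 2*ranksum
    total <- choose(n, n1)
    p_le <- sum(dist[seq_len(s_obs + 1L)]) / total
    p_ge <- sum(dist[(s_obs + 1L):length(dist)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(u = u, u_other = u_other, p_value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "mannwhitney_test")
}

# Number of size-k subsets of the integer multiset `vals` having each
# possible sum; returns counts indexed by sum 0..sum(vals) (1-based offset).
subset_sum_counts <- function(vals, k) {
  total <- sum(vals)
  dp <- matrix(0, k + 1L, total + 1L)
  dp[1L, 1L] <- 1
  for (v in vals) {
    jmax <- k
    for (j in jmax:1L) {
      nz <- which(dp[j, ] > 0)
      if (length(nz)) dp[j + 1L, nz + v] <- dp[j + 1L, nz + v] + dp[j, nz]
    }
  }
  dp[k + 1L, ]
}

#' @export
print.mannwhitney_test <- function(x, ...) {
  cat(sprintf("<mannwhitney_test> U = %g (U' = %g), p = %.4g [%s], n = %d/%d\n",
              x$u, x$u_other, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' @rdname mannwhitney_exact
#' @param x A `mannwhitney_test` object (for `tidy`).
#' @param ... Unused.
#' @export
tidy.mannwhitney_test <- function(x, ...) {
  tibble::tibble(statistic = x$u, p.value = x$p_value, method = x$method,
                 n1 = x$n1, n2 = x$n2)
}

#' Holm-Bonferroni step-down multiple-comparison thresholds
#'
#' Sorts the p-values ascending; the threshold at sorted position `i`
#' (1-based) is `alpha / (m - i + 1)`. Rejection is step-down: stop at the
#' first sorted p-value exceeding its threshold. Tied p-values share the
#' (most stringent) threshold of the first position of their tie block.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level (default 0.05).
#' @return Tibble in the original order: `p`, `rank`, `threshold`,
#'   `reject`.
#' @examples
#' holm_bonferroni(c(0.001, 0.02, 0.04))
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1), alpha > 0, alpha < 1)
  m <- length(pvals)
  ord <- order(pvals)
  thr_sorted <- alpha / (m - seq_len(m) + 1)
  p_sorted <- pvals[ord]
  # ties share the first (smallest) threshold of their tie block
  first_pos <- match(p_sorted, p_sorted)
  thr_shared <- thr_sorted[first_pos]
  rej_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p_sorted[i] <= thr_shared[i] && (i == 1L || rej_sorted[i - 1L])) {
      rej_sorted[i] <- TRUE
    } else break
  }
  out <- tibble::tibble(p = pvals, rank = NA_integer_,
                        threshold = NA_real_, reject = NA)
  out$rank[ord] <- seq_len(m)
  out$threshold[ord] <- thr_shared
  out$reject[ord] <- rej_sorted
  out
}

#' log(MAR) visual-acuity loss score
#'
#' The magnification requirement (MAR) is the inverse of the decimal visual
#' acuity (viewing distance over letter size); its base-10 logarithm is the
#' acuity-loss score: 0 means reference-standard vision and each +0.1 is one
#' line of loss.
#'
#' @param acuity_decimal Decimal acuity score(s), > 0.
#' @return log(MAR) value(s).
#' @examples
#' logmar(1)    # 0
#' logmar(0.5)  # 0.301
#' @export
logmar <- function(acuity_decimal) {
  if (any(acuity_decimal <= 0)) abort("acuity must be positive")
  log10(1 / acuity_decimal)
}
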