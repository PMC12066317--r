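#' Two-sided one-sample Wilcoxon signed-rank test
#'
#' The workhorse behind both the voxel-wise sweet-spot test and the
#' paired clinical tests. Conventions: zero differences are dropped
#' before ranking; absolute values are ranked with midranks for ties.
#' For n <= `exact_n_max` the exact sign-flip null distribution of the
#' rank sum W is used, built by direct convolution over the doubled
#' midranks (an exact integer-count construction that also covers tied
#' data). For larger n a normal approximation with
#' tie-corrected variance and continuity correction is used. The
#' sign-flip distribution of W is symmetric about its mean even under
#' ties, so the two-sided p equals `2 * min(P(W <= w), P(W >= w))`,
#' capped at 1.
#'
#' @param x Numeric vector of differences.
#' @param exact_n_max Largest n (after dropping zeros) for which the
#'   exact null distribution is used.
#' @return List with `n` (non-zero differences used), `statistic` (W,
#'   the positive-rank sum), `z` (tie-corrected normal deviate),
#'   `p_value`, `exact` (logical), and `all_zero` flag. All differences
#'   zero (or empty input) gives `p_value = 1` by convention.
#' @export
signed_rank_test <- function(x, exact_n_max = 25L) {
  x <- x[!is.na(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L)
    return(list(n = 0L, statistic = 0, z = 0, p_value = 1,
                exact = TRUE, all_zero = TRUE))
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- tabulate(as.integer(round(2 * r)))  # counts per distinct midrank
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- if (sigma2 > 0) {
    (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
  } else 0
  if (n <= exact_n_max) {
    # exact sign-flip distribution over doubled midranks (integer counts)
    r2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(r2)))   # counts[s+1] = #assignments with 2W = s
    for (ri in r2)
      counts <- counts + c(numeric(ri), counts[seq_len(length(counts) - ri)])
    tot <- 2^n
    w2 <- as.integer(round(2 * w))
    p_lo <- sum(counts[seq_len(w2 + 1)]) / tot
    p_hi <- sum(counts[(w2 + 1):length(counts)]) / tot
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(n = n, statistic = w, z = z, p_value = p,
                exact = TRUE, all_zero = FALSE))
  }
  p <- if (sigma2 > 0) min(1, 2 * stats::pnorm(-abs(z))) else 1
  list(n = n, statistic = w, z = z, p_value = p, exact = FALSE,
       all_zero = FALSE)
}

#' Spearman rank correlation with rho, p
#'
#' rho is Pearson correlation of the ranks (midranks for ties). P-values:
#' exact distribution for n <= 10 with untied data (via
#' [stats::cor.test]'s exact method), t approximation with
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Numeric vectors (pairs with NA in either are dropped).
#' @return List with `n`, `rho`, `p_value`, and `flag` ("ok",
#'   "zero_variance" or "too_few").
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    return(list(n = n, rho = NA_real_, p_value = NA_real_, flag = "too_few"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(n = n, rho = NA_real_, p_value = NA_real_,
                flag = "zero_variance"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- any(duplicated(x)) || any(duplicated(y))
  if (n <= 10 && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(n = n, rho = rho, p_value = p, flag = "ok")
}
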