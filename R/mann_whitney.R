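#' Two-sided Mann-Whitney U test
#'
#' Rank-sum U with midranks for ties. When both groups have fewer than
#' `exact_max` observations and the pooled data are tie-free, the
#' two-sided p-value comes from the exact null distribution of U;
#' otherwise a tie-corrected normal approximation with continuity
#' correction is used (the convention of R's `wilcox.test`).
#'
#' @param x,y Non-empty numeric vectors (the two groups).
#' @param exact_max Use the exact distribution when `max(n1, n2)` is
#'   below this and there are no ties.
#' @return List with `u` (U statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y, exact_max = 50) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)

  if (!has_ties && n1 < exact_max && n2 < exact_max) {
    p <- if (u > n1 * n2 / 2) {
      stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      stats::pwilcox(u, n1, n2)
    }
    p <- min(2 * p, 1)
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties)
    n <- n1 + n2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      # continuity correction toward the null, as in wilcox.test
      z <- sign(z) * max(0, abs(z) - 0.5)
      p <- min(2 * stats::pnorm(-abs(z) / sqrt(sigma2)), 1)
    }
  }
  list(u = unname(u), p = unname(p))
}
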