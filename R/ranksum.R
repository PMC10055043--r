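#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is the Mann-Whitney U of the first group (rank sum of x
#' minus its minimum).  For tie-free data with both group sizes at most 20
#' the p-value is exact (two-sided, from the exact null distribution of U);
#' otherwise a normal approximation with midrank tie correction is used.
#'
#' @param x,y numeric vectors
#' @return list with \code{statistic} (U), \code{p.value}, \code{method}
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("empty group in rank_sum_test")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && nx <= 20 && ny <= 20) {
    # exact two-sided p: sum tail probabilities of the null U distribution
    p <- if (U > nx * ny / 2) {
      stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE) * 2
    } else {
      stats::pwilcox(U, nx, ny) * 2
    }
    return(list(statistic = U, p.value = min(1, p), method = "exact"))
  }
  mu <- nx * ny / 2
  n <- nx + ny
  sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(statistic = U, p.value = 1,
                             method = "normal"))
  z <- (U - mu) / sqrt(sig2)
  list(statistic = U, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}
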