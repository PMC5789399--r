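# Rank-based descriptive and two-sample statistics.

# all permutations of 1..n as an (n! x n) integer matrix
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    m <- matrix(0L, nrow(sub), n)
    m[, k] <- n
    m[, -k] <- sub
    out[[k]] <- m
  }
  do.call(rbind, out)
}

#' Spearman's rank-order correlation
#'
#' Pearson correlation of average-ranked data.  For n <= 9 the two-sided
#' p-value is exact, from full enumeration of the n! permutations of one
#' margin (conditional on the observed ranks, so ties are handled); for
#' larger n the usual t approximation on `rho * sqrt((n-2)/(1-rho^2))` is
#' used.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: `rho`, `p`, `n`, `method`.
#' @export
#' @examples
#' spearman_rho(1:6, c(2, 1, 4, 3, 6, 5))
spearman_rho <- function(x, y) {
  check_finite(x, "x"); check_finite(y, "y")
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 3) stopf("need n >= 3")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stopf("Spearman's rho is undefined for constant input")
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    ryp <- matrix(ry[perms], nrow(perms))
    rxc <- rx - mean(rx)
    rho_all <- as.vector(ryp %*% rxc) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), n - 2))
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two independent samples.  The statistic `W` is the Mann-Whitney U of the
#' first sample (sum of pooled ranks of `x` minus `n1 (n1 + 1) / 2`), the
#' convention reported by R's own `wilcox.test`.  For `n1 + n2 <= 12` the
#' two-sided p-value is exact, from enumeration of all `choose(n1 + n2, n1)`
#' group assignments of the pooled values (valid under ties as well); larger
#' samples use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples, each non-empty.
#' @return list: `W`, `p`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y) {
  check_finite(x, "x"); check_finite(y, "y")
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stopf("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= 12) {
    sel <- utils::combn(n1 + n2, n1)
    Uall <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(W = W, p = p, n1 = n1, n2 = n2, method = method)
}

#' Median and interquartile range
#'
#' Descriptives in the style used for non-normally distributed mechanical
#' leaf characteristics: median, IQR, minimum, maximum and n.  Quartiles use
#' linear interpolation between closest order statistics (R quantile type 7).
#'
#' @param values numeric vector, n >= 1.
#' @return data frame row: `median`, `iqr`, `min`, `max`, `n`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5))
median_iqr <- function(values) {
  if (!length(values)) stopf("empty input")
  check_finite(values, "values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(median = q[2], iqr = q[3] - q[1],
             min = min(values), max = max(values), n = length(values))
}
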