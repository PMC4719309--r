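# Two-sample Kolmogorov-Smirnov and exact binomial tests, written out in
# full because both are applied at exact small-sample settings (the KS p is
# the exact conditional null probability when sample sizes are small) and
# the binomial two-sided p uses the tail-doubling convention.

#' Two-sample two-tailed Kolmogorov-Smirnov test
#'
#' D is the supremum absolute difference between the two empirical CDFs.
#' For small samples (m*n <= `exact_limit`, no ties assumed) the p-value is
#' the exact conditional probability of D >= observed under random
#' assignment, computed by lattice path counting; otherwise the asymptotic
#' Kolmogorov distribution with effective n = mn/(m+n) is used.
#'
#' @param x,y numeric samples.
#' @param exact_limit switch to the asymptotic p above this m*n product.
#' @return list(`D`, `p`, `method`).
#' @export
ks_two_sample <- function(x, y, exact_limit = 10000) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m < 1 || n < 1) stop("both samples must be non-empty")
  w <- c(x, y)
  z <- cumsum(ifelse(order(w) <= m, 1 / m, -1 / n))
  # at tied values only the last cumulative step is an ECDF evaluation point
  ws <- sort(w)
  keep <- c(diff(ws) != 0, TRUE)
  D <- max(abs(z[keep]))
  if (m * n <= exact_limit) {
    p <- 1 - ks_exact_cdf(D, m, n)
    method <- "exact"
  } else {
    ne <- m * n / (m + n)
    t <- sqrt(ne) * D
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
    method <- "asymptotic"
  }
  list(D = D, p = min(max(p, 0), 1), method = method)
}

# P(D < d) under the exact conditional null (no ties): fraction of the
# choose(m+n, m) orderings whose ECDF difference stays strictly below d,
# via the standard normalized lattice recursion.
ks_exact_cdf <- function(d, m, n) {
  q <- matrix(0, m + 1, n + 1)
  for (i in 0:m) for (j in 0:n) {
    if (abs(i / m - j / n) >= d - 1e-12) { q[i + 1, j + 1] <- 0; next }
    if (i == 0 && j == 0) { q[1, 1] <- 1; next }
    acc <- 0
    if (i > 0) acc <- acc + i * q[i, j + 1]
    if (j > 0) acc <- acc + j * q[i + 1, j]
    q[i + 1, j + 1] <- acc / (i + j)
  }
  q[m + 1, n + 1]
}

#' Exact two-sided binomial test (tail-doubling convention)
#'
#' Two-sided p = min(1, 2 * min(P(X <= k), P(X >= k))) for X ~
#' Binomial(n, p0).
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability (default 0.5).
#' @return the two-sided p-value.
#' @export
binom_two_sided <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n)
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}
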