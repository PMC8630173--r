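#' Two-by-two contingency table
#'
#' Cell layout: rows are cohorts, columns feature present/absent —
#' `matrix(c(a, c, b, d), 2, 2)` with `a`,`b` the first cohort's
#' present/absent counts and `c`,`d` the second's.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A 2x2 integer matrix of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells)))
    abort("cells must be non-negative integers")
  if (sum(cells) == 0) abort("table total must be positive")
  structure(matrix(as.integer(c(a, c, b, d)), nrow = 2,
                   dimnames = list(cohort = c("A", "B"),
                                   feature = c("present", "absent"))),
            class = c("two_by_two", "matrix"))
}

as_two_by_two <- function(t) {
  if (inherits(t, "two_by_two")) return(t)
  if (is.matrix(t) && all(dim(t) == c(2, 2)))
    return(two_by_two(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
  abort("expected a 2x2 table")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by full hypergeometric enumeration with the
#' point-probability (minimum-likelihood) rule: conditioning on the margins,
#' the p-value is the total probability of all tables whose point probability
#' does not exceed that of the observed table (within a small relative
#' tolerance to absorb floating-point ties). The odds ratio is the sample
#' cross-product ratio `ad/bc`, reported as `Inf` when `bc = 0`.
#'
#' @param t A [two_by_two()] (or plain 2x2 matrix).
#' @return A tibble with `p_two_sided` and `odds_ratio`.
#' @examples
#' fisher_exact(two_by_two(2, 0, 0, 2))  # p = 1/3
#' @export
fisher_exact <- function(t) {
  t <- as_two_by_two(t)
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  if ((a + b) == 0 || (c + d) == 0)
    abort("degenerate margins: both row totals must be positive")
  m <- a + c; nn <- b + d; kk <- a + b
  lo <- max(0, kk - nn); hi <- min(kk, m)
  support <- lo:hi
  probs <- dhyper(support, m, nn, kk)
  p_obs <- dhyper(a, m, nn, kk)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  orat <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  tibble(p_two_sided = min(1, p), odds_ratio = orat)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed-form statistic `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the
#' Yates continuity correction optional, referred to the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param t A [two_by_two()] (or plain 2x2 matrix).
#' @param continuity_correction Apply the Yates correction.
#' @return A tibble with `statistic` and `p`.
#' @examples
#' chi_square(two_by_two(20, 10, 10, 20))  # statistic 20/3
#' @export
chi_square <- function(t, continuity_correction = FALSE) {
  t <- as_two_by_two(t)
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    abort("degenerate margins: all row and column totals must be positive")
  num <- abs(a * d - b * c)
  if (continuity_correction) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  tibble(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# U statistic with midrank ties: number of (x, y) pairs with x > y,
# counting ties as 1/2
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' U is computed with midranks for ties. For combined sample sizes up to
#' `exact_max` (default 12) the two-sided p-value is exact: all
#' `choose(n, n_x)` assignments of the pooled values to the two groups are
#' enumerated and the p-value is the proportion with `|U - n_x n_y / 2|` at
#' least as large as observed. Beyond that a Normal approximation with the
#' tie-corrected variance is used (no continuity correction).
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_max Largest combined size for exact enumeration.
#' @return A tibble with `U`, `p_two_sided` and `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0)
    abort("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  u <- u_statistic(x, y)
  mu <- nx * ny / 2
  if (n <= exact_max) {
    pooled <- c(x, y)
    sets <- utils::combn(n, nx)
    dev <- abs(u - mu)
    us <- apply(sets, 2, function(idx)
      u_statistic(pooled[idx], pooled[-idx]))
    p <- mean(abs(us - mu) >= dev - 1e-9)
    return(tibble(U = u, p_two_sided = p, method = "exact"))
  }
  r <- rank(c(x, y))
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(tibble(U = u, p_two_sided = 1, method = "normal"))
  z <- (u - mu) / sqrt(sigma2)
  tibble(U = u, p_two_sided = min(1, 2 * pnorm(-abs(z))), method = "normal")
}
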