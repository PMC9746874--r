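#' Pooled two-proportion z-test on detection rates
#'
#' Compares the fraction of cells in which a gene is detected (count > 0)
#' between two cell groups, using the classical pooled-proportion z
#' statistic. This is the first HEART component: under the null the gene is
#' "on" equally often in both groups.
#'
#' All arguments are vectorised over genes. When the pooled proportion is 0
#' or 1 the standard error degenerates; the statistic is then defined as 0
#' with p-value 1 (a gene detected in no cell, or in every cell, of both
#' groups carries no detection-rate evidence).
#'
#' @param m1,m2 Number of cells with positive counts in group 1 / group 2.
#' @param n1,n2 Total number of cells in group 1 / group 2.
#' @return A list with components `z` (the statistic) and `L1` (two-sided
#'   p-value, floored at `1e-300`).
#' @examples
#' proportion_test(8, 10, 2, 10)
#' @export
proportion_test <- function(m1, n1, m2, n2) {
  k <- max(length(m1), length(n1), length(m2), length(n2))
  m1 <- rep_len(as.numeric(m1), k); n1 <- rep_len(as.numeric(n1), k)
  m2 <- rep_len(as.numeric(m2), k); n2 <- rep_len(as.numeric(n2), k)
  if (any(n1 < 1) || any(n2 < 1))
    stop("group sizes must be >= 1")
  if (any(m1 < 0) || any(m2 < 0) || any(m1 > n1) || any(m2 > n2))
    stop("positive-cell counts must satisfy 0 <= m <= n")
  p1 <- m1 / n1
  p2 <- m2 / n2
  pstar <- (m1 + m2) / (n1 + n2)
  se2 <- pstar * (1 - pstar) * (1 / n1 + 1 / n2)
  z <- ifelse(se2 > 0, (p1 - p2) / sqrt(pmax(se2, .Machine$double.xmin)), 0)
  L1 <- ifelse(se2 > 0, 2 * pnorm(-abs(z)), 1)
  list(z = z, L1 = .clamp_p(L1))
}

#' Welch t-test on positive-part means
#'
#' The second HEART component: compares the mean expression of a gene's
#' "on" state (cells with positive counts only) between two groups with the
#' unequal-variance t statistic and Welch-Satterthwaite degrees of freedom.
#'
#' Zeros must be removed by the caller; this test deliberately sees only
#' the positive part, detection-rate differences being the first
#' component's job. If both sample variances are zero the statistic is 0
#' with p-value 1 when the means agree, and the p-value underflows to the
#' clamp floor when they differ (two distinct constants are trivially
#' different).
#'
#' @param x1,x2 Numeric vectors of positive counts (the "on" parts).
#' @return List with `t`, `df_t` (Welch-Satterthwaite df), `L2`
#'   (two-sided p-value) and `degenerate` (`TRUE` when both parts were
#'   constant and equal, i.e. the component carries no evidence).
#' @examples
#' location_test(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
#' @export
location_test <- function(x1, x2) {
  if (any(x1 <= 0) || any(x2 <= 0))
    stop("positive-part vectors must contain only positive values")
  m1 <- length(x1); m2 <- length(x2)
  if (m1 < 2 || m2 < 2)
    stop("each group needs at least 2 positive cells")
  v1 <- var(x1); v2 <- var(x2)
  d <- mean(x1) - mean(x2)
  se2 <- v1 / m1 + v2 / m2
  if (se2 == 0) {
    # both positive parts constant: no usable location evidence when the
    # constants agree, overwhelming evidence when they differ
    if (d == 0)
      return(list(t = 0, df_t = m1 + m2 - 2, L2 = 1, degenerate = TRUE))
    return(list(t = sign(d) * Inf, df_t = m1 + m2 - 2, L2 = .P_FLOOR,
                degenerate = FALSE))
  }
  tt <- d / sqrt(se2)
  df <- se2^2 / (v1^2 / (m1^2 * (m1 - 1)) + v2^2 / (m2^2 * (m2 - 1)))
  list(t = tt, df_t = df, L2 = .clamp_p(2 * pt(-abs(tt), df)),
       degenerate = FALSE)
}

#' Brown-Forsythe test on positive-part dispersion
#'
#' The third HEART component: a Levene-type test of equal scatter of the
#' "on" parts, built on absolute deviations from each group's median and
#' referred to an F(1, m1 + m2 - 2) distribution (upper tail). Median
#' centring makes the test robust to the skewness typical of count data.
#'
#' When the within-group deviations are all equal the denominator sum of
#' squares vanishes: the p-value is 1 if the between-group deviation means
#' also agree, and is clamped to the floor otherwise.
#'
#' @param x1,x2 Numeric vectors of positive counts.
#' @return List with `W` (the F-distributed statistic), `L3` (one-sided
#'   upper-tail p-value) and `degenerate` (`TRUE` when every absolute
#'   deviation was identical in and across groups).
#' @examples
#' scale_test(c(1, 2, 3, 4, 5), c(1, 1, 3, 5, 5))
#' @export
scale_test <- function(x1, x2) {
  if (any(x1 <= 0) || any(x2 <= 0))
    stop("positive-part vectors must contain only positive values")
  m1 <- length(x1); m2 <- length(x2)
  if (m1 < 2 || m2 < 2)
    stop("each group needs at least 2 positive cells")
  z1 <- abs(x1 - median(x1))
  z2 <- abs(x2 - median(x2))
  zb1 <- mean(z1); zb2 <- mean(z2)
  zb <- (sum(z1) + sum(z2)) / (m1 + m2)
  ss_between <- m1 * (zb1 - zb)^2 + m2 * (zb2 - zb)^2
  ss_within <- sum((z1 - zb1)^2) + sum((z2 - zb2)^2)
  df2 <- m1 + m2 - 2
  if (ss_within == 0) {
    if (ss_between == 0) return(list(W = 0, L3 = 1, degenerate = TRUE))
    return(list(W = Inf, L3 = .P_FLOOR, degenerate = FALSE))
  }
  W <- df2 * ss_between / ss_within
  list(W = W, L3 = .clamp_p(pf(W, 1, df2, lower.tail = FALSE)),
       degenerate = FALSE)
}
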