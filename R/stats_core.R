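## Shared exact and asymptotic statistics used across the pipeline stages.

#' Fisher's exact test on a 2x2 table
#'
#' The p-value is the sum of hypergeometric probabilities, with the table's
#' margins fixed, of all tables as or more extreme than the observed one.
#' Two-sided extremity uses the probability-mass rule (tables with
#' probability no greater than the observed, up to a small relative
#' tolerance), the convention of standard implementations. The odds ratio is
#' the sample odds ratio (a*d)/(b*c), reported as `Inf` when b*c = 0 with
#' a*d > 0 and `NA` when both products are zero.
#'
#' @param a,b,c,d non-negative integer cells: rows are the condition of
#'   interest, columns the outcome, so `a` counts condition-and-outcome.
#' @param sided `"two"` (default) or `"greater"` (upper tail on `a`).
#' @return list with elements `odds_ratio` and `p`.
#' @export
fisher_exact <- function(a, b, c, d, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell in contingency table")
  if (any(cells != round(cells))) stop("non-integer cell")
  if (sum(cells) == 0) stop("all margins zero")
  m <- a + b     # row 1 total
  n <- c + d     # row 2 total
  k <- a + c     # column 1 total
  ad <- a * d; bc <- b * c
  or <- if (bc > 0) ad / bc else if (ad > 0) Inf else NA_real_
  lo <- max(0, k - n)
  hi <- min(k, m)
  if (sided == "greater") {
    p <- phyper(a - 1, m, n, k, lower.tail = FALSE)
  } else {
    support <- lo:hi
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  list(odds_ratio = or, p = min(1, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution (sample sizes in this
#' pipeline are in the hundreds, where the asymptotic form is accurate).
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list with elements `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("both samples need >= 2 values")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; q-values are monotone in the input p-values and
#' clipped to 1. NA p-values propagate to NA q-values.
#'
#' @param p numeric p-values in [0, 1] (NA allowed).
#' @return numeric q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Upper-tail binomial probability
#'
#' P(X >= x) for X ~ Binomial(n, p0), the backbone of the STARR-seq
#' binomial activity caller.
#'
#' @param x observed successes (0 <= x <= n).
#' @param n number of trials.
#' @param p0 null success probability in (0, 1).
#' @return upper-tail probability.
#' @export
binomial_upper_tail <- function(x, n, p0) {
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must lie in (0, 1)")
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n")
  pbinom(x - 1, n, p0, lower.tail = FALSE)
}
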