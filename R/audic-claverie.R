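# The Audic-Claverie exact test for tag-count differences between two
# libraries of sizes N1 and N2. Conditional on observing x tags in the
# first library, the probability of observing y in the second is
#
#   p(y | x) = (N2/N1)^y * (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) )
#
# which is a negative-binomial distribution in y with size x+1 and success
# probability N1/(N1+N2). Everything is evaluated in log space via
# log-gamma so counts of order 1e6 do not overflow.

#' Audic-Claverie conditional probability
#'
#' @param x,y Tag counts of a gene in the two libraries (non-negative,
#'   vectorized).
#' @param n1,n2 Library sizes (clean-tag totals), > 0.
#' @return `p(y | x)` in `(0, 1]`.
#' @export
#' @examples
#' ac_probability(0, 0, 1e6, 1e6)  # 0.5
ac_probability <- function(x, y, n1, n2) {
  assert_counts(x, "x")
  assert_counts(y, "y")
  assert_scalar_number(n1, "n1", min = 0, strict_min = TRUE)
  assert_scalar_number(n2, "n2", min = 0, strict_min = TRUE)
  r <- n2 / n1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

# log p(k | x) over a vector of k, shared prefactors precomputed.
ac_log_prob_k <- function(k, x, logr, log1pr) {
  k * logr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1pr
}

#' Audic-Claverie two-sided p-value
#'
#' Two-sided tail probability under the conditional distribution of the
#' second count given the first: `p = min(1, 2 * min(P(Y <= y), P(Y >= y)))`.
#' The lower tail is summed directly; the upper tail is summed forward from
#' `y` and truncated once terms fall below `1e-16` of the running sum
#' (past the distribution mode).
#'
#' @inheritParams ac_probability
#' @param rel_tol Truncation tolerance for the upper-tail summation.
#' @return Two-sided p-values in `(0, 1]` (vectorized over `x`, `y`).
#' @export
#' @examples
#' ac_pvalue_two_sided(5, 5, 1e6, 1e6)  # symmetric center: 1
ac_pvalue_two_sided <- function(x, y, n1, n2, rel_tol = 1e-16) {
  assert_counts(x, "x")
  assert_counts(y, "y")
  assert_scalar_number(n1, "n1", min = 0, strict_min = TRUE)
  assert_scalar_number(n2, "n2", min = 0, strict_min = TRUE)
  if (length(x) != length(y)) {
    k <- max(length(x), length(y))
    x <- rep_len(x, k)
    y <- rep_len(y, k)
  }
  r <- n2 / n1
  logr <- log(r)
  log1pr <- log1p(r)
  one <- function(xi, yi) {
    lower <- 0
    done <- 0
    while (done <= yi) {  # chunked so huge y does not allocate huge vectors
      ks <- done:min(yi, done + 262143)
      lower <- lower + sum(exp(ac_log_prob_k(ks, xi, logr, log1pr)))
      done <- done + 262144
    }
    mode_k <- r * (xi + 1)
    upper <- 0
    from <- yi
    repeat {
      ks <- from:(from + 255)
      terms <- exp(ac_log_prob_k(ks, xi, logr, log1pr))
      upper <- upper + sum(terms)
      from <- from + 256
      # `<=` so the loop also stops when both sides underflow to zero
      if (from > mode_k && terms[256] <= rel_tol * upper) break
    }
    min(1, 2 * min(lower, upper))
  }
  vapply(seq_along(x), function(i) one(x[i], y[i]), numeric(1))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `q(i) = min_{j >= i} m * p(j) / j` over ascending
#' p-values, order-preserving in the original input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (FDR / q-values) in `[0, 1]`.
#' @export
bh_fdr <- function(p) {
  assert_probability(p, "p")
  p.adjust(p, method = "BH")
}
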