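# Wilcoxon/Mann-Whitney rank-sum machinery shared by the differential
# expression and spatial modules. Exact p-values come from enumeration of
# all C(n, nA) assignments of the pooled (average-rank) values, which
# remains valid under ties; larger samples use the tie-corrected normal
# approximation of the rank-sum statistic (no continuity correction).

# distribution of rank-sums over all subsets of size nx
ranksum_enumerate <- function(r, nx) {
  colSums(matrix(r[utils::combn(length(r), nx)], nrow = nx))
}

ranksum_p <- function(x, y,
                      alternative = c("two.sided", "less"),
                      exact_max = 10L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) {
    stop_input("both samples must be nonempty.")
  }
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  if (nx <= exact_max && ny <= exact_max) {
    sums <- ranksum_enumerate(r, nx)
    if (alternative == "less") {
      p <- mean(sums <= w)
    } else {
      e <- nx * (nx + ny + 1) / 2
      p <- mean(abs(sums - e) >= abs(w - e) - 1e-9)
    }
    return(min(1, p))
  }
  n <- nx + ny
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (w - nx * (n + 1) / 2) / sqrt(sigma2)
  p <- switch(alternative,
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  min(1, p)
}

#' One-sided Mann-Whitney test that sample A is stochastically smaller
#'
#' Used to compare observed nearest-neighbor distances against pooled
#' permutation-null distances. Exact by enumeration when both samples have
#' at most 8 values (valid under ties); tie-corrected normal approximation
#' of the rank-sum statistic otherwise.
#'
#' @param a,b Numeric samples (e.g. distances); both nonempty.
#' @return One-sided p-value for the alternative "a is smaller than b".
#' @export
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6)) # 1/20
mwu_test <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    stop_input("`a` and `b` must be numeric.")
  }
  ranksum_p(a, b, alternative = "less", exact_max = 8L)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validated wrapper around the standard step-up procedure:
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_input("p-values must be numeric in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}
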