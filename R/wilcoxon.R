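# Exact Wilcoxon tests with ties.
#
# The IE comparisons in this package operate on small per-patient summaries
# (typically 7 vs 7), often containing tied values (e.g. identical LR scores
# or zero fractions). stats::wilcox.test() falls back to a normal
# approximation whenever ties are present; here the exact conditional null
# distribution given the observed (tied) ranks is computed by dynamic
# programming over the generating function, which is cheap at these sizes.
# Average ranks are doubled so all rank sums are integers.

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Computes the rank-sum statistic of the first sample and its exact
#' conditional null distribution given the pooled (tie-averaged) ranks: all
#' `choose(n1 + n2, n1)` assignments of ranks to the first group are counted
#' by dynamic programming. The two-sided p-value doubles the smaller tail
#' probability (capped at 1). Falls back to the normal approximation with tie
#' correction when the pooled size exceeds `exact_max`.
#'
#' @param x,y numeric samples.
#' @param exact_max largest pooled sample size for which the exact
#'   distribution is computed (default 200).
#' @return list(statistic = rank sum of `x`, p, method).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 200) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("domain error: both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (N <= exact_max) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # dp[k+1, s+1] = number of size-k subsets with doubled-rank sum s
    dp <- matrix(0, n1 + 1, total + 1)
    dp[1, 1] <- 1
    for (ri in r2) {
      for (k in n1:1) {
        nz <- which(dp[k, ] > 0)
        if (length(nz)) dp[k + 1, nz + ri] <- dp[k + 1, nz + ri] + dp[k, nz]
      }
    }
    cnt <- dp[n1 + 1, ]
    tot <- sum(cnt)
    w2 <- as.integer(round(2 * w))
    pl <- sum(cnt[seq_len(w2 + 1)]) / tot
    pu <- sum(cnt[(w2 + 1):(total + 1)]) / tot
    p <- min(1, 2 * min(pl, pu))
    return(list(statistic = w, p = p, method = "exact"))
  }
  mu <- n1 * (N + 1) / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z <- (w - mu) / sqrt(sigma2)
  list(statistic = w, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' For paired samples: zero differences are dropped (signed-rank
#' convention); the statistic is the sum of the (tie-averaged) ranks of
#' `|d|` carried by positive differences. The exact null enumerates all
#' `2^n` sign assignments via the generating function
#' `prod_i (1 + z^(2 r_i)) / 2^n`. The two-sided p doubles the smaller tail,
#' capped at 1. When every difference is zero the test is undefined and
#' `p = 1` is returned with a warning. Normal approximation (with tie
#' correction) beyond `exact_max` non-zero pairs.
#'
#' @param x,y numeric paired samples (`y` omitted: `x` are the differences).
#' @param exact_max largest number of non-zero pairs for the exact
#'   distribution (default 100).
#' @return list(statistic, p, n_used, method).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 100) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero: signed-rank test undefined, p = 1")
    return(list(statistic = NA_real_, p = 1, n_used = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- numeric(total + 1); cnt[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), cnt[seq_len(total + 1 - ri)])
      cnt <- cnt + shifted
    }
    tot <- sum(cnt)
    v2 <- as.integer(round(2 * v))
    pl <- sum(cnt[seq_len(v2 + 1)]) / tot
    pu <- sum(cnt[(v2 + 1):(total + 1)]) / tot
    p <- min(1, 2 * min(pl, pu))
    return(list(statistic = v, p = p, n_used = n, method = "exact"))
  }
  mu <- sum(r) / 2
  sigma2 <- sum(r^2) / 4
  z <- (v - mu) / sqrt(sigma2)
  list(statistic = v, p = min(1, 2 * stats::pnorm(-abs(z))), n_used = n,
       method = "normal")
}
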