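.test_result <- function(statistic, p, n, method) {
  structure(list(statistic = statistic, p_two_sided = p,
                 n_effective = n, method = method),
            class = "da_test_result")
}

#' @export
print.da_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.6g, n = %d\n",
              x$method, x$statistic, x$p_two_sided, x$n_effective))
  invisible(x)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided one-sample Wilcoxon signed-rank test on a vector of paired
#' differences.  Zero differences are dropped; tied absolute values receive
#' midranks.  For `n <= exact_max_n` non-zero differences the null
#' distribution of the positive-rank sum is computed exactly over all `2^n`
#' sign assignments (by convolution of the rank generating function, so ties
#' are handled exactly), and the two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.  Above that, a normal
#' approximation with tie correction is used.
#'
#' With `n` all-positive differences the exact two-sided p is `2 / 2^n`:
#' 0.00390625 at n = 9 and 0.015625 at n = 7, the floor attainable in
#' session-level behavioral comparisons at those sample sizes.
#'
#' @param diffs Numeric vector of differences.
#' @param exact_max_n Largest n for which the exact distribution is used.
#' @return A `da_test_result` with the positive-rank sum as statistic and
#'   `method` `"wilcoxon_exact"` or `"wilcoxon_normal"`.
#' @examples
#' wilcoxon_signed_rank(rep(1, 9))$p_two_sided  # 2/512
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max_n = 25) {
  if (!length(diffs)) stop("no differences supplied", call. = FALSE)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) {
    stop("all differences are zero; signed-rank test undefined", call. = FALSE)
  }
  r <- rank(abs(d))            # midranks for ties
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    ir <- as.integer(round(2 * r))   # doubled ranks are integers
    total <- sum(ir)
    f <- numeric(total + 1)          # f[k+1] = #assignments with 2W = k
    f[1] <- 1
    for (x in ir) {
      g <- numeric(total + 1)
      g[(x + 1):(total + 1)] <- f[1:(total + 1 - x)]
      f <- f + g
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[1:(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    .test_result(w, p, n, "wilcoxon_exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    .test_result(w, p, n, "wilcoxon_normal")
  }
}

#' Exact two-sided sign test
#'
#' Binomial sign test on counts of positive and negative differences (ties
#' already removed by the caller).  The two-sided p-value is
#' `min(1, 2 * min(P(X <= n_neg), P(X <= n_pos)))` with
#' `X ~ Binomial(n_pos + n_neg, 1/2)`.
#'
#' @param n_pos,n_neg Non-negative counts.
#' @return A `da_test_result` with `n_pos` as statistic, method `"sign_exact"`.
#' @examples
#' sign_test(9, 0)$p_two_sided  # 2 * (1/2)^9
#' @export
sign_test <- function(n_pos, n_neg) {
  if (n_pos < 0 || n_neg < 0) stop("counts must be non-negative", call. = FALSE)
  n <- n_pos + n_neg
  if (n < 1) stop("need at least one non-tied observation", call. = FALSE)
  # by symmetry P(X >= n_pos) = P(X <= n_neg)
  p <- min(1, 2 * min(stats::pbinom(n_pos, n, 0.5),
                      stats::pbinom(n_neg, n, 0.5)))
  .test_result(n_pos, p, n, "sign_exact")
}

#' Welch two-sample t-test
#'
#' Two-sided Welch t-test (unequal variances) on two independent samples.
#'
#' @param a,b Numeric vectors, each with at least 2 values; at least one group
#'   must have non-zero variance.
#' @return A `da_test_result` with method `"t_two_sample"`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("both groups have zero variance; t-test degenerate", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  .test_result(unname(ht$statistic), ht$p.value, length(a) + length(b),
               "t_two_sample")
}

#' Permutation test for a difference of group means
#'
#' Tests whether two groups share a distribution by permuting group labels.
#' The statistic is the difference of group means.  When the number of
#' distinct relabelings `choose(n_a + n_b, n_a)` is at most
#' `exhaustive_limit`, all relabelings are enumerated and the p-value is
#' exact; otherwise `n_perm` random relabelings are drawn and the add-one
#' estimator `p = (1 + #{|T*| >= |T_obs|}) / (n_perm + 1)` is used, which can
#' never return 0.
#'
#' @param group_a,group_b Numeric vectors, non-empty.
#' @param stat Test statistic; only `"mean_difference"` is implemented.
#' @param n_perm Number of random permutations (ignored when exhaustive).
#' @param seed Integer seed for the random relabelings.
#' @param exhaustive_limit Enumerate exactly when the relabeling count is at
#'   most this.
#' @return A list of class `da_perm_result` with `observed_stat`,
#'   `n_permutations`, `p_two_sided`, `seed`, `exhaustive`.
#' @examples
#' permutation_test(c(10, 11), c(0, 1), seed = 1)$p_two_sided  # 2/6
#' @export
permutation_test <- function(group_a, group_b, stat = "mean_difference",
                             n_perm = 10000, seed = 1,
                             exhaustive_limit = 10000) {
  stat <- match.arg(stat, "mean_difference")
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  na <- length(group_a)
  pooled <- c(group_a, group_b)
  nn <- length(pooled)
  obs <- mean(group_a) - mean(group_b)
  tol <- 1e-12 * (1 + abs(obs))
  total_mean_term <- sum(pooled)
  stat_from_idx <- function(idx) {
    sa <- sum(pooled[idx])
    sa / na - (total_mean_term - sa) / (nn - na)
  }
  n_distinct <- choose(nn, na)
  if (n_distinct <= exhaustive_limit) {
    idx <- utils::combn(nn, na)
    ts <- apply(idx, 2, stat_from_idx)
    p <- sum(abs(ts) >= abs(obs) - tol) / ncol(idx)
    res <- list(observed_stat = obs, n_permutations = ncol(idx),
                p_two_sided = p, seed = seed, exhaustive = TRUE)
  } else {
    if (n_perm < 100) warning("n_perm < 100: permutation p-value is coarse")
    ts <- .with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) stat_from_idx(sample.int(nn, na)), numeric(1))
    })
    p <- (1 + sum(abs(ts) >= abs(obs) - tol)) / (n_perm + 1)
    res <- list(observed_stat = obs, n_permutations = n_perm,
                p_two_sided = p, seed = seed, exhaustive = FALSE)
  }
  class(res) <- "da_perm_result"
  res
}

#' @export
print.da_perm_result <- function(x, ...) {
  cat(sprintf("permutation (%s): observed = %.4g, p = %.6g (%d relabelings)\n",
              if (x$exhaustive) "exhaustive" else "monte-carlo",
              x$observed_stat, x$p_two_sided, x$n_permutations))
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  code
}
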