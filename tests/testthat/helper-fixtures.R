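# Shared fixtures: small generator configurations and independent oracles.

# Small two-block session parameters; spikes/licks/saccades toggled per test.
small_params <- function(...) {
  synth_params(n_trials_pre = 12, n_trials_inact = 12, ...)
}

# Pre-block-only parameters for spike analyses.
spikes_only_params <- function(n = 50, ...) {
  synth_params(n_trials_pre = n, n_trials_inact = 0, ...)
}

default_events <- function() {
  list(fp_onset = 0.5, cs_onset = 1.4, cs_offset = 2.4, reward_time = 2.7)
}

# Brute-force Wilcoxon signed-rank oracle: enumerate all 2^n sign
# assignments of the midranked |d| and take the two-sided tail probability.
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# Sign-test oracle by direct binomial PMF summation.
sign_oracle <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  lower <- sum(stats::dbinom(0:min(n_pos, n_neg), n, 0.5))
  upper <- sum(stats::dbinom(max(n_pos, n_neg):n, n, 0.5))
  min(1, 2 * min(lower, upper))
}
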