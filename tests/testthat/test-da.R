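test_that("SDF closed forms: single-spike peak and mass conservation", {
  s <- spike_density(list(0), kernel_sigma = 0.010)
  expect_equal(max(s$rate), 1 / (0.010 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(s$grid[which.max(s$rate)], 0)
  # no spikes -> identically zero
  expect_true(all(spike_density(list(numeric(0)))$rate == 0))
  # integral = mean spike count per trial for spikes away from the edges
  set.seed(31)
  trials <- lapply(1:40, function(i) sort(runif(rpois(1, 6), -0.4, 0.9)))
  s2 <- spike_density(trials)
  integral <- sum(s2$rate) * s2$step
  expect_equal(integral, mean(lengths(trials)), tolerance = 0.01)
  expect_error(spike_density(list()), "at least one")
})

test_that("SDF of a homogeneous Poisson process is flat at the true rate", {
  set.seed(32)
  trials <- lapply(1:5000, function(i) {
    n <- rpois(1, 5 * 2)
    sort(runif(n, -0.5, 1.5))
  })
  s <- spike_density(trials, span = c(-0.5, 1.0))
  interior <- s$rate[s$grid > -0.45 & s$grid < 0.95]
  # pointwise SE of a kernel rate estimate is sqrt(lambda / (n * 2 sigma
  # sqrt(pi))) ~ 0.17 spikes/s here; the max over ~1400 grid points
  # (decorrelating every ~40 ms) sits near 3.3 SE, so bound the extremes at
  # 4.2 SE and the bulk at 3 SE
  se <- sqrt(5 / (5000 * 2 * 0.01 * sqrt(pi)))
  expect_true(all(abs(interior - 5) < 4.2 * se))
  expect_gt(mean(abs(interior - 5) < 3 * se), 0.98)
})

test_that("baseline statistics summarise the pre-event grid", {
  s <- spike_density(list(numeric(0)))
  s$rate <- rep(7, length(s$grid))
  bl <- baseline_stats(s)
  expect_equal(bl$mean, 7)
  expect_equal(bl$sd, 0)
  s$rate <- rep(c(0, 10), length.out = length(s$grid))
  bl2 <- baseline_stats(s)
  expect_equal(bl2$mean, 5)
  expect_equal(bl2$sd, 5, tolerance = 0.01)
  expect_equal(bl2$n_bins, 500)
  expect_error(baseline_stats(s, c(-2, -1.5)), "outside")
})

test_that("L latency is the first 2SD crossing and stays absent when flat", {
  s <- spike_density(list(numeric(0)))
  s$rate <- ifelse(s$grid < 0.080 - 1e-9, 5, 30)
  bl <- list(mean = 5, sd = 1)
  res <- l_latency(s, bl)
  expect_equal(res$latency, 0.080)
  expect_equal(res$threshold, 7)
  # SDF identical to baseline mean: no crossing, even with sd = 0
  s$rate <- rep(5, length(s$grid))
  expect_false(l_latency(s, list(mean = 5, sd = 0))$detected)
  expect_true(is.na(l_latency(s, list(mean = 5, sd = 0))$latency))
  # raising the threshold multiplier can only delay the crossing
  set.seed(33)
  trials <- lapply(1:40, function(i) {
    sort(c(runif(rpois(1, 5), -0.5, 1.0), runif(rpois(1, 3), 0.1, 0.25)))
  })
  sdf <- spike_density(trials)
  bl3 <- baseline_stats(sdf)
  l2 <- l_latency(sdf, bl3, sd_mult = 2)$latency
  l3 <- l_latency(sdf, bl3, sd_mult = 3)$latency
  if (!is.na(l2) && !is.na(l3)) expect_gte(l3, l2)
})

test_that("V latency finds a constructed sustained differentiation", {
  # 10 pairs: LR has a burst from t = 0.100, SR never does -> every window
  # in the burst has all-positive differences, sign-test p = 2/1024
  lr <- lapply(1:10, function(i) seq(0.1005, 0.40, by = 0.005))
  sr <- lapply(1:10, function(i) numeric(0))
  res <- v_latency(lr, sr)
  expect_identical(res$status, "detected")
  # earliest 1-ms grid start s whose window [s, s + 0.015) reaches the first
  # divergent spike at 0.1005 is s = 0.086: the reported onset leads the true
  # divergence by at most one window width and never trails it
  expect_equal(res$latency, 0.086, tolerance = 1e-9)
  expect_gte(res$latency, 0.1005 - 0.015)
  expect_true(all(res$runs$duration > 0.015))
  # byte-identical LR and SR trials: every comparison ties, no onset
  same <- lapply(1:10, function(i) c(0.05, 0.2, 0.31))
  res2 <- v_latency(same, same)
  expect_identical(res2$status, "none")
  expect_true(is.na(res2$latency))
  # below the detectability bound the result is flagged, not "none"
  res3 <- v_latency(lr[1:5], sr[1:5])
  expect_identical(res3$status, "undetectable")
})

test_that("V latency is monotone in persistence and alpha", {
  p <- spikes_only_params(n = 40)
  s <- generate_session(p, seed = 61, with_licks = FALSE,
                        with_saccades = FALSE)
  lr <- aligned_spikes(s, "n01", "CS", condition = "pre", value_label = "LR")
  sr <- aligned_spikes(s, "n01", "CS", condition = "pre", value_label = "SR")
  v_base <- v_latency(lr, sr)$latency
  v_long <- v_latency(lr, sr, persistence = 0.030)$latency
  v_strict <- v_latency(lr, sr, alpha = 0.01)$latency
  if (is.na(v_base)) {
    # no onset at the default settings: stricter settings cannot create one
    expect_true(is.na(v_long))
    expect_true(is.na(v_strict))
  } else {
    expect_true(is.na(v_long) || v_long >= v_base - 1e-12)
    expect_true(is.na(v_strict) || v_strict >= v_base - 1e-12)
  }
})

test_that("window_rate converts counts to rates over half-open windows", {
  trials <- list(c(0.10, 0.15, 0.20, 0.25), c(0.30), numeric(0))
  res <- window_rate(trials, window = c(0.1, 0.3))
  expect_equal(res$rates, c(20, 0, 0))
  expect_equal(res$mean, mean(c(20, 0, 0)))
  expect_error(window_rate(trials, window = c(0.3, 0.1)), "t0 < t1")
  # Poisson rate recovery: 500 trials at 12 spikes/s in a 0.2 s window
  set.seed(34)
  tr <- lapply(1:500, function(i) sort(runif(rpois(1, 12 * 0.5), 0, 0.5)))
  wr <- window_rate(tr, window = c(0.1, 0.3))
  se <- sqrt(12 / (0.2 * 500))
  expect_lt(abs(wr$mean - 12), qnorm(0.995) * se)
})

test_that("DA screening is a strict conjunction of the four criteria", {
  ok <- list(baseline_rate = 4, has_reward_response = TRUE,
             spike_width = 0.0020, nearby_snr_widths = rep(0.0010, 5),
             location_ok = TRUE)
  expect_true(do.call(screen_da_neuron, ok)$accepted)
  # flipping any single criterion flips acceptance
  low <- ok; low$baseline_rate <- 0.5
  expect_false(do.call(screen_da_neuron, low)$accepted)
  expect_false(do.call(screen_da_neuron, low)$criteria$baseline_in_range)
  high <- ok; high$baseline_rate <- 45   # SNr-like fast firing
  expect_false(do.call(screen_da_neuron, high)$accepted)
  norw <- ok; norw$has_reward_response <- FALSE
  expect_false(do.call(screen_da_neuron, norw)$accepted)
  thin <- ok; thin$spike_width <- 0.0011
  expect_false(do.call(screen_da_neuron, thin)$accepted)
  away <- ok; away$location_ok <- FALSE
  expect_false(do.call(screen_da_neuron, away)$accepted)
  # no SNr reference: width criterion indeterminate, conservative rejection
  nosnr <- ok; nosnr$nearby_snr_widths <- numeric(0)
  res <- do.call(screen_da_neuron, nosnr)
  expect_false(res$accepted)
  expect_true(is.na(res$criteria$spike_width_ok))
})

test_that("pre/post comparison is null on a copied block and exact at n = 9", {
  set.seed(35)
  rates <- lapply(1:3, function(i) rpois(20, 10) / 0.2)
  names(rates) <- paste0("n", 1:3)
  res <- pre_post_comparison(rates, rates, n_perm = 200, seed = 4,
                             min_neurons = 5)
  expect_true(all(res$per_neuron$perm_p == 1))
  expect_true(all(res$per_neuron$delta == 0))
  expect_match(res$population_note, "needs >= 5")
  # 9 neurons all decreasing: population Wilcoxon at its exact minimum
  pre <- lapply(1:9, function(i) rnorm(15, 12, 1))
  post <- lapply(pre, function(x) x - 3 + rnorm(15, 0, 0.1))
  names(pre) <- names(post) <- paste0("n", 1:9)
  res2 <- pre_post_comparison(pre, post, n_perm = 200, seed = 4)
  expect_equal(res2$population$p_two_sided, 0.00390625)
  expect_true(all(res2$per_neuron$delta < 0))
})

test_that("reduced CS drive during inactivation reaches the population test", {
  hits <- vapply(1:12, function(k) {
    p <- synth_params(n_trials_pre = 30, n_trials_inact = 30, n_neurons = 9,
                      kernels = default_kernels(cs_condition_scale = 0.5))
    s <- generate_session(p, seed = 8000 + k, with_licks = FALSE,
                          with_saccades = FALSE)
    rates <- lapply(c("pre", "inactivation"), function(cond) {
      out <- lapply(s$neuron_ids, function(nid) {
        window_rate(aligned_spikes(s, nid, "CS", condition = cond,
                                   value_label = "LR"))$rates
      })
      names(out) <- s$neuron_ids
      out
    })
    pre_post_comparison(rates[[1]], rates[[2]], n_perm = 200,
                        seed = k)$population$p_two_sided < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
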