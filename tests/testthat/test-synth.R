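test_that("identical (params, seed) give identical sessions", {
  p <- small_params()
  s1 <- generate_session(p, seed = 99)
  s2 <- generate_session(p, seed = 99)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$licks, s2$licks)
  expect_identical(s1$saccades, s2$saccades)
  s3 <- generate_session(p, seed = 100)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("adding trials never perturbs earlier trials", {
  p12 <- small_params()
  p20 <- synth_params(n_trials_pre = 20, n_trials_inact = 12)
  s12 <- generate_session(p12, seed = 5)
  s20 <- generate_session(p20, seed = 5)
  first <- s20$spikes[s20$spikes$trial_id <= 12, ]
  ref <- s12$spikes[s12$spikes$trial_id <= 12, ]
  rownames(first) <- rownames(ref) <- NULL
  expect_equal(first, ref)
})

test_that("trial timing honours the task structure", {
  s <- generate_session(synth_params(n_trials_pre = 200, n_trials_inact = 0),
                        seed = 31, with_spikes = FALSE, with_licks = FALSE,
                        with_saccades = FALSE)
  soa <- s$trials$cs_onset - s$trials$fp_onset
  expect_true(all(soa >= 0.7 & soa <= 1.2))
  expect_equal(s$trials$cs_offset - s$trials$cs_onset,
               rep(1.0, 200), tolerance = 1e-9)
  # LR/SR assignment is a fair coin: 99% binomial CI around 0.5
  n <- 4000
  labs <- vapply(1:20, function(k) {
    ss <- generate_session(synth_params(n_trials_pre = 200, n_trials_inact = 0),
                           seed = 4000 + k, with_spikes = FALSE,
                           with_licks = FALSE, with_saccades = FALSE)
    sum(ss$trials$value_label == "LR")
  }, numeric(1))
  frac <- sum(labs) / n
  ci <- qnorm(0.995) * sqrt(0.25 / n)
  expect_lt(abs(frac - 0.5), ci)
})

test_that("homogeneous spike trains have the Poisson mean count", {
  ev <- default_events()
  counts <- vapply(1:2000, function(i) {
    length(generate_spike_train(ev, "LR", "pre", t_end = 4, baseline = 5,
                                kernels = list(), seed = i))
  }, numeric(1))
  # E[N] = lambda * T = 20; 99% CI for the mean of 2000 draws
  se <- sqrt(20 / 2000)
  expect_lt(abs(mean(counts) - 20), qnorm(0.995) * se)
})

test_that("a Gaussian kernel adds amplitude * sigma * sqrt(2*pi) spikes", {
  ev <- default_events()
  k <- list(response_kernel("CS", onset_latency = 0.08, width_sigma = 0.02,
                            amplitude_lr = 40, amplitude_sr = 40))
  counts <- vapply(1:2000, function(i) {
    length(generate_spike_train(ev, "LR", "pre", t_end = 4, baseline = 0,
                                kernels = k, seed = 10000 + i))
  }, numeric(1))
  expected <- 40 * 0.02 * sqrt(2 * pi)   # ~2.005 spikes per trial
  se <- sqrt(expected / 2000)
  expect_lt(abs(mean(counts) - expected), qnorm(0.995) * se)
})

test_that("empirical PSTH converges to the specified intensity", {
  ev <- default_events()
  kern <- default_kernels()
  n <- 3000
  breaks <- seq(0, 3.5, by = 0.05)
  acc <- numeric(length(breaks) - 1)
  for (i in seq_len(n)) {
    st <- generate_spike_train(ev, "LR", "pre", t_end = 3.5, baseline = 5,
                               kernels = kern, seed = 20000 + i)
    acc <- acc + hist(st, breaks = breaks, plot = FALSE)$counts
  }
  # bin-averaged intensity (the bumps curve appreciably across a 50 ms bin)
  fine <- seq(0.005, 3.5 - 0.005, by = 0.01)
  lam_fine <- dacue:::.intensity(fine, 5, kern, ev, "LR", "pre")
  lam <- colMeans(matrix(lam_fine, nrow = 5))
  emp <- acc / n / 0.05
  se <- sqrt(lam / (n * 0.05))
  expect_true(all(abs(emp - lam) < 4 * se + 0.05))
})

test_that("negative intensity is rejected before simulation", {
  ev <- default_events()
  k <- list(response_kernel("CS", 0.08, 0.02, amplitude_lr = -10,
                            amplitude_sr = -10))
  expect_error(generate_spike_train(ev, "LR", "pre", 4, baseline = 2,
                                    kernels = k, seed = 1),
               "negative")
  expect_error(generate_spike_train(ev, "LR", "pre", 4, baseline = 0,
                                    kernels = list(), seed = 1),
               "must be > 0")
})

test_that("licks concentrate in the value-dependent anticipatory window", {
  ev <- default_events()
  # LR: [cs_onset, reward); SR: [cs_offset, reward)
  lr <- unlist(lapply(1:300, function(i) {
    generate_licks(ev, "LR", "pre", 3.4, baseline = 0, anticipatory = 4,
                   seed = i)
  }))
  expect_true(all(lr >= ev$cs_onset & lr < ev$reward_time))
  ev_sr <- ev
  ev_sr$reward_time <- ev$cs_offset + 0.5
  sr <- unlist(lapply(1:300, function(i) {
    generate_licks(ev_sr, "SR", "pre", 3.4, baseline = 0, anticipatory = 4,
                   seed = 500 + i)
  }))
  expect_true(all(sr >= ev$cs_offset & sr < ev_sr$reward_time))
  # zero rates -> no licks
  expect_length(generate_licks(ev, "LR", "pre", 3.4, 0, 0, seed = 1), 0)
  expect_error(generate_licks(ev, "LR", "pre", 3.4, -1, 2, seed = 1), ">= 0")
})

test_that("equal anticipatory and baseline rates yield no LR/SR difference", {
  diffs <- vapply(1:40, function(i) {
    p <- synth_params(n_trials_pre = 40, n_trials_inact = 0,
                      lick_baseline_rate = 2, lick_anticipatory_rate = 2)
    s <- generate_session(p, seed = 6000 + i, with_spikes = FALSE,
                          with_saccades = FALSE)
    cr <- cr_discrimination(s)
    cr$mean_rate_lr - cr$mean_rate_sr
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1e-9)
})

test_that("saccade model shifts only the affected direction", {
  model <- list(directions = c(-45, 45, 135), latency_mean = 180,
                latency_sd = 20, affected_direction = 45,
                inactivation_shift = 53, n_per_cell = 300)
  rec <- generate_saccades(model, seed = 77)
  expect_true(all(rec$latency_ms > 50))
  est <- saccade_prolongation(rec)
  aff <- est[est$direction == 45, ]
  oth <- est[est$direction != 45, ]
  # SE of a difference of means at n = 300/group, SD 20 ms is ~1.6 ms,
  # so +/- 6 ms is a ~3.7 SD bound
  expect_lt(abs(aff$delta_ms - 53), 6)
  expect_true(all(abs(oth$delta_ms) < 6))
})
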