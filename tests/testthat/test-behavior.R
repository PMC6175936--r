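test_that("licking rate counts in a half-open window", {
  ev <- list(cs_onset = 1.0, reward_time = 1.6)
  licks <- 1.0 + c(0.05, 0.1, 0.2, 0.3, 0.4, 0.55)
  res <- licking_rate(licks, ev)   # 6 licks in 0.6 s
  expect_equal(res$rate, 10)
  expect_equal(res$n_licks, 6)
  expect_equal(licking_rate(numeric(0), ev)$rate, 0)
  # fixed window [0.7, 1.3) after CS onset: boundaries half-open
  ev2 <- list(cs_onset = 2.0, reward_time = 3.3)
  res2 <- licking_rate(c(2.71, 3.29, 3.30), ev2, window_rule = "fixed")
  expect_equal(res2$n_licks, 2)
  expect_error(licking_rate(1, list(cs_onset = 1, reward_time = 1)),
               "empty")
})

test_that("binned lick counts partition the window total", {
  ev <- list(cs_onset = 0.5, reward_time = 1.8)
  set.seed(8)
  licks <- sort(runif(40, 0, 2))
  res <- licking_rate(licks, ev, bin = 0.1)
  expect_equal(sum(res$bin_counts), res$n_licks)
  # additivity across an arbitrary split of the window
  n_left <- sum(licks >= 0.5 & licks < 1.1)
  n_right <- sum(licks >= 1.1 & licks < 1.8)
  expect_equal(res$n_licks, n_left + n_right)
})

test_that("cr_discrimination reproduces the exact paired Wilcoxon", {
  # 9 units, all LR > SR: minimal attainable two-sided p
  pairs <- data.frame(rate_lr = 5 + (1:9) / 10, rate_sr = 2 + (1:9) / 10)
  res <- cr_discrimination(pairs)
  expect_equal(res$test$p_two_sided, 0.00390625)
  expect_equal(res$n_pairs, 9)
  # alternating equal-magnitude signs at even n: p = 1 by symmetry
  alt <- data.frame(rate_lr = c(3, 2, 3, 2), rate_sr = c(2, 3, 2, 3))
  expect_equal(cr_discrimination(alt)$test$p_two_sided, 1.0)
  # agreement with the enumeration oracle on arbitrary differences
  set.seed(11)
  d <- rnorm(8)
  pr <- data.frame(rate_lr = d + 1, rate_sr = rep(1, 8))
  expect_equal(cr_discrimination(pr)$test$p_two_sided, wilcoxon_oracle(d))
})

test_that("strong anticipatory licking is detected across experiments", {
  # 9-session experiments with anticipatory >> baseline licking
  reject <- vapply(1:30, function(k) {
    rates <- t(vapply(1:9, function(j) {
      s <- generate_session(small_params(), seed = 900 * k + j,
                            with_spikes = FALSE, with_saccades = FALSE)
      cr <- cr_discrimination(s, condition = "pre")
      c(cr$mean_rate_lr, cr$mean_rate_sr)
    }, numeric(2)))
    cr_discrimination(data.frame(rate_lr = rates[, 1],
                                 rate_sr = rates[, 2]))$test$p_two_sided < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("inactivation comparison is null when behavior is intact", {
  s <- generate_session(small_params(), seed = 15, with_spikes = FALSE,
                        with_saccades = FALSE)
  res <- inactivation_effect_licking(s, n_perm = 499, seed = 2)
  expect_s3_class(res$permutation, "da_perm_result")
  expect_length(res$diff_pre, min(table(
    s$trials$value_label[s$trials$condition == "pre"])))
  # pre block copied verbatim as inactivation block: permutation p = 1
  tr <- s$trials[s$trials$condition == "pre", ]
  tr2 <- tr
  tr2$trial_id <- tr$trial_id + 100
  tr2$condition <- "inactivation"
  lk <- s$licks[s$licks$trial_id %in% tr$trial_id, ]
  lk2 <- lk
  lk2$trial_id <- lk$trial_id + 100
  twin <- da_session(rbind(tr, tr2), licks = rbind(lk, lk2),
                     config = s$config)
  res2 <- inactivation_effect_licking(twin, n_perm = 499, seed = 2)
  expect_equal(res2$permutation$p_two_sided, 1.0)
  expect_null(res2$wilcoxon)
  expect_match(res2$wilcoxon_note, "zero")
})

test_that("abolished anticipatory licking is detected during inactivation", {
  hits <- vapply(1:25, function(k) {
    p <- synth_params(n_trials_pre = 30, n_trials_inact = 30,
                      lick_inactivation_scale = 0)
    s <- generate_session(p, seed = 7000 + k, with_spikes = FALSE,
                          with_saccades = FALSE)
    inactivation_effect_licking(s, n_perm = 999, seed = k)$
      permutation$p_two_sided < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("saccade prolongation recovers a constructed 53 ms shift", {
  set.seed(21)
  rec <- data.frame(
    condition = rep(c("pre", "inactivation"), each = 40),
    target_direction = 45,
    latency_ms = c(180 + rnorm(40, sd = 0.1), 233 + rnorm(40, sd = 0.1)))
  est <- saccade_prolongation(rec)
  expect_equal(est$delta_ms, 53, tolerance = 0.1)
  expect_lt(est$p_two_sided, 1e-5)
  # a direction missing one condition is skipped with a warning
  rec2 <- rbind(rec, data.frame(condition = "pre", target_direction = 135,
                                latency_ms = 170 + rnorm(40)))
  expect_warning(est2 <- saccade_prolongation(rec2), "skipped")
  expect_equal(est2$direction, 45)
  expect_error(suppressWarnings(saccade_prolongation(rec2[81:120, ])),
               "no direction")
})
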