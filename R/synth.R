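# Synthetic Pavlovian-conditioning sessions with known ground truth.
#
# Generative model, per trial:
#   * fp_onset fixed; cs_onset = fp_onset + U(0.7, 1.2); CS lasts cs_duration;
#     reward at cs_onset + reward_delay_lr (LR) or cs_offset + reward_delay_sr
#     (SR); LR/SR assigned with equal probability.
#   * spikes: inhomogeneous Poisson, intensity
#       lambda(t) = baseline + sum_k amp_k(value, condition) *
#                   exp(-(t - center_k)^2 / (2 sigma_k^2)),
#     center_k = event_k + onset_latency_k + 2 sigma_k, so onset_latency is
#     the ground-truth response onset (the bump starts rising ~2 sigma before
#     its center). Sampled exactly by thinning against lambda_max.
#   * licks: piecewise-homogeneous Poisson, baseline rate everywhere and
#     anticipatory rate inside [cs_onset, reward) on LR trials and
#     [cs_offset, reward) on SR trials.
#   * saccades: per direction/condition Gaussian latencies truncated at
#     > 50 ms, with a mean shift added only to the muscimol-affected
#     direction during inactivation.
# One master seed spawns independent per-trial, per-component substreams, so
# adding trials never perturbs earlier trials.

#' Event-locked response kernel
#'
#' A Gaussian intensity bump locked to a trial event, with value-dependent
#' amplitude and an optional multiplicative scale applied during SC
#' inactivation.  `onset_latency` is the ground-truth response onset: the bump
#' center sits at `event + onset_latency + 2 * width_sigma`.
#'
#' @param event `"FP"`, `"CS"` or `"RW"`.
#' @param onset_latency Ground-truth onset relative to the event, s.
#' @param width_sigma Bump SD, s (> 0).
#' @param amplitude_lr,amplitude_sr Peak amplitude on LR / SR trials,
#'   spikes/s.
#' @param condition_scale_inactivation Multiplier applied to both amplitudes
#'   during the inactivation block (1 = no effect).
#' @return A `response_kernel` list.
#' @export
response_kernel <- function(event, onset_latency, width_sigma,
                            amplitude_lr, amplitude_sr,
                            condition_scale_inactivation = 1) {
  event <- match.arg(event, ALIGN_EVENTS)
  if (width_sigma <= 0) stop("width_sigma must be > 0", call. = FALSE)
  structure(list(event = event, onset_latency = onset_latency,
                 width_sigma = width_sigma,
                 amplitude_lr = amplitude_lr, amplitude_sr = amplitude_sr,
                 condition_scale_inactivation = condition_scale_inactivation),
            class = "response_kernel")
}

#' Default DA response kernels
#'
#' The canonical phasic response profile: a value-independent FP response, a
#' strongly value-coded CS response (large on LR trials, weak on SR trials)
#' with ~85 ms onset, and no response to predicted reward delivery.
#'
#' @param cs_onset_latency CS response onset, s.
#' @param cs_amplitude_lr,cs_amplitude_sr CS response peak amplitudes,
#'   spikes/s.
#' @param cs_condition_scale CS amplitude multiplier during inactivation.
#' @return List of [response_kernel()] objects.
#' @export
default_kernels <- function(cs_onset_latency = 0.085,
                            cs_amplitude_lr = 50, cs_amplitude_sr = 10,
                            cs_condition_scale = 1) {
  list(
    response_kernel("FP", onset_latency = 0.100, width_sigma = 0.020,
                    amplitude_lr = 30, amplitude_sr = 30),
    response_kernel("CS", onset_latency = cs_onset_latency,
                    width_sigma = 0.020,
                    amplitude_lr = cs_amplitude_lr,
                    amplitude_sr = cs_amplitude_sr,
                    condition_scale_inactivation = cs_condition_scale),
    response_kernel("RW", onset_latency = 0.150, width_sigma = 0.030,
                    amplitude_lr = 0, amplitude_sr = 0)
  )
}

#' Synthetic session parameters
#'
#' Full generative specification for [generate_session()].  Defaults emulate
#' the study conditions: a control block of about 60 trials followed by an
#' inactivation block, baseline DA rate inside the 1.0--10.0 spikes/s
#' screening range, a 1.0 s CS appearing 0.7--1.2 s after FP onset, reward at
#' 1.3 s after CS onset (LR) or 0.5 s after CS offset (SR), clear anticipatory
#' licking, and a 53 ms saccade-latency shift confined to the affected
#' direction during inactivation.
#'
#' @param n_trials_pre,n_trials_inact Trials per block.
#' @param n_neurons Number of simulated DA neurons.
#' @param baseline_rate Baseline firing rate, spikes/s.
#' @param kernels List of [response_kernel()] objects.
#' @param lick_baseline_rate Lick rate outside the anticipatory window, /s.
#' @param lick_anticipatory_rate Lick rate inside the anticipatory window, /s.
#' @param lick_inactivation_scale Scale on the anticipatory elevation during
#'   inactivation (1 = behavior intact, 0 = anticipatory licking abolished).
#' @param saccade List: `directions` (deg), `latency_mean` and `latency_sd`
#'   (ms), `affected_direction` (deg), `inactivation_shift` (ms),
#'   `n_per_cell` (records per condition x direction).
#' @param fp_onset FP onset time within the trial, s.
#' @param cs_duration CS presentation time, s (1.0 or 1.7 depending on
#'   animal).
#' @param reward_delay_lr Reward delay after CS onset on LR trials, s.
#' @param reward_delay_sr Reward delay after CS offset on SR trials, s.
#' @param trial_tail Simulated time after reward, s.
#' @param stimulus A [stimulus_spec()].
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_trials_pre = 60, n_trials_inact = 60,
                         n_neurons = 1,
                         baseline_rate = 5,
                         kernels = default_kernels(),
                         lick_baseline_rate = 0.5,
                         lick_anticipatory_rate = 4,
                         lick_inactivation_scale = 1,
                         saccade = list(directions = c(-135, -45, 45, 135),
                                        latency_mean = 180, latency_sd = 20,
                                        affected_direction = 45,
                                        inactivation_shift = 53,
                                        n_per_cell = 60),
                         fp_onset = 0.5, cs_duration = 1.0,
                         reward_delay_lr = 1.3, reward_delay_sr = 0.5,
                         trial_tail = 0.5,
                         stimulus = stimulus_spec()) {
  if (n_trials_pre < 1 || n_trials_inact < 0) {
    stop("need n_trials_pre >= 1 and n_trials_inact >= 0", call. = FALSE)
  }
  if (baseline_rate < 0) stop("baseline_rate must be >= 0", call. = FALSE)
  if (lick_baseline_rate < 0 || lick_anticipatory_rate < 0) {
    stop("lick rates must be >= 0", call. = FALSE)
  }
  if (saccade$latency_sd <= 0) stop("saccade latency SD must be > 0",
                                    call. = FALSE)
  structure(list(
    n_trials_pre = n_trials_pre, n_trials_inact = n_trials_inact,
    n_neurons = n_neurons, baseline_rate = baseline_rate, kernels = kernels,
    lick_baseline_rate = lick_baseline_rate,
    lick_anticipatory_rate = lick_anticipatory_rate,
    lick_inactivation_scale = lick_inactivation_scale,
    saccade = saccade,
    fp_onset = fp_onset, cs_duration = cs_duration,
    reward_delay_lr = reward_delay_lr, reward_delay_sr = reward_delay_sr,
    trial_tail = trial_tail, stimulus = stimulus
  ), class = "synth_params")
}

# Independent substream seed for (master, trial, component). Components:
# 0 timing, 100 + neuron for spikes, 1 licks, 2 saccades.
.substream <- function(master, trial, component) {
  (as.double(master) * 7919 + trial * 104729 + component * 1299709 +
     15485863) %% 2147483629
}

.kernel_amp <- function(k, value_label, condition) {
  amp <- if (value_label == "LR") k$amplitude_lr else k$amplitude_sr
  if (condition == "inactivation") amp <- amp * k$condition_scale_inactivation
  amp
}

.event_time <- function(events, name) {
  switch(name, FP = events$fp_onset, CS = events$cs_onset,
         RW = events$reward_time)
}

.intensity <- function(t, baseline, kernels, events, value_label, condition) {
  lam <- rep(baseline, length(t))
  for (k in kernels) {
    amp <- .kernel_amp(k, value_label, condition)
    if (amp == 0) next
    center <- .event_time(events, k$event) + k$onset_latency + 2 * k$width_sigma
    lam <- lam + amp * exp(-(t - center)^2 / (2 * k$width_sigma^2))
  }
  lam
}

#' Simulate one trial's spike train
#'
#' Draws spike times on `[0, t_end)` from an inhomogeneous Poisson process
#' whose intensity is the baseline rate plus the event-locked Gaussian bumps
#' of `kernels`, by thinning against the intensity upper bound (exact, no
#' discretisation).  Negative intensities anywhere on the trial are a
#' parameter error and are rejected before simulation.
#'
#' @param events List with `fp_onset`, `cs_onset`, `cs_offset`, `reward_time`
#'   (seconds).
#' @param value_label `"LR"` or `"SR"`.
#' @param condition `"pre"` or `"inactivation"`.
#' @param t_end Trial length, s.
#' @param baseline Baseline rate, spikes/s.
#' @param kernels List of [response_kernel()] objects.
#' @param seed Substream seed.
#' @return Sorted numeric vector of spike times, s.
#' @export
generate_spike_train <- function(events, value_label, condition, t_end,
                                 baseline, kernels, seed) {
  lam_max <- baseline +
    sum(vapply(kernels, function(k) {
      max(0, .kernel_amp(k, value_label, condition))
    }, numeric(1)))
  if (lam_max <= 0) stop("maximum intensity must be > 0", call. = FALSE)
  # reject parameterisations whose intensity dips below zero
  grid <- seq(0, t_end, by = 0.001)
  lam_grid <- .intensity(grid, baseline, kernels, events, value_label,
                         condition)
  if (any(lam_grid < -1e-9)) {
    stop("intensity is negative on the trial; reduce suppressive amplitudes",
         call. = FALSE)
  }
  .with_seed(seed, {
    n <- stats::rpois(1, lam_max * t_end)
    if (n == 0) {
      numeric(0)
    } else {
      cand <- sort(stats::runif(n, 0, t_end))
      keep <- stats::runif(n) * lam_max <
        .intensity(cand, baseline, kernels, events, value_label, condition)
      cand[keep]
    }
  })
}

#' Simulate one trial's lick times
#'
#' Piecewise-homogeneous Poisson process: `baseline` rate everywhere, raised
#' to `anticipatory` inside the anticipatory window -- `[cs_onset, reward)` on
#' LR trials, `[cs_offset, reward)` on SR trials.  During inactivation the
#' elevation above baseline is multiplied by `inactivation_scale`.
#'
#' @inheritParams generate_spike_train
#' @param baseline,anticipatory Lick rates, /s (>= 0).
#' @param inactivation_scale Scale on the anticipatory elevation during the
#'   inactivation block.
#' @return Sorted numeric vector of lick times, s.
#' @export
generate_licks <- function(events, value_label, condition, t_end,
                           baseline, anticipatory, seed,
                           inactivation_scale = 1) {
  if (baseline < 0 || anticipatory < 0) {
    stop("lick rates must be >= 0", call. = FALSE)
  }
  w0 <- if (value_label == "LR") events$cs_onset else events$cs_offset
  w1 <- min(events$reward_time, t_end)
  rate_in <- baseline + (anticipatory - baseline) *
    (if (condition == "inactivation") inactivation_scale else 1)
  if (rate_in < 0) stop("effective anticipatory rate is negative", call. = FALSE)
  segs <- rbind(c(0, min(w0, t_end), baseline),
                c(min(w0, t_end), w1, rate_in),
                c(w1, t_end, baseline))
  .with_seed(seed, {
    out <- numeric(0)
    for (i in seq_len(nrow(segs))) {
      len <- segs[i, 2] - segs[i, 1]
      if (len <= 0 || segs[i, 3] == 0) next
      n <- stats::rpois(1, segs[i, 3] * len)
      if (n > 0) out <- c(out, stats::runif(n, segs[i, 1], segs[i, 2]))
    }
    sort(out)
  })
}

# Times are stored at 1e-6 s resolution as the double closest to their
# 6-decimal string, so write_session()/read_session() round-trip exactly.
.round6 <- function(x) as.numeric(sprintf("%.6f", x))

#' Simulate saccade-latency records
#'
#' Gaussian latencies truncated at > 50 ms for every condition x direction
#' cell; the inactivation shift is added to the mean only for the affected
#' direction during the inactivation condition.
#'
#' @param model Saccade model list (see [synth_params()]).
#' @param seed Substream seed.
#' @return Data frame with `condition`, `target_direction`, `latency_ms`.
#' @export
generate_saccades <- function(model, seed) {
  .with_seed(seed, {
    rows <- list()
    for (cond in CONDITIONS) {
      for (dir in model$directions) {
        mu <- model$latency_mean +
          if (cond == "inactivation" && dir == model$affected_direction) {
            model$inactivation_shift
          } else 0
        # truncated-normal sampling via inverse CDF, support (50, Inf) ms
        lo <- stats::pnorm(50, mu, model$latency_sd)
        u <- stats::runif(model$n_per_cell, lo, 1)
        lat <- stats::qnorm(u, mu, model$latency_sd)
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, target_direction = dir,
          latency_ms = .round6(round(lat, 3)))
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a full synthetic session
#'
#' Simulates trial timing, per-neuron spike trains, lick times and saccade
#' records under `params`.  LR/SR labels are assigned with equal probability;
#' `cs_onset - fp_onset ~ Uniform(0.7, 1.2)`; the first `n_trials_pre` trials
#' form the pre block.  Identical `(params, seed)` yield identical sessions,
#' and per-trial substreams mean earlier trials are unchanged when trials are
#' added.  All times are rounded to 1 microsecond so sessions round-trip
#' exactly through [write_session()] / [read_session()].
#'
#' @param params A [synth_params()].
#' @param seed Master seed (integer).
#' @param with_spikes,with_licks,with_saccades Disable components that a
#'   given analysis does not need (faster simulation).
#' @return A validated `da_session` carrying `params` as ground truth.
#' @export
generate_session <- function(params, seed, with_spikes = TRUE,
                             with_licks = TRUE, with_saccades = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$n_trials_pre + params$n_trials_inact
  cond <- rep(CONDITIONS, c(params$n_trials_pre, params$n_trials_inact))
  loc_map <- c(LR = "upper", SR = "lower")

  trials <- vector("list", n)
  spikes <- vector("list", n)
  licks <- vector("list", n)
  for (i in seq_len(n)) {
    tim <- .with_seed(.substream(seed, i, 0), {
      list(label = if (stats::runif(1) < 0.5) "LR" else "SR",
           soa = stats::runif(1, 0.7, 1.2))
    })
    fp <- params$fp_onset
    cs_on <- .round6(fp + tim$soa)
    cs_off <- .round6(cs_on + params$cs_duration)
    rw <- if (tim$label == "LR") {
      .round6(cs_on + params$reward_delay_lr)
    } else {
      .round6(cs_off + params$reward_delay_sr)
    }
    t_end <- rw + params$trial_tail
    events <- list(fp_onset = fp, cs_onset = cs_on, cs_offset = cs_off,
                   reward_time = rw)
    trials[[i]] <- data.frame(
      trial_id = i, value_label = tim$label, condition = cond[i],
      cs_location = unname(loc_map[tim$label]),
      fp_onset = fp, cs_onset = cs_on, cs_offset = cs_off, reward_time = rw)
    if (with_spikes && params$n_neurons > 0) {
      per_neuron <- lapply(seq_len(params$n_neurons), function(j) {
        st <- generate_spike_train(events, tim$label, cond[i], t_end,
                                   params$baseline_rate, params$kernels,
                                   .substream(seed, i, 100 + j))
        if (!length(st)) return(NULL)
        data.frame(trial_id = i, neuron_id = sprintf("n%02d", j),
                   spike_time = .round6(st))
      })
      spikes[[i]] <- do.call(rbind, per_neuron)
    }
    if (with_licks) {
      lt <- generate_licks(events, tim$label, cond[i], t_end,
                           params$lick_baseline_rate,
                           params$lick_anticipatory_rate,
                           .substream(seed, i, 1),
                           params$lick_inactivation_scale)
      if (length(lt)) {
        licks[[i]] <- data.frame(trial_id = i, lick_time = .round6(lt))
      }
    }
  }
  saccades <- if (with_saccades) {
    generate_saccades(params$saccade, .substream(seed, 0, 2))
  } else NULL
  da_session(
    trials = do.call(rbind, trials),
    spikes = do.call(rbind, spikes),
    licks = do.call(rbind, licks),
    saccades = saccades,
    config = list(cs_duration = params$cs_duration,
                  fp_onset = params$fp_onset,
                  reward_delay_lr = params$reward_delay_lr,
                  reward_delay_sr = params$reward_delay_sr,
                  stimulus = params$stimulus,
                  master_seed = seed),
    params = c(unclass(params)[setdiff(names(params), c("kernels", "stimulus"))],
               list(kernels = lapply(params$kernels, unclass),
                    master_seed = seed)),
    validate = TRUE)
}
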