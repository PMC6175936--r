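---
title: "Methods: dopamine cue-response and conditioned-behavior analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dopamine cue-response and conditioned-behavior analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dacue)
```

`dacue` analyses Pavlovian visual-conditioning sessions in which midbrain
dopamine (DA) neurons are recorded across a control block (~60 trials) and a
block during reversible muscimol inactivation of the superior colliculus
(SC). This vignette is the package's account of its models and procedures:
what is computed, under which assumptions, with which defaults, and what the
validation on synthetic data does and does not establish.

## Time conventions

All times are seconds from trial start; latencies appear as milliseconds
only in rendered reports. Every analysis window is half-open, `[t0, t1)`:
an event exactly at `t0` is counted, one exactly at `t1` is not, so windows
that tile an interval count each event exactly once. Events (FP onset, CS
onset/offset, reward) are stored absolute within the trial and aligned on
demand (`align_times()`), which is what permits the three standard
alignments (FP, CS, reward) of the same spike train.

## The synthetic-session generator

No sessions of this kind are publicly deposited, so validation rests on a
generator (`generate_session()`) that emulates the statistical structure the
analyses assume. Its defaults are the study conditions and are not meant to
be tuned per analysis:

* **Task timing.** FP onset at 0.5 s; CS onset uniform 0.7–1.2 s after FP;
  CS duration 1.0 s (configurable to 1.7 s, as the two animals differed);
  LR/SR label a fair coin per trial, with a fixed label-to-location mapping.
  Reward is delivered 1.3 s after CS onset on LR trials (the end of the
  anticipatory measurement window) and 0.5 s after CS offset on SR trials;
  the task only constrains SR reward to follow CS offset, so these delays
  are free parameters chosen once.
* **Spikes.** Inhomogeneous Poisson with intensity
  `baseline + Σ_k amp_k(value, condition) · exp(−(t − c_k)² / 2σ_k²)`,
  sampled exactly by thinning against the intensity bound (no grid
  discretisation). The Gaussian bump is the simplest event-locked shape
  whose kernel-smoothed expectation is known analytically. The bump center
  is `event + onset + 2σ_k`, so the `onset` parameter marks where the
  response begins to rise — the quantity the latency detectors estimate.
  Defaults: baseline 5 spikes/s (inside the 1.0–10.0 spikes/s DA screening
  band); FP response 30 spikes/s, value-independent (the FP predicts a trial
  but not its value); CS response onset 85 ms, 50 spikes/s on LR trials and
  10 on SR trials (value coding); no response to predicted reward delivery.
  An optional multiplicative `condition_scale_inactivation` per kernel
  models suppression of cue-evoked drive.
* **Licks.** Piecewise-homogeneous Poisson: baseline 0.5 licks/s
  everywhere, 4 licks/s inside the anticipatory window — CS onset → reward
  on LR trials, CS offset → reward on SR trials, the value-dependent timing
  that makes licking a discrimination readout. Rates are free parameters
  (only figure-level licking data exist to emulate); the defaults give a
  clearly visible effect at ~30 trial pairs. `lick_inactivation_scale`
  scales the anticipatory elevation during the inactivation block (1 =
  behavior intact, 0 = conditioned responding abolished).
* **Saccades.** Per direction and condition, Gaussian latencies (mean
  180 ms, SD 20 ms) truncated at > 50 ms; during inactivation a 53 ms shift
  is added to the affected direction (45°) only.
* **Seeding.** One master seed spawns independent per-trial, per-component
  substreams, so identical `(params, seed)` reproduce a session exactly and
  adding trials never perturbs earlier ones. Generated times are stored at
  1 µs resolution as the double nearest their decimal representation, which
  makes `write_session()`/`read_session()` an exact identity.

What the generator does **not** emulate: refractoriness, bursting and
slow non-stationarities of real DA spike trains; lick-bout structure
(licks are a point process, not detector-crossing bouts); eye traces;
drug-washout dynamics within the inactivation block. Tests passing on this
generator therefore establish internal correctness and calibration of the
estimators under Poisson assumptions, not performance on real data.

## Exact and resampling statistics

The behavioral comparisons run at session counts of 7–9, where asymptotic
p-values are untrustworthy; the package therefore carries exact tests.

* `wilcoxon_signed_rank()` drops zero differences, midranks ties, and for
  n ≤ 25 computes the null distribution of the positive-rank sum over all
  2^n sign assignments by convolving the rank generating function (ties
  exact, cost O(n · Σr) rather than 2^n). The two-sided p is
  `min(1, 2·min(P(W ≤ w), P(W ≥ w)))`. Above n = 25 it switches to the
  normal approximation with tie correction and records the method. A direct
  consequence of exactness: with n unanimous differences the p-value is
  2/2^n — 0.00390625 at n = 9 and 0.015625 at n = 7 — which is why
  session-level discrimination tests at those sample sizes bottom out at
  exactly those values.
* `sign_test()` is the exact two-sided binomial test on positive/negative
  counts, `min(1, 2·min(P(X ≤ n⁻), P(X ≤ n⁺)))`; at fewer than 6 informative
  pairs it cannot reach p < 0.05, which the V detector reports as
  "undetectable" rather than "no onset".
* `two_sample_t()` is Welch's test (via `stats::t.test`): the blocks being
  compared have no reason to share variances.
* `permutation_test()` uses the difference of group means, enumerating all
  relabelings exactly when there are at most 10,000 (`exhaustive = TRUE`,
  exact p), otherwise drawing random relabelings and reporting the add-one
  estimator `p = (1 + #{|T*| ≥ |T_obs|})/(n_perm + 1)`, which cannot return
  zero. Tie comparisons use a relative 1e−12 tolerance so exhaustive
  enumeration is robust to float noise.

## Behavioral analyses

The licking rate of a trial is the lick count in a half-open window divided
by its length. Two window rules are provided: the interval from CS onset to
reward delivery (default — the period over which anticipatory licking can
express value), and the fixed 0.7–1.3 s window after CS onset that is common
to both reward schedules. 0.1 s sub-bin counts are returned for time-course
displays.

LR and SR trials are not naturally paired, so paired tests use *order
pairing*: the i-th LR trial is paired with the i-th SR trial in block order,
surplus trials dropped. This is deterministic, seed-free, and unbiased
because trial labels are exchangeable within a block; a seeded random
pairing would add variance without adding validity. `cr_discrimination()`
applies the exact Wilcoxon to the per-pair (or per-session) LR−SR
differences; `inactivation_effect_licking()` compares the per-pair
differences between blocks twice — an order-paired Wilcoxon and a
permutation test on the difference of block means — because with ~30 pairs
per block neither dominates and their agreement is itself a useful
diagnostic. `saccade_prolongation()` bins directions exactly (targets are
discrete) and reports the mean latency shift and Welch t per direction.

## Spike-train analyses

The spike density function (`spike_density()`) is a Gaussian-kernel rate
estimate on a 1 ms grid, averaged over trials: each spike contributes a
Gaussian of SD σ = 10 ms truncated at ±4σ. A single spike peaks at
`1/(σ√2π)` ≈ 39.9 spikes/s, and the SDF integrates to the mean spike count
per trial up to edge-truncated kernel mass — both asserted in the tests.
σ is a free smoothing choice (the quantity has no canonical bandwidth);
latency conclusions should be checked at σ ∈ {5, 10, 20} ms, and the
detector tests exercise the sensitivity of the L rule to the threshold
multiplier directly.

**'L' latency** (`l_latency()`): baseline mean and SD are computed across
the grid points of the −500–0 ms window of the trial-averaged SDF — the
2 SD rule is a property of the averaged trace, not of across-trial scatter
(an across-trial version would confound rate variability with estimator
noise). L is the first grid time ≥ 0 at which the SDF strictly exceeds
mean + 2 SD; no crossing means no latency (`NA`), never 0, and a constant
trace with zero-SD baseline yields none. No minimum supra-threshold
duration is imposed (strict first crossing); smoothing can pull the
crossing earlier than the true onset by up to roughly one kernel width,
which is the dominant bias seen in the recovery simulations.

**'V' latency** (`v_latency()`): the onset of value differentiation — the
earliest time from which paired LR−SR activity differences are significant
by the exact two-sided sign test (α = 0.05, ties dropped) sustained for
more than 15 ms. The critical design choice is *what activity* enters the
per-time sign test:

* The default is the spike count in a **sliding 15 ms window** starting at
  the test time, stepped at 1 ms. Two test times more than one window width
  apart share no spikes, so under the null hypothesis significance
  decorrelates within 15 ms and a >15 ms run of significant times is
  genuinely improbable: the run-length persistence rule is then a real
  false-positive control. Measured on 200 null sessions (LR and SR
  amplitudes equalised) the detector's session-level false-detection rate
  is below 2% — conservative relative to the nominal 5%, because at
  baseline most pairs tie and the sign test cannot reach significance at
  all. Onsets are resolved at 1 ms; the window-start convention can lead
  the true divergence by at most one window width and in practice the
  detection delay (the window must capture enough divergent mass)
  dominates, so the estimate sits slightly after the true onset.
* A variant computing the sign test at every grid point of
  **kernel-smoothed single-trial traces** (`method = "smoothed"`) is kept
  for sensitivity analyses. It is *not* calibrated: smoothing correlates
  neighbouring 1 ms bins over several kernel widths, chance runs far longer
  than 15 ms are common, and on null sessions the majority of runs produce
  a spurious onset. It exists to show what the persistence rule does and
  does not buy; its detections should not be reported as onsets.

Both detectors are validated by parameter recovery: across synthetic
sessions with ground-truth CS onsets of 70, 85 and 100 ms and an LR
response of ten times baseline, the median |L − truth| is within 15 ms,
the median |V − truth| within 25 ms, and V ≥ L in the overwhelming
majority of sessions where both detect — value differentiation cannot
precede response detectability when the SR response is non-negative, which
mirrors the L < V ordering such experiments report. Monotonicity
properties (longer persistence or smaller α never yield an earlier onset;
a higher SD multiplier never yields an earlier L) are property-tested.

Response magnitudes (`window_rate()`) are per-trial counts over
100–300 ms after FP or CS onset and 150–350 ms after reward, divided by
the window length; `pre_post_comparison()` tests each neuron (Welch t and
permutation) and the population (exact Wilcoxon on per-neuron mean
differences, requiring at least 5 neurons), with no multiplicity
correction — the convention of the analyses it mirrors, so its per-neuron
significance flags should be read accordingly.

`screen_da_neuron()` encodes the four DA screening criteria as a strict
conjunction: SNc/VTA location, phasic response to unpredicted reward,
baseline 1.0–10.0 spikes/s (fast-firing SNr neurons exceed 40 spikes/s),
and a spike width exceeding 1.5× the median of nearby SNr reference
widths. "Clearly longer" is not quantified anywhere authoritative; 1.5× is
the package's operationalisation, configurable via `width_ratio`, and an
empty SNr reference list makes the width criterion indeterminate and the
unit conservatively rejected.

## Numerical and degenerate-input choices

* Exact-test tie handling: midranks (Wilcoxon), dropped ties (sign test),
  zero differences dropped before ranking; an all-zero difference vector is
  an error, not p = 1.
* Latency grids: `seq(t0, t1)` half-open with a half-step guard against
  float drift; run lengths compare against `floor(persistence/step + 1e−9) + 1`
  so "more than 15 ms" is exact at 1 ms resolution.
* Absent onsets are `NA` with a status field; reports render them as
  `"none"` — an absent latency is categorically different from a 0 ms one.
* Sessions round-trip exactly through CSV (6-decimal times, sorted rows,
  fixed field order), making written sessions byte-stable and diffable.

## Problem sizes used in validation

The shipped tests run the oracle-equivalence checks at 500 random vectors
(n ≤ 12, full 2^n enumeration) and all sign-test splits to n = 30;
calibration at 400 permutation-test null runs and 200 null sessions for the
V detector; recovery at 300 sessions (100 per ground-truth onset); and the
end-to-end behavioral property at 200 seeds of 120-trial sessions. These
sizes give binomial standard errors of 1–2 percentage points on the
calibration rates while keeping the default suite in the low minutes on a
single core.

## Known limitations

* The generator's Poisson assumption understates spike-count dispersion of
  real DA neurons; calibration rates on real data may differ.
* Order pairing makes paired tests deterministic but discards surplus
  trials from the larger class; at a 50/50 label split the loss is small.
* The V detector's conservatism (false-positive rate well below α) trades
  sensitivity for trustworthy onsets; weak value coding near threshold will
  often return "none" — which is the intended behavior, not a failure to
  run.
* `pre_post_comparison()` applies no multiple-testing correction across
  neurons or events, by design; treat per-neuron flags as descriptive.
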