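# Pair the i-th LR trial with the i-th SR trial in block order, dropping the
# surplus. Deterministic and unbiased with respect to trial content.
.order_pairs <- function(idx_lr, idx_sr) {
  m <- min(length(idx_lr), length(idx_sr))
  if (m == 0) return(NULL)
  cbind(lr = idx_lr[seq_len(m)], sr = idx_sr[seq_len(m)])
}

#' Conditioned-licking rate for one trial
#'
#' Counts licks in a half-open window anchored at CS onset and converts to a
#' rate in licks/s.  Two window rules are provided: `"cs_to_reward"`, the
#' interval from CS onset to reward delivery, and `"fixed"`, a fixed interval
#' after CS onset (default 0.7--1.3 s, the anticipatory period shared by both
#' reward schedules).  Counts per `bin`-wide sub-bin are returned for
#' time-course plots.
#'
#' @param licks Sorted lick times for one trial, s (absolute trial time).
#' @param events Event list with `cs_onset` and `reward_time`.
#' @param window_rule `"cs_to_reward"` or `"fixed"`.
#' @param fixed_window Length-2 window after CS onset used when
#'   `window_rule = "fixed"`, s.
#' @param bin Sub-bin width for the binned counts, s.
#' @return List with `rate` (licks/s), `n_licks`, `window` (absolute, s),
#'   `bin_counts` and `bin_starts` (window-relative, s).
#' @export
licking_rate <- function(licks, events,
                         window_rule = c("cs_to_reward", "fixed"),
                         fixed_window = c(0.7, 1.3), bin = 0.1) {
  window_rule <- match.arg(window_rule)
  w <- if (window_rule == "cs_to_reward") {
    c(events$cs_onset, events$reward_time)
  } else {
    events$cs_onset + fixed_window
  }
  if (w[2] <= w[1]) stop("empty licking window", call. = FALSE)
  inside <- align_times(licks, w[1], c(0, w[2] - w[1]))
  len <- w[2] - w[1]
  starts <- seq(0, len - 1e-12, by = bin)
  counts <- vapply(starts, function(s) {
    sum(inside >= s & inside < min(s + bin, len))
  }, numeric(1))
  list(rate = length(inside) / len, n_licks = length(inside), window = w,
       bin_counts = counts, bin_starts = starts)
}

# Per-trial licking rates for a session subset; returns the trials table with
# a `rate` column appended.
.session_lick_rates <- function(session, window_rule, condition = NULL) {
  tr <- session$trials
  if (!is.null(condition)) tr <- tr[tr$condition %in% condition, , drop = FALSE]
  by_trial <- split(session$licks$lick_time, session$licks$trial_id)
  tr$rate <- vapply(seq_len(nrow(tr)), function(i) {
    lt <- by_trial[[as.character(tr$trial_id[i])]]
    if (is.null(lt)) lt <- numeric(0)
    licking_rate(lt, as.list(tr[i, c("cs_onset", "reward_time")]),
                 window_rule = window_rule)$rate
  }, numeric(1))
  tr
}

#' LR/SR discrimination of the conditioned licking response
#'
#' Tests whether anticipatory licking discriminates the large-reward from the
#' small-reward CS with a paired exact Wilcoxon signed-rank test on per-unit
#' LR-SR rate differences.
#'
#' Input is either a data frame with columns `rate_lr` and `rate_sr` (one row
#' per unit, e.g. per session means across an experiment) or a `da_session`,
#' in which case the i-th LR trial is paired with the i-th SR trial in block
#' order and per-pair differences are used.
#'
#' @param x Data frame of rate pairs or a `da_session`.
#' @param window_rule Licking window rule (see [licking_rate()]); session
#'   input only.
#' @param condition Conditions to include for session input (default both).
#' @return List of class `cr_summary`: `mean_rate_lr`, `mean_rate_sr`,
#'   `differences`, `test` (a `da_test_result`), `n_pairs`.
#' @export
cr_discrimination <- function(x, window_rule = c("cs_to_reward", "fixed"),
                              condition = c("pre", "inactivation")) {
  window_rule <- match.arg(window_rule)
  if (inherits(x, "da_session")) {
    tr <- .session_lick_rates(x, window_rule, condition)
    pairs <- .order_pairs(which(tr$value_label == "LR"),
                          which(tr$value_label == "SR"))
    if (is.null(pairs)) stop("need at least one LR and one SR trial",
                             call. = FALSE)
    rate_lr <- tr$rate[pairs[, "lr"]]
    rate_sr <- tr$rate[pairs[, "sr"]]
  } else {
    if (!all(c("rate_lr", "rate_sr") %in% names(x))) {
      stop("rate-pair input needs columns rate_lr and rate_sr", call. = FALSE)
    }
    rate_lr <- x$rate_lr
    rate_sr <- x$rate_sr
  }
  d <- rate_lr - rate_sr
  structure(list(
    mean_rate_lr = mean(rate_lr), mean_rate_sr = mean(rate_sr),
    differences = d, n_pairs = length(d),
    test = wilcoxon_signed_rank(d)
  ), class = "cr_summary")
}

#' Effect of SC inactivation on conditioned licking
#'
#' Compares the LR-SR licking-rate difference between the pre-injection block
#' and the inactivation block.  Within each block, LR and SR trials are
#' paired in block order and per-pair differences computed; blocks are then
#' compared twice: by an exact Wilcoxon signed-rank test on order-paired
#' (inactivation - pre) differences-of-differences, and by a permutation test
#' on the difference of block means with labels shuffled between blocks.
#'
#' @param session A `da_session` containing both blocks.
#' @param window_rule Licking window rule (see [licking_rate()]).
#' @param n_perm Permutation count.
#' @param seed Seed for the permutation test.
#' @return List with `diff_pre`, `diff_inact` (per-pair LR-SR differences),
#'   `wilcoxon` (`da_test_result`, or `NULL` with `wilcoxon_note` when
#'   degenerate), and `permutation` (`da_perm_result`).
#' @export
inactivation_effect_licking <- function(session,
                                        window_rule = c("cs_to_reward", "fixed"),
                                        n_perm = 10000, seed = 1) {
  window_rule <- match.arg(window_rule)
  block_diffs <- function(cond) {
    tr <- .session_lick_rates(session, window_rule, cond)
    pairs <- .order_pairs(which(tr$value_label == "LR"),
                          which(tr$value_label == "SR"))
    if (is.null(pairs) || nrow(pairs) < 2) {
      stop("block '", cond, "' has fewer than 2 LR/SR trial pairs",
           call. = FALSE)
    }
    tr$rate[pairs[, "lr"]] - tr$rate[pairs[, "sr"]]
  }
  d_pre <- block_diffs("pre")
  d_in <- block_diffs("inactivation")
  m <- min(length(d_pre), length(d_in))
  wil <- tryCatch(wilcoxon_signed_rank(d_in[seq_len(m)] - d_pre[seq_len(m)]),
                  error = function(e) NULL)
  list(
    diff_pre = d_pre, diff_inact = d_in,
    wilcoxon = wil,
    wilcoxon_note = if (is.null(wil)) "all paired differences zero" else NULL,
    permutation = permutation_test(d_pre, d_in, n_perm = n_perm, seed = seed)
  )
}

#' Saccade-latency prolongation per target direction
#'
#' For each target direction with at least `min_n` records in both
#' conditions, reports the change in mean latency (inactivation - pre, ms)
#' and a Welch two-sample t-test.  Directions lacking a condition are skipped
#' with a warning.  Effective SC inactivation prolongs latencies only for
#' targets in the muscimol-affected visual field.
#'
#' @param records Data frame with `condition`, `target_direction`,
#'   `latency_ms` (e.g. `session$saccades`).
#' @param min_n Minimum records per condition per direction.
#' @return Data frame, one row per analysed direction (sorted):
#'   `direction`, `delta_ms`, `t_statistic`, `p_two_sided`, `n_pre`,
#'   `n_inact`.
#' @export
saccade_prolongation <- function(records, min_n = 2) {
  dirs <- sort(unique(records$target_direction))
  rows <- lapply(dirs, function(dd) {
    pre <- records$latency_ms[records$target_direction == dd &
                                records$condition == "pre"]
    post <- records$latency_ms[records$target_direction == dd &
                                 records$condition == "inactivation"]
    if (length(pre) < min_n || length(post) < min_n) {
      warning(sprintf("direction %g skipped: needs >= %d records per condition",
                      dd, min_n))
      return(NULL)
    }
    tt <- two_sample_t(post, pre)
    data.frame(direction = dd, delta_ms = mean(post) - mean(pre),
               t_statistic = tt$statistic, p_two_sided = tt$p_two_sided,
               n_pre = length(pre), n_inact = length(post))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no direction has enough records in both conditions", call. = FALSE)
  }
  out
}
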