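VALUE_LABELS <- c("LR", "SR")
CONDITIONS <- c("pre", "inactivation")
CS_LOCATIONS <- c("upper", "lower")
ALIGN_EVENTS <- c("FP", "CS", "RW")

#' Construct a recording session
#'
#' A session bundles the trial table, spike times, lick times, saccade records
#' and configuration into one object mirroring the on-disk CSV/JSON layout.
#' All times are in seconds from trial start.
#'
#' @param trials Data frame with columns `trial_id`, `value_label` (`"LR"` or
#'   `"SR"`), `condition` (`"pre"` or `"inactivation"`), `cs_location`
#'   (`"upper"` or `"lower"`), `fp_onset`, `cs_onset`, `cs_offset`,
#'   `reward_time`.
#' @param spikes Data frame with columns `trial_id`, `neuron_id`,
#'   `spike_time`; may have zero rows.
#' @param licks Data frame with columns `trial_id`, `lick_time`.
#' @param saccades Data frame with columns `condition`, `target_direction`
#'   (degrees), `latency_ms` (from target onset, > 0).
#' @param config List of timing constants and the [stimulus_spec()]; must at
#'   least contain `cs_duration` (seconds).
#' @param params Optional [synth_params()] the session was generated from
#'   (ground truth for parameter-recovery tests); `NULL` for real data.
#' @param validate Run [validate_session()] before returning?
#' @return An object of class `da_session` with elements `trials`, `spikes`,
#'   `licks`, `saccades`, `config`, `neuron_ids`, `block_start` (1-based index
#'   of the first inactivation trial, `NA` if none) and `params`.
#' @seealso [read_session()], [write_session()], [generate_session()]
#' @export
da_session <- function(trials, spikes = NULL, licks = NULL, saccades = NULL,
                       config = list(cs_duration = 1.0,
                                     stimulus = stimulus_spec()),
                       params = NULL, validate = TRUE) {
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  if (is.null(spikes)) {
    spikes <- empty(c("trial_id", "neuron_id", "spike_time"))
  }
  if (is.null(licks)) licks <- empty(c("trial_id", "lick_time"))
  if (is.null(saccades)) {
    saccades <- empty(c("condition", "target_direction", "latency_ms"))
  }
  inact <- which(trials$condition == "inactivation")
  s <- structure(list(
    trials = trials,
    spikes = spikes,
    licks = licks,
    saccades = saccades,
    config = config,
    neuron_ids = sort(unique(spikes$neuron_id)),
    block_start = if (length(inact)) min(inact) else NA_integer_,
    params = params
  ), class = "da_session")
  if (validate) validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks event ordering (`fp_onset < cs_onset < cs_offset`,
#' `reward_time > cs_onset`), label domains, ascending spike and lick times,
#' non-negative times, a constant value-label-to-location mapping, and that
#' the control block precedes the inactivation block.  Violations raise an
#' error naming the offending trial.
#'
#' @param session A `da_session`.
#' @return The session, invisibly, if valid.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  need <- c("trial_id", "value_label", "condition", "cs_location",
            "fp_onset", "cs_onset", "cs_offset", "reward_time")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop("trials table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tr$trial_id)) {
    stop("duplicate trial_id in trials table", call. = FALSE)
  }
  bad_label <- !tr$value_label %in% VALUE_LABELS
  if (any(bad_label)) {
    stop("unknown value_label in trial ", tr$trial_id[which(bad_label)[1]],
         call. = FALSE)
  }
  bad_cond <- !tr$condition %in% CONDITIONS
  if (any(bad_cond)) {
    stop("unknown condition in trial ", tr$trial_id[which(bad_cond)[1]],
         call. = FALSE)
  }
  bad_loc <- !tr$cs_location %in% CS_LOCATIONS
  if (any(bad_loc)) {
    stop("unknown cs_location in trial ", tr$trial_id[which(bad_loc)[1]],
         call. = FALSE)
  }
  ev <- c("fp_onset", "cs_onset", "cs_offset", "reward_time")
  for (col in ev) {
    if (any(tr[[col]] < 0)) {
      stop(col, " < 0 in trial ", tr$trial_id[which(tr[[col]] < 0)[1]],
           call. = FALSE)
    }
  }
  bad <- !(tr$fp_onset < tr$cs_onset & tr$cs_onset < tr$cs_offset)
  if (any(bad)) {
    stop("event order fp_onset < cs_onset < cs_offset violated in trial ",
         tr$trial_id[which(bad)[1]], call. = FALSE)
  }
  bad <- !(tr$reward_time > tr$cs_onset)
  if (any(bad)) {
    stop("reward_time must exceed cs_onset in trial ",
         tr$trial_id[which(bad)[1]], call. = FALSE)
  }
  # one CS location per value label throughout the session
  map <- unique(tr[, c("value_label", "cs_location")])
  if (anyDuplicated(map$value_label)) {
    stop("value_label to cs_location mapping is not constant within session",
         call. = FALSE)
  }
  # blocks must be contiguous: pre first, inactivation after
  if (!is.na(session$block_start)) {
    cond <- tr$condition
    if (any(cond[seq_len(session$block_start - 1)] != "pre") ||
        any(cond[session$block_start:nrow(tr)] != "inactivation")) {
      stop("pre block must precede inactivation block contiguously",
           call. = FALSE)
    }
  }
  for (nm in c("spikes", "licks")) {
    df <- session[[nm]]
    tcol <- if (nm == "spikes") "spike_time" else "lick_time"
    if (nrow(df)) {
      if (any(df[[tcol]] < 0)) {
        stop(nm, " contain negative times (trial ",
             df$trial_id[which(df[[tcol]] < 0)[1]], ")", call. = FALSE)
      }
      orphan <- !df$trial_id %in% tr$trial_id
      if (any(orphan)) {
        stop(nm, " reference unknown trial_id ",
             df$trial_id[which(orphan)[1]], call. = FALSE)
      }
      key <- if (nm == "spikes") paste(df$trial_id, df$neuron_id) else df$trial_id
      unsorted <- unlist(lapply(split(df[[tcol]], key), is.unsorted),
                         use.names = TRUE)
      if (any(unsorted)) {
        stop(nm, " times not ascending within trial (key ",
             names(unsorted)[which(unsorted)[1]], ")", call. = FALSE)
      }
    }
  }
  if (nrow(session$saccades) && any(session$saccades$latency_ms <= 0)) {
    stop("saccade latencies must be > 0", call. = FALSE)
  }
  invisible(session)
}

#' Align event times to a reference event within a window
#'
#' Returns `t - event` for every `t` whose aligned time falls in the half-open
#' window `[t0, t1)`.  Input must be sorted ascending; output is sorted.
#'
#' @param times Sorted numeric vector of times, seconds.
#' @param event Reference event time, seconds.
#' @param window Length-2 numeric `c(t0, t1)` with `t0 < t1`, seconds relative
#'   to `event`.
#' @return Numeric vector of event-relative times within the window.
#' @examples
#' align_times(c(1.0, 1.5), event = 1.0, window = c(0, 1))  # 0.0 0.5
#' @export
align_times <- function(times, event, window) {
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("`window` must be c(t0, t1) with t0 < t1", call. = FALSE)
  }
  if (is.unsorted(times)) stop("`times` must be sorted ascending", call. = FALSE)
  rel <- times - event
  rel[rel >= window[1] & rel < window[2]]
}

# Aligned spike times per trial for one neuron, optionally filtered by
# condition / value label. Returns a list (one sorted numeric vector per
# trial, trials in table order).
#' Extract per-trial aligned spike trains
#'
#' Convenience accessor: for each selected trial, aligns one neuron's spikes
#' to the chosen event (`"FP"`, `"CS"` or `"RW"`) and keeps times in `span`.
#'
#' @param session A `da_session`.
#' @param neuron_id Neuron identifier present in `session$spikes`.
#' @param event Alignment event: FP onset, CS onset, or reward delivery.
#' @param span Half-open window relative to the event, seconds.
#' @param condition Optional filter: `"pre"` or `"inactivation"`.
#' @param value_label Optional filter: `"LR"` or `"SR"`.
#' @return List of numeric vectors, one per trial, in block order.
#' @export
aligned_spikes <- function(session, neuron_id, event = c("CS", "FP", "RW"),
                           span = c(-0.5, 1.0),
                           condition = NULL, value_label = NULL) {
  event <- match.arg(event)
  tr <- session$trials
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(condition)) keep <- keep & tr$condition %in% condition
  if (!is.null(value_label)) keep <- keep & tr$value_label %in% value_label
  tr <- tr[keep, , drop = FALSE]
  evcol <- switch(event, FP = "fp_onset", CS = "cs_onset", RW = "reward_time")
  sp <- session$spikes[session$spikes$neuron_id == neuron_id, , drop = FALSE]
  by_trial <- split(sp$spike_time, sp$trial_id)
  lapply(seq_len(nrow(tr)), function(i) {
    tt <- by_trial[[as.character(tr$trial_id[i])]]
    if (is.null(tt)) tt <- numeric(0)
    align_times(tt, tr[[evcol]][i], span)
  })
}

#' Per-trial aligned lick times
#'
#' @inheritParams aligned_spikes
#' @return List of numeric vectors of lick times relative to `event`.
#' @export
aligned_licks <- function(session, event = c("CS", "FP", "RW"),
                          span = c(-0.5, 3.0),
                          condition = NULL, value_label = NULL) {
  event <- match.arg(event)
  tr <- session$trials
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(condition)) keep <- keep & tr$condition %in% condition
  if (!is.null(value_label)) keep <- keep & tr$value_label %in% value_label
  tr <- tr[keep, , drop = FALSE]
  evcol <- switch(event, FP = "fp_onset", CS = "cs_onset", RW = "reward_time")
  by_trial <- split(session$licks$lick_time, session$licks$trial_id)
  lapply(seq_len(nrow(tr)), function(i) {
    tt <- by_trial[[as.character(tr$trial_id[i])]]
    if (is.null(tt)) tt <- numeric(0)
    align_times(tt, tr[[evcol]][i], span)
  })
}

#' @export
print.da_session <- function(x, ...) {
  cat(sprintf(
    "da_session: %d trials (%d pre, %d inactivation), %d neurons, %d spikes, %d licks, %d saccades\n",
    nrow(x$trials), sum(x$trials$condition == "pre"),
    sum(x$trials$condition == "inactivation"),
    length(x$neuron_ids), nrow(x$spikes), nrow(x$licks), nrow(x$saccades)))
  invisible(x)
}
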