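#' Analysis configuration
#'
#' Collects every tunable analysis parameter with its conventional default:
#' 10 ms SDF kernel, 1 ms grid, `[-0.5, 1.0)` s analysis span, `[-0.5, 0)` s
#' baseline, response windows 0.100--0.300 s after FP and CS onset and
#' 0.150--0.350 s after reward, alpha 0.05, 15 ms persistence for the V
#' detector, order pairing, 10,000 permutations.  Every report embeds the
#' config it was produced with.
#'
#' @param kernel_sigma SDF kernel SD, s.
#' @param step Analysis grid step, s.
#' @param span Event-aligned analysis span, s.
#' @param baseline_window Baseline window for the 'L' rule, s.
#' @param window_fp,window_cs,window_rw Response-magnitude windows, s.
#' @param alpha Significance level.
#' @param persistence V-detector persistence, s.
#' @param v_method V-detector trace construction (see [v_latency()]).
#' @param v_bin_width V-detector count-window width, s.
#' @param n_perm Permutation count.
#' @param lick_window_rule `"cs_to_reward"` or `"fixed"` (see
#'   [licking_rate()]).
#' @param pairing Trial pairing mode; only `"order"` is implemented.
#' @param seed Seed for all resampling stages.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(kernel_sigma = 0.010, step = 0.001,
                            span = c(-0.5, 1.0),
                            baseline_window = c(-0.5, 0),
                            window_fp = c(0.100, 0.300),
                            window_cs = c(0.100, 0.300),
                            window_rw = c(0.150, 0.350),
                            alpha = 0.05, persistence = 0.015,
                            v_method = c("sliding", "smoothed"),
                            v_bin_width = 0.015,
                            n_perm = 10000,
                            lick_window_rule = c("cs_to_reward", "fixed"),
                            pairing = "order", seed = 1) {
  structure(list(
    kernel_sigma = kernel_sigma, step = step, span = span,
    baseline_window = baseline_window,
    window_fp = window_fp, window_cs = window_cs, window_rw = window_rw,
    alpha = alpha, persistence = persistence,
    v_method = match.arg(v_method), v_bin_width = v_bin_width,
    n_perm = n_perm,
    lick_window_rule = match.arg(lick_window_rule),
    pairing = match.arg(pairing, "order"), seed = seed
  ), class = "analysis_config")
}

# Run one pipeline stage; on error, record the message in `env$errors` under
# `name` and return NULL so later stages still run.
.stage <- function(env, name, expr) {
  tryCatch(expr, error = function(e) {
    env$errors[[name]] <- conditionMessage(e)
    NULL
  })
}

#' Run the full analysis pipeline on one session
#'
#' Executes, in order: conditioned-licking discrimination
#' ([cr_discrimination()]), the inactivation effect on licking
#' ([inactivation_effect_licking()]), saccade-latency prolongation
#' ([saccade_prolongation()]), per-neuron windowed response magnitudes and
#' pre/post comparison ([window_rate()], [pre_post_comparison()]), and the
#' 'L' and 'V' CS-response latencies per condition ([l_latency()],
#' [v_latency()]).  A stage failure is recorded under `errors` and the
#' remaining stages still run.  Identical inputs and config (including seed)
#' reproduce an identical report.
#'
#' @param session A `da_session`.
#' @param config An [analysis_config()].
#' @return List of class `da_report` with elements `config`, `provenance`,
#'   `behavior`, `saccades`, `neurons`, `latency`, `errors`.
#' @export
run_full_pipeline <- function(session, config = analysis_config()) {
  st <- environment()   # holds `errors`, written by .stage()
  errors <- list()
  both_blocks <- !is.na(session$block_start)

  cr <- .stage(st, "cr_discrimination",
               cr_discrimination(session,
                                 window_rule = config$lick_window_rule))
  inact_lick <- if (both_blocks) {
    .stage(st, "inactivation_effect_licking",
           inactivation_effect_licking(session,
                                       window_rule = config$lick_window_rule,
                                       n_perm = config$n_perm,
                                       seed = config$seed))
  } else NULL
  sacc <- if (nrow(session$saccades)) {
    .stage(st, "saccade_prolongation",
           saccade_prolongation(session$saccades))
  } else NULL

  neuron_windows <- list()
  rates_pre <- list()
  rates_in <- list()
  for (nid in session$neuron_ids) {
    per_event <- list()
    for (ev in ALIGN_EVENTS) {
      win <- switch(ev, FP = config$window_fp, CS = config$window_cs,
                    RW = config$window_rw)
      # CS responses are value coded: magnitude windows use LR trials only
      vl <- if (ev == "CS") "LR" else NULL
      for (cond in intersect(unique(session$trials$condition), CONDITIONS)) {
        sp <- aligned_spikes(session, nid, event = ev, span = config$span,
                             condition = cond, value_label = vl)
        wr <- window_rate(sp, window = win, event = ev)
        per_event[[paste(ev, cond, sep = "_")]] <- wr
        if (ev == "CS" && cond == "pre") rates_pre[[nid]] <- wr$rates
        if (ev == "CS" && cond == "inactivation") rates_in[[nid]] <- wr$rates
      }
    }
    neuron_windows[[nid]] <- per_event
  }
  pre_post <- if (both_blocks && length(rates_pre) && length(rates_in)) {
    .stage(st, "pre_post_comparison",
           pre_post_comparison(rates_pre, rates_in, n_perm = config$n_perm,
                               seed = config$seed))
  } else NULL

  latency <- list()
  for (nid in session$neuron_ids) {
    for (cond in intersect(unique(session$trials$condition), CONDITIONS)) {
      lr <- aligned_spikes(session, nid, "CS", span = config$span,
                           condition = cond, value_label = "LR")
      sr <- aligned_spikes(session, nid, "CS", span = config$span,
                           condition = cond, value_label = "SR")
      key <- paste(nid, cond, sep = "_")
      latency[[key]] <- .stage(st, paste0("latency_", key), {
        s <- spike_density(lr, kernel_sigma = config$kernel_sigma,
                           span = config$span, step = config$step,
                           align_event = "CS")
        bl <- baseline_stats(s, config$baseline_window)
        list(neuron_id = nid, condition = cond,
             L = l_latency(s, bl),
             V = v_latency(lr, sr, method = config$v_method,
                           bin_width = config$v_bin_width,
                           kernel_sigma = config$kernel_sigma,
                           span = config$span, step = config$step,
                           alpha = config$alpha,
                           persistence = config$persistence),
             baseline = bl)
      })
    }
  }

  structure(list(
    config = unclass(config),
    provenance = list(package = "dacue",
                      version = as.character(utils::packageVersion("dacue")),
                      n_trials = nrow(session$trials),
                      neuron_ids = session$neuron_ids,
                      seed = config$seed),
    behavior = list(cr_discrimination = cr,
                    inactivation_effect_licking = inact_lick),
    saccades = sacc,
    neurons = list(windows = neuron_windows, pre_post = pre_post),
    latency = latency,
    errors = errors
  ), class = "da_report")
}

.fmt_ms <- function(x) {
  if (is.null(x) || is.na(x)) "none" else sprintf("%.0f", round(x * 1000))
}

#' Render a pipeline report
#'
#' Writes a [run_full_pipeline()] report as JSON (machine-readable,
#' round-trippable) or markdown (per-neuron pre/post response table with
#' significance flags, and an L/V latency table in ms; undetected onsets are
#' rendered as `"none"`, never 0).
#'
#' @param report A `da_report`.
#' @param path Output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", force = TRUE,
                         pretty = TRUE)
    return(invisible(path))
  }
  lines <- c("# Session analysis report", "",
             sprintf("dacue %s; seed %s; alpha %g",
                     report$provenance$version, report$provenance$seed,
                     report$config$alpha), "")
  cr <- report$behavior$cr_discrimination
  if (!is.null(cr)) {
    lines <- c(lines, "## Conditioned licking", "",
               sprintf("Mean rate LR %.2f licks/s vs SR %.2f licks/s; Wilcoxon signed-rank p = %.4g (n = %d pairs).",
                       cr$mean_rate_lr, cr$mean_rate_sr,
                       cr$test$p_two_sided, cr$n_pairs), "")
  }
  il <- report$behavior$inactivation_effect_licking
  if (!is.null(il)) {
    wp <- if (is.null(il$wilcoxon)) "n/a (degenerate)" else
      sprintf("%.4g", il$wilcoxon$p_two_sided)
    lines <- c(lines, "## Licking: pre vs inactivation", "",
               sprintf("Wilcoxon p = %s; permutation p = %.4g (%d relabelings).",
                       wp, il$permutation$p_two_sided,
                       il$permutation$n_permutations), "")
  }
  if (!is.null(report$saccades)) {
    lines <- c(lines, "## Saccade latency prolongation", "",
               "| direction (deg) | delta (ms) | p |", "|---|---|---|",
               sprintf("| %g | %.1f | %.4g |", report$saccades$direction,
                       report$saccades$delta_ms, report$saccades$p_two_sided),
               "")
  }
  pp <- report$neurons$pre_post
  if (!is.null(pp)) {
    sig <- ifelse(!is.na(pp$per_neuron$t_p) &
                    pp$per_neuron$t_p < report$config$alpha, "*", "")
    lines <- c(lines, "## CS response magnitude: pre vs inactivation", "",
               "| neuron | pre (spikes/s) | inact (spikes/s) | t p | perm p | sig |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %.2f | %.2f | %.4g | %.4g | %s |",
                       pp$per_neuron$neuron_id, pp$per_neuron$mean_pre,
                       pp$per_neuron$mean_inact, pp$per_neuron$t_p,
                       pp$per_neuron$perm_p, sig), "")
    if (!is.null(pp$population)) {
      lines <- c(lines,
                 sprintf("Population Wilcoxon signed-rank p = %.4g (n = %d neurons).",
                         pp$population$p_two_sided,
                         pp$population$n_effective), "")
    }
  }
  if (length(report$latency)) {
    rows <- vapply(report$latency, function(x) {
      sprintf("| %s | %s | %s | %s |", x$neuron_id, x$condition,
              .fmt_ms(x$L$latency), .fmt_ms(x$V$latency))
    }, character(1))
    lines <- c(lines, "## CS response latencies", "",
               "| neuron | condition | L (ms) | V (ms) |", "|---|---|---|---|",
               rows, "")
  }
  if (length(report$errors)) {
    lines <- c(lines, "## Stage errors", "",
               sprintf("- %s: %s", names(report$errors),
                       unlist(report$errors)), "")
  }
  writeLines(lines, path)
  invisible(path)
}
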