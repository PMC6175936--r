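# On-disk layout (all UTF-8, '.' decimal, times in seconds):
#   trials.csv   trial_id,value_label,condition,cs_location,fp_onset,cs_onset,cs_offset,reward_time
#   spikes.csv   trial_id,neuron_id,spike_time
#   licks.csv    trial_id,lick_time
#   saccades.csv condition,target_direction,latency_ms
#   session.json stimulus spec, timing constants, block boundary, generator params
# Times are written with 6 decimals, so sessions whose times are multiples of
# 1e-6 s round-trip exactly; generate_session() rounds to that resolution.

.fmt <- function(x) sprintf("%.6f", x)

.write_csv_stable <- function(df, path, num_cols) {
  for (col in num_cols) df[[col]] <- .fmt(df[[col]])
  lines <- paste(names(df), collapse = ",")
  if (nrow(df)) {
    body <- do.call(paste, c(unname(as.list(df)), sep = ","))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

#' Write a session to a directory
#'
#' Writes `trials.csv`, `spikes.csv`, `licks.csv`, `saccades.csv` and
#' `session.json` under `dir`.  Output is deterministic and byte-stable for a
#' fixed session: rows are sorted, times formatted with 6 decimals.
#'
#' @param session A validated `da_session`.
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  validate_session(session)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tr <- session$trials[order(session$trials$trial_id), , drop = FALSE]
  .write_csv_stable(tr, file.path(dir, "trials.csv"),
                    c("fp_onset", "cs_onset", "cs_offset", "reward_time"))
  sp <- session$spikes
  sp <- sp[order(sp$trial_id, sp$neuron_id, sp$spike_time), , drop = FALSE]
  .write_csv_stable(sp, file.path(dir, "spikes.csv"), "spike_time")
  lk <- session$licks[order(session$licks$trial_id, session$licks$lick_time),
                      , drop = FALSE]
  .write_csv_stable(lk, file.path(dir, "licks.csv"), "lick_time")
  sc <- session$saccades
  sc <- sc[order(sc$condition, sc$target_direction, sc$latency_ms), ,
           drop = FALSE]
  .write_csv_stable(sc, file.path(dir, "saccades.csv"),
                    c("target_direction", "latency_ms"))
  meta <- list(
    config = session$config,
    block_start = session$block_start,
    neuron_ids = session$neuron_ids,
    params = session$params
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  invisible(dir)
}

.read_csv <- function(path, classes) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = classes, stringsAsFactors = FALSE)
  miss <- setdiff(names(classes), names(df))
  if (length(miss)) {
    stop(basename(path), " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df[, names(classes), drop = FALSE]
}

#' Read a session from a directory
#'
#' Reads the file set written by [write_session()] and validates all session
#' invariants; violations raise an error naming the offending trial.
#'
#' @param dir Directory containing the session files.
#' @return A validated `da_session`.
#' @export
read_session <- function(dir) {
  trials <- .read_csv(file.path(dir, "trials.csv"), c(
    trial_id = "integer", value_label = "character",
    condition = "character", cs_location = "character",
    fp_onset = "numeric", cs_onset = "numeric", cs_offset = "numeric",
    reward_time = "numeric"))
  spikes <- .read_csv(file.path(dir, "spikes.csv"), c(
    trial_id = "integer", neuron_id = "character", spike_time = "numeric"))
  licks <- .read_csv(file.path(dir, "licks.csv"), c(
    trial_id = "integer", lick_time = "numeric"))
  saccades <- .read_csv(file.path(dir, "saccades.csv"), c(
    condition = "character", target_direction = "numeric",
    latency_ms = "numeric"))
  meta_path <- file.path(dir, "session.json")
  config <- list(cs_duration = 1.0, stimulus = stimulus_spec())
  params <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$config)) {
      config <- meta$config
      if (!is.null(config$stimulus)) {
        config$stimulus <- do.call(stimulus_spec, c(
          config$stimulus[c("background_luminance", "weber_contrast",
                            "michelson_contrast", "size_deg",
                            "eccentricity_deg", "direction_deg")]))
      }
    }
    if (!is.null(meta$params)) params <- meta$params
  }
  da_session(trials, spikes, licks, saccades, config = config,
             params = params, validate = TRUE)
}
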