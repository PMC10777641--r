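# Readers and writers. Recordings are stored as a directory containing a
# JSON metadata file plus one long-format CSV of samples (one group per
# recording; the native DAQ format is proprietary and out of scope).
# Feature tables, IO curves, session logs and behaviour tables are
# delimiter-separated text with header rows; configuration is JSON.
# Within sweeps, time is in ms relative to stimulus onset; distances are
# derived from the lead geometry.

#' Write / read a multi-channel recording
#'
#' A recording is written as `<dir>/meta.json` (sample rate, geometry,
#' program) and `<dir>/sweeps.csv` (columns `pulse`, `channel`, `sample`,
#' `mv`). `read_recording()` restores a `multichannel_recording` equal in
#' value to the one written.
#'
#' @param recording A `multichannel_recording`.
#' @param dir Output directory (created if missing).
#' @return `write_recording()` the directory, invisibly;
#'   `read_recording()` a `multichannel_recording`.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "multichannel_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- recording$geometry
  p <- recording$program
  meta <- list(sample_rate = recording$sample_rate,
               n_samples = dim(recording$sweeps)[3],
               geometry = list(n_contacts = g$n_contacts,
                               spacing_mm = g$spacing_mm,
                               stim_index = g$stim_index,
                               contact_labels = g$contact_labels),
               program = list(frequency_hz = p$frequency_hz,
                              pulse_width_us = p$pulse_width_us,
                              duration_s = p$duration_s,
                              current_ma = p$current_ma))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  d <- dim(recording$sweeps)
  long <- data.table::data.table(
    pulse = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    mv = as.vector(recording$sweeps))
  data.table::fwrite(long, file.path(dir, "sweeps.csv"))
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  long <- data.table::fread(file.path(dir, "sweeps.csv"))
  g <- lead_geometry(meta$geometry$n_contacts, meta$geometry$spacing_mm,
                     meta$geometry$stim_index,
                     meta$geometry$contact_labels)
  p <- stimulus_program(meta$program$frequency_hz,
                        meta$program$pulse_width_us,
                        meta$program$duration_s,
                        meta$program$current_ma)
  n_p <- max(long$pulse); n_ch <- max(long$channel)
  n_s <- meta$n_samples
  sweeps <- array(0, dim = c(n_p, n_ch, n_s))
  sweeps[cbind(long$pulse, long$channel, long$sample)] <- long$mv
  t_ms <- (seq_len(n_s) - 1) / meta$sample_rate * 1000
  structure(list(sweeps = sweeps, time_ms = t_ms,
                 sample_rate = meta$sample_rate,
                 geometry = g, program = p),
            class = "multichannel_recording")
}

#' Write / read a plain table (features, IO curves, behaviour)
#'
#' Thin CSV round-trip helpers. `read_behavior_table()` additionally
#' restores the `behavior_table` class.
#'
#' @param x A data.frame.
#' @param path CSV path.
#' @return The path (writers, invisibly) or a data.frame (readers).
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_table_csv
#' @export
read_behavior_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(timepoint = "character"))
  class(out) <- c("behavior_table", "data.frame")
  out
}

#' Write / read a closed-loop session log
#'
#' The per-pulse records go to `<path>` as CSV; the session metadata
#' (mode, target, thresholds, update count, frequency, saturation flag)
#' goes to a `<path>.json` sidecar so the round trip preserves the full
#' `cl_session_log`.
#'
#' @param log A `cl_session_log`.
#' @param path CSV path.
#' @return The path (writer, invisibly) or a `cl_session_log` (reader).
#' @export
write_session_log <- function(log, path) {
  data.table::fwrite(as.data.frame(log), path)
  meta <- list(mode = attr(log, "mode"),
               target_mv = attr(log, "target_mv"),
               ecapt = attr(log, "ecapt"),
               mt_current = attr(log, "mt_current"),
               mt_amplitude = attr(log, "mt_amplitude"),
               n_updates = attr(log, "n_updates"),
               frequency_hz = attr(log, "frequency_hz"),
               saturated = attr(log, "saturated"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  structure(df, class = c("cl_session_log", "data.frame"),
            mode = meta$mode, target_mv = meta$target_mv,
            ecapt = meta$ecapt, mt_current = meta$mt_current,
            mt_amplitude = meta$mt_amplitude,
            n_updates = meta$n_updates,
            frequency_hz = meta$frequency_hz,
            saturated = meta$saturated)
}

#' Run configuration
#'
#' A serialisable bundle of every tunable of a run: seed, lead geometry,
#' stimulus program, ground-truth parameters, controller parameters and
#' analysis options. `read_config()`/`write_config()` round-trip it as
#' JSON, and every CLI run echoes its effective configuration to the
#' output directory.
#'
#' @param seed Integer seed.
#' @param preset Ground-truth preset, `"sham"` or `"sni"`.
#' @param gt,geometry,program Optional explicit parameter lists
#'   overriding the preset (plain lists of constructor arguments).
#' @param controller Controller parameter overrides.
#' @param analysis Analysis options: `smoothing`, `k`, `blanking_ms`,
#'   `search_window_ms`, `target_mv`, `duration_min`.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L, preset = c("sham", "sni"),
                       gt = list(), geometry = list(), program = list(),
                       controller = list(), analysis = list()) {
  preset <- match.arg(preset)
  analysis <- utils::modifyList(
    list(smoothing = 0.95, k = 3, blanking_ms = 0.5,
         search_window_ms = c(0.5, 5), target_mv = NA_real_,
         duration_min = 30), analysis)
  structure(list(seed = as.integer(seed), preset = preset, gt = gt,
                 geometry = geometry, program = program,
                 controller = controller, analysis = analysis),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$seed) || is.null(x$preset))
    stop("config schema violation: 'seed' and 'preset' are required")
  run_config(seed = x$seed, preset = x$preset,
             gt = as.list(x$gt), geometry = as.list(x$geometry),
             program = as.list(x$program),
             controller = as.list(x$controller),
             analysis = as.list(x$analysis))
}

# Materialize config pieces into package objects.
config_gt <- function(config) {
  base <- if (config$preset == "sni") gt_sni else gt_sham
  do.call(base, config$gt)
}

config_geometry <- function(config) {
  do.call(lead_geometry, config$geometry)
}

config_program <- function(config, ...) {
  args <- utils::modifyList(config$program, list(...))
  do.call(stimulus_program, args)
}
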