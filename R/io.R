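# Interchange formats: trace CSV + JSON sidecar, image CSV-per-channel.
# The sidecar declares the modality, units and protocol so a reader can
# reconstruct the typed object and validate its invariants.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_json_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
}

read_json_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    cmq_stop(sprintf("missing sidecar '%s'", sp), "cmq_missing_sidecar")
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

deterministic_write_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", eol = "\n")
}

#' Write a recording to CSV with a JSON sidecar
#'
#' Column 1 is time (ms for electrophysiology, s for calcium); remaining
#' columns are sweeps or the signal. Metadata (modality, units, protocol,
#' capacitance, stimulus times, ground-truth generator parameters) goes
#' to `<path-sans-ext>.json`.
#'
#' @param x a `sweep_family`, `voltage_trace` or `fluorescence_trace`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) UseMethod("write_trace_csv")

#' @export
write_trace_csv.sweep_family <- function(x, path) {
  df <- data.frame(time_ms = x$time, x$sweeps)
  names(df)[-1L] <- sprintf("sweep_%g", x$step_voltages)
  deterministic_write_csv(df, path)
  write_json_sidecar(list(
    modality = x$modality, units = list(time = "ms", signal = "pA"),
    step_voltages = x$step_voltages, capacitance = x$capacitance,
    protocol = unclass(x$protocol), step_window = x$step_window,
    baseline_window = x$baseline_window, seed = x$seed,
    ground_truth = if (!is.null(x$ground_truth)) unclass(x$ground_truth)), path)
  invisible(path)
}

#' @export
write_trace_csv.voltage_trace <- function(x, path) {
  deterministic_write_csv(data.frame(time_ms = x$time, voltage_mV = x$voltage),
                          path)
  write_json_sidecar(list(
    modality = "ap", units = list(time = "ms", signal = "mV"),
    stimulus_times = x$stimulus_times, sampling_rate = x$sampling_rate,
    seed = x$seed,
    ground_truth = if (!is.null(x$targets)) unclass(x$targets)), path)
  invisible(path)
}

#' @export
write_trace_csv.fluorescence_trace <- function(x, path) {
  deterministic_write_csv(data.frame(time_s = x$time, ratio = x$ratio), path)
  write_json_sidecar(list(
    modality = "ca", units = list(time = "s", signal = "ratio"),
    stimulus_times = x$stimulus_times, pacing_hz = x$pacing_hz,
    sampling_rate = x$sampling_rate, seed = x$seed,
    ground_truth = if (!is.null(x$targets)) unclass(x$targets)), path)
  invisible(path)
}

rebuild_protocol <- function(p, modality) {
  if (modality == "na") do.call(vclamp_protocol, p) else do.call(inact_protocol, p)
}

#' Read a recording written by [write_trace_csv()]
#'
#' Dispatches on the sidecar's `modality` field and validates the
#' invariants of the reconstructed object (uniform time grid, expected
#' column count, units).
#'
#' @param path CSV path (sidecar expected at `<path-sans-ext>.json`).
#' @return a `sweep_family`, `voltage_trace` or `fluorescence_trace`.
#' @export
read_trace_csv <- function(path) {
  meta <- read_json_sidecar(path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is_uniform(df[[1L]]))
    cmq_stop("non-uniform time grid in trace CSV", "cmq_invalid_trace")
  modality <- meta$modality %||% cmq_stop("sidecar lacks 'modality'",
                                          "cmq_invalid_sidecar")
  if (modality %in% c("na", "inact")) {
    if (ncol(df) < 3L)
      cmq_stop("sweep-family CSV needs a time column and at least 2 sweeps",
               "cmq_invalid_trace")
    if (!identical(meta$units$time, "ms"))
      cmq_stop("sweep-family time must be in ms", "cmq_unit_mismatch")
    gt <- if (!is.null(meta$ground_truth))
      do.call(gating_preset, meta$ground_truth)
    sweeps <- as.matrix(df[, -1L, drop = FALSE])
    dimnames(sweeps) <- NULL
    structure(list(time = df[[1L]],
                   sweeps = sweeps,
                   step_voltages = as.numeric(meta$step_voltages),
                   capacitance = meta$capacitance,
                   protocol = rebuild_protocol(meta$protocol, modality),
                   step_window = as.numeric(meta$step_window),
                   baseline_window = as.numeric(meta$baseline_window),
                   modality = modality, ground_truth = gt,
                   seed = meta$seed),
              class = "sweep_family")
  } else if (modality == "ap") {
    if (ncol(df) != 2L)
      cmq_stop("voltage-trace CSV must have exactly time + voltage columns",
               "cmq_invalid_trace")
    if (!identical(meta$units$time, "ms"))
      cmq_stop("voltage-trace time must be in ms", "cmq_unit_mismatch")
    tg <- if (!is.null(meta$ground_truth)) do.call(ap_targets, meta$ground_truth)
    structure(list(time = df[[1L]], voltage = df[[2L]],
                   stimulus_times = as.numeric(meta$stimulus_times),
                   sampling_rate = meta$sampling_rate, targets = tg,
                   seed = meta$seed),
              class = "voltage_trace")
  } else if (modality == "ca") {
    if (ncol(df) != 2L)
      cmq_stop("fluorescence-trace CSV must have exactly time + ratio columns",
               "cmq_invalid_trace")
    if (!identical(meta$units$time, "s"))
      cmq_stop("fluorescence-trace time must be in s", "cmq_unit_mismatch")
    tg <- if (!is.null(meta$ground_truth))
      do.call(transient_targets, meta$ground_truth)
    structure(list(time = df[[1L]], ratio = df[[2L]],
                   stimulus_times = as.numeric(meta$stimulus_times),
                   pacing_hz = meta$pacing_hz,
                   sampling_rate = meta$sampling_rate, targets = tg,
                   seed = meta$seed),
              class = "fluorescence_trace")
  } else {
    cmq_stop(sprintf("unknown modality '%s' in sidecar", modality),
             "cmq_invalid_sidecar")
  }
}

#' Write / read a multi-channel image as CSV matrices
#'
#' One CSV matrix per channel (`<prefix>_ch<i>.csv`) plus a JSON sidecar
#' (`<prefix>.json`) holding pixel size, channel labels and the
#' ground-truth geometry. A plain-text stand-in for multi-page TIFF.
#'
#' @param image a `multichannel_image`.
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_image_csv <- function(image, prefix) {
  stopifnot(inherits(image, "multichannel_image"))
  for (i in seq_along(image$channels))
    utils::write.table(image$channels[[i]], sprintf("%s_ch%d.csv", prefix, i),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       eol = "\n")
  jsonlite::write_json(list(
    pixel_size = image$pixel_size, channel_labels = image$channel_labels,
    n_channels = length(image$channels),
    ground_truth = if (!is.null(image$ground_truth)) unclass(image$ground_truth)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paste0(prefix, ".json"))
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(prefix) {
  sp <- paste0(prefix, ".json")
  if (!file.exists(sp))
    cmq_stop(sprintf("missing image sidecar '%s'", sp), "cmq_missing_sidecar")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  channels <- lapply(seq_len(meta$n_channels), function(i)
    as.matrix(utils::read.csv(sprintf("%s_ch%d.csv", prefix, i),
                              header = FALSE)))
  channels <- lapply(channels, unname)
  gt <- if (!is.null(meta$ground_truth)) {
    g <- meta$ground_truth
    striation_geometry(g$period, g$zdisk_sigma, g$actin_shift, g$band_length,
                       g$pixel_size, g$image_size, g$channel_gains)
  }
  multichannel_image(channels, meta$pixel_size, meta$channel_labels, gt)
}
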