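#' Multichannel recording container
#'
#' An `ecog_recording` holds a channels-by-samples amplitude matrix together
#' with its sampling rate, channel labels, wall-clock start time and amplitude
#' unit. All downstream operations (filtering, channel rejection, windowing,
#' feature extraction) consume and return this container.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names; defaults to
#'   `"CH001"`, `"CH002"`, ...
#' @param start_time wall-clock time of the first sample (`POSIXct`).
#' @param unit amplitude unit string as found in the file header (e.g. `"mV"`).
#'
#' @return An object of class `ecog_recording`.
#' @export
new_recording <- function(data, fs, channel_labels = NULL,
                          start_time = as.POSIXct("1970-01-01", tz = "UTC"),
                          unit = "mV") {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%03d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` length must equal the number of channels", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         start_time = as.POSIXct(start_time), unit = unit),
    class = "ecog_recording"
  )
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s), unit %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$unit))
  cat("  start:", format(x$start_time, "%Y-%m-%d %H:%M:%S %Z"), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `ecog_recording`.
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Read a recording stored as raw binary samples plus a JSON sidecar
#'
#' The sidecar (`<path>.json`) describes the binary layout: `fs`,
#' `n_channels`, `n_samples`, `channel_labels`, `start_time`, `unit`,
#' `dtype` (`"double"` or `"int16"`) and, for `int16`, a `scale` factor.
#' Samples are stored channel-interleaved (sample-major), little-endian.
#'
#' @param path path to the binary payload; `paste0(path, ".json")` must exist.
#' @return An `ecog_recording`.
#' @export
read_raw_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    stop("recording payload or JSON sidecar not found: ", path, call. = FALSE)
  }
  hdr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- hdr$n_channels * hdr$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  if (identical(hdr$dtype, "int16")) {
    raw <- readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
    raw <- raw * hdr$scale
  } else {
    raw <- readBin(con, "double", n = n, size = 8L, endian = "little")
  }
  data <- matrix(raw, nrow = hdr$n_channels)  # sample-major interleave
  new_recording(data, fs = hdr$fs, channel_labels = hdr$channel_labels,
                start_time = as.POSIXct(hdr$start_time, tz = "UTC"),
                unit = hdr$unit %||% "mV")
}

#' Write a recording as raw binary samples plus a JSON sidecar
#'
#' @param rec an `ecog_recording`.
#' @param path output path for the binary payload; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param dtype `"double"` (lossless) or `"int16"` (scaled to the per-file
#'   absolute maximum).
#' @return `path`, invisibly.
#' @export
write_raw_recording <- function(rec, path, dtype = c("double", "int16")) {
  dtype <- match.arg(dtype)
  hdr <- list(fs = rec$fs, n_channels = nrow(rec$data),
              n_samples = ncol(rec$data), channel_labels = rec$channel_labels,
              start_time = format(rec$start_time, "%Y-%m-%dT%H:%M:%S"),
              unit = rec$unit, dtype = dtype)
  x <- as.vector(rec$data)  # column-major = sample-major interleave
  con <- file(path, "wb")
  on.exit(close(con))
  if (dtype == "int16") {
    scale <- max(abs(x), 1e-12) / 32767
    hdr$scale <- scale
    writeBin(as.integer(round(x / scale)), con, size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 8L, endian = "little")
  }
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a European Data Format (EDF) recording
#'
#' Minimal EDF reader covering continuous EDF files with a uniform sampling
#' rate across signals, as produced by [write_edf()] and by standard
#' acquisition software. Annotations channels are not supported.
#'
#' @param path path to an `.edf` file.
#' @return An `ecog_recording`; amplitudes are mapped from digital to physical
#'   values via the per-signal calibration in the header.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8)                                   # version
  rd(80); rd(80)                          # patient / recording id
  startdate <- rd(8); starttime <- rd(8)
  as.integer(rd(8))                       # header bytes
  rd(44)                                  # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)           # reserved
  if (length(unique(spr)) != 1L) {
    stop("EDF files with per-signal sampling rates are not supported", call. = FALSE)
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  offset <- pmin - gain * dmin
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                   signed = TRUE, endian = "little")
    blk <- matrix(blk, nrow = spr[1])     # one column per signal
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, cols] <- t(blk * rep(gain, each = spr[1]) + rep(offset, each = spr[1]))
  }
  start <- as.POSIXct(paste(startdate, starttime), format = "%d.%m.%y %H.%M.%S",
                      tz = "UTC")
  if (is.na(start)) start <- as.POSIXct("1970-01-01", tz = "UTC")
  new_recording(data, fs = spr[1] / rec_dur, channel_labels = make.unique(labels),
                start_time = start, unit = units[1])
}

#' Write a recording to European Data Format (EDF)
#'
#' Physical amplitudes are scaled to the full signed 16-bit digital range
#' using the per-channel absolute maximum.
#'
#' @param rec an `ecog_recording`; its duration must be an integer number of
#'   seconds (EDF data records of 1 s are used).
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  if (n_samp %% fs != 0L) stop("recording length must be a whole number of seconds", call. = FALSE)
  n_rec <- n_samp %/% fs
  pmax <- apply(abs(rec$data), 1L, max)
  pmax <- ifelse(pmax <= 0, 1, pmax)
  gain <- pmax / 32767
  digital <- round(rec$data / gain)       # channels x samples

  pad <- function(x, w) formatC(substr(as.character(x), 1L, w), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad("0", 8))
  wr(pad("X X X X", 80)); wr(pad("Startdate X X X X", 80))
  wr(pad(format(rec$start_time, "%d.%m.%y"), 8))
  wr(pad(format(rec$start_time, "%H.%M.%S"), 8))
  wr(pad(256L * (1L + ns), 8)); wr(pad("", 44))
  wr(pad(n_rec, 8)); wr(pad("1", 8)); wr(pad(ns, 4))
  for (l in rec$channel_labels) wr(pad(l, 16))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad(rec$unit, 8))
  for (i in seq_len(ns)) wr(pad(sprintf("%.5g", -pmax[i]), 8))
  for (i in seq_len(ns)) wr(pad(sprintf("%.5g", pmax[i]), 8))
  for (i in seq_len(ns)) wr(pad("-32767", 8))
  for (i in seq_len(ns)) wr(pad("32767", 8))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad(fs, 8))
  for (i in seq_len(ns)) wr(pad("", 32))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(digital[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
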