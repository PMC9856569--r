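#' Preprocessing configuration
#'
#' Bundles the parameters of the preprocessing stage: band-pass corner
#' frequencies and filter order, the high-amplitude channel-rejection
#' threshold, the sliding-window geometry, and the target rate at which the
#' signal is resampled before symbolic (wSMI) analysis.
#'
#' @param f_low high-pass corner in Hz.
#' @param f_high low-pass corner in Hz.
#' @param filter_order Butterworth order (applied per band edge).
#' @param amp_threshold channel-rejection threshold in the recording's
#'   amplitude unit; a channel whose peak absolute amplitude exceeds it is
#'   discarded.
#' @param window_s window length in seconds.
#' @param stride_s window stride in seconds.
#' @param wsmi_fs sampling rate in Hz used for symbolic connectivity.
#'
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(f_low = 0.5, f_high = 45, filter_order = 3,
                              amp_threshold = 200, window_s = 3, stride_s = 1,
                              wsmi_fs = 200) {
  cfg <- list(f_low = f_low, f_high = f_high, filter_order = as.integer(filter_order),
              amp_threshold = amp_threshold, window_s = window_s,
              stride_s = stride_s, wsmi_fs = wsmi_fs)
  if (!(f_low > 0 && f_low < f_high)) stop("need 0 < f_low < f_high", call. = FALSE)
  if (!(window_s >= stride_s && stride_s > 0)) {
    stop("need window_s >= stride_s > 0", call. = FALSE)
  }
  if (amp_threshold <= 0) stop("`amp_threshold` must be positive", call. = FALSE)
  class(cfg) <- "preprocess_config"
  cfg
}

check_config_vs_fs <- function(cfg, fs) {
  if (cfg$f_high >= fs / 2) {
    stop(sprintf("f_high (%g Hz) must lie below the Nyquist frequency (%g Hz)",
                 cfg$f_high, fs / 2), call. = FALSE)
  }
  invisible(TRUE)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel forward and backward (zero-phase), so the effective
#' attenuation is the squared magnitude response of the designed filter and
#' no phase distortion is introduced — important because phase shifts would
#' bias the imaginary-coherency feature.
#'
#' @param rec an `ecog_recording`.
#' @param cfg a [preprocess_config()].
#' @return A filtered `ecog_recording` with identical shape and labels.
#' @export
bandpass <- function(rec, cfg = preprocess_config()) {
  check_config_vs_fs(cfg, rec$fs)
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$f_low, cfg$f_high) / (rec$fs / 2), type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(bf, ch)))
  rownames(out$data) <- rec$channel_labels
  out
}

#' Reject channels exceeding an absolute amplitude threshold
#'
#' A channel is rejected when its peak absolute amplitude over the whole
#' recording exceeds `cfg$amp_threshold`. Channel order among survivors is
#' preserved.
#'
#' @param rec an `ecog_recording`.
#' @param cfg a [preprocess_config()].
#' @return A list with elements `recording` (surviving channels) and
#'   `rejected` (labels of removed channels).
#' @export
reject_channels <- function(rec, cfg = preprocess_config()) {
  peak <- apply(abs(rec$data), 1L, max)
  bad <- peak > cfg$amp_threshold
  if (all(bad)) {
    stop(sprintf("all %d channels exceed the %g %s amplitude threshold",
                 nrow(rec$data), cfg$amp_threshold, rec$unit), call. = FALSE)
  }
  rejected <- rec$channel_labels[bad]
  if (length(rejected)) {
    message("rejected ", length(rejected), " channel(s): ",
            paste(rejected, collapse = ", "))
  }
  out <- rec
  out$data <- rec$data[!bad, , drop = FALSE]
  out$channel_labels <- rec$channel_labels[!bad]
  list(recording = out, rejected = rejected)
}

#' Closed-form sliding-window count
#'
#' Number of complete windows of `window_s` seconds at `stride_s` stride that
#' fit into `duration_s` seconds:
#' `floor((duration_s - window_s) / stride_s) + 1`.
#'
#' @param duration_s recording duration in seconds.
#' @param window_s window length in seconds.
#' @param stride_s stride in seconds.
#' @return Integer window count (0 when the recording is shorter than one
#'   window).
#' @export
count_windows <- function(duration_s, window_s = 3, stride_s = 1) {
  if (duration_s < window_s) return(0L)
  as.integer(floor((duration_s - window_s) / stride_s) + 1L)
}

#' Cut a recording into overlapping windows
#'
#' Windows never span file boundaries: each `ecog_windows` object belongs to
#' one source recording. Timestamps are absolute (wall clock of the window's
#' first sample). Blocks are not materialised; use [window_block()] to
#' extract the channels-by-samples matrix of one window.
#'
#' @param rec an `ecog_recording`.
#' @param cfg a [preprocess_config()].
#' @param source_file optional identifier of the originating file.
#' @return An `ecog_windows` object with fields `starts` (1-based sample
#'   indices), `timestamps` (POSIXct), `n_window_samples`, `recording`,
#'   `source_file`.
#' @export
window_recording <- function(rec, cfg = preprocess_config(), source_file = NA_character_) {
  nwin_samp <- as.integer(round(cfg$window_s * rec$fs))
  stride_samp <- cfg$stride_s * rec$fs
  n <- ncol(rec$data)
  if (n < nwin_samp) {
    stop("recording shorter than one window; no windows can be formed", call. = FALSE)
  }
  k <- count_windows(rec_duration(rec), cfg$window_s, cfg$stride_s)
  starts <- as.integer(round((seq_len(k) - 1L) * stride_samp)) + 1L
  structure(
    list(starts = starts,
         timestamps = rec$start_time + (starts - 1L) / rec$fs,
         n_window_samples = nwin_samp,
         recording = rec,
         source_file = source_file),
    class = "ecog_windows"
  )
}

#' Extract one window's data block
#' @param ws an `ecog_windows` object.
#' @param i window index.
#' @return Channels-by-samples numeric matrix.
#' @export
window_block <- function(ws, i) {
  s <- ws$starts[i]
  ws$recording$data[, s:(s + ws$n_window_samples - 1L), drop = FALSE]
}

#' @export
print.ecog_windows <- function(x, ...) {
  cat(sprintf("<ecog_windows> %d windows of %d samples (%d channels)\n",
              length(x$starts), x$n_window_samples, nrow(x$recording$data)))
  invisible(x)
}

#' Anti-aliased resampling to a lower rate
#'
#' Polyphase resampling (rational factor, FIR anti-aliasing); the
#' 500-to-200 Hz factor of 2/5 is non-integer, so plain decimation is not
#' applicable.
#'
#' @param rec an `ecog_recording`.
#' @param target_fs target sampling rate in Hz; must be below `rec$fs`.
#' @return The resampled `ecog_recording`; duration is preserved to within
#'   one sample.
#' @export
downsample <- function(rec, target_fs) {
  if (target_fs >= rec$fs) {
    stop("`target_fs` must be strictly below the current sampling rate", call. = FALSE)
  }
  frac <- ratio_approx(target_fs / rec$fs)
  out <- rec
  out$data <- t(apply(rec$data, 1L, function(ch) {
    resample_poly(ch, p = frac[1], q = frac[2])
  }))
  rownames(out$data) <- rec$channel_labels
  out$fs <- target_fs
  out
}

# rational-factor polyphase resampling: zero-stuff by p, windowed-sinc FIR
# low-pass at the tighter of the two Nyquist limits, pick every q-th sample
resample_poly <- function(x, p, q, ntaps_per_phase = 20L) {
  if (p == 1L && q == 1L) return(x)
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1L, by = p, length.out = n)] <- x
  N <- 2L * ntaps_per_phase * max(p, q)       # even order -> linear phase
  h <- p * signal::fir1(N, 1 / max(p, q))
  delay <- N %/% 2L
  yf <- signal::fftfilt(h, c(up, numeric(delay)))
  yf <- yf[(delay + 1L):(delay + n * p)]
  yf[seq(1L, by = q, length.out = ceiling(n * p / q))]
}

# smallest integer ratio p/q equal to x (x rational with small denominator)
ratio_approx <- function(x, max_q = 10000L) {
  for (q in seq_len(max_q)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("cannot express resampling ratio as a small rational", call. = FALSE)
}
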