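#' State schedule for synthetic recordings
#'
#' Ordered, contiguous, non-overlapping intervals labelled `"conscious"` or
#' `"unconscious"` covering `[0, duration]` seconds from the start of the
#' first synthetic file.
#'
#' @param start_s,end_s,state equal-length vectors describing the intervals.
#' @return A `state_schedule` data frame.
#' @export
state_schedule <- function(start_s, end_s, state) {
  df <- data.frame(start_s = start_s, end_s = end_s, state = state)
  df <- df[order(df$start_s), ]
  stopifnot(all(df$state %in% c("conscious", "unconscious")),
            all(df$end_s > df$start_s))
  if (df$start_s[1] != 0) stop("schedule must start at 0 s", call. = FALSE)
  if (nrow(df) > 1L && any(abs(df$start_s[-1] - df$end_s[-nrow(df)]) > 1e-9)) {
    stop("schedule intervals must be contiguous and non-overlapping", call. = FALSE)
  }
  class(df) <- c("state_schedule", "data.frame")
  df
}

#' Alternating conscious/unconscious schedule
#' @param total_s total duration in seconds.
#' @param block_s length of each state block in seconds.
#' @param first state of the first block.
#' @return A [state_schedule()].
#' @export
alternating_schedule <- function(total_s, block_s, first = "conscious") {
  n_blocks <- ceiling(total_s / block_s - 1e-9)
  starts <- (seq_len(n_blocks) - 1) * block_s
  ends <- pmin(starts + block_s, total_s)
  states <- rep(c(first, setdiff(c("conscious", "unconscious"), first)),
                length.out = length(starts))
  state_schedule(starts, ends, states)
}

#' Synthetic-ECoG generator configuration
#'
#' Emulates a chronic multichannel ECoG acquisition: 64 channels at 500 Hz
#' in consecutive one-hour files by default. Every channel is pink (1/f)
#' background noise plus state-dependent components:
#'
#' * conscious epochs add band-limited theta (2-4 Hz) and beta (15-25 Hz)
#'   stochastic oscillations shared across channels with a distinct per-channel
#'   lag (so lag-sensitive coupling measures respond) plus private broadband
#'   noise (raising complexity);
#' * unconscious epochs add a dominant zero-lag coherent sedation-like
#'   alpha rhythm (9-13 Hz) and a modest zero-lag slow wave (0.5-1.5 Hz),
#'   with little broadband noise — spectrally concentrated, regular, and
#'   invisible to zero-lag-blind coupling measures.
#'
#' Gains are component variances before the overall `amplitude_scale`;
#' `coupling_strength` is the shared (versus channel-private) fraction of
#' each oscillatory component. `noisy_channels` channels are multiplied by
#' `noisy_multiplier` so they exceed the amplitude-rejection threshold.
#'
#' @param n_channels,fs,file_length_s,n_files acquisition geometry.
#' @param seed integer RNG seed; the full output is reproducible from it.
#' @param conscious,unconscious named lists overriding profile defaults.
#' @param background_gain 1/f background variance.
#' @param amplitude_scale overall output scale in `unit`.
#' @param noisy_channels number of channels driven above threshold.
#' @param noisy_multiplier amplitude multiplier for those channels.
#' @param unit amplitude unit string.
#' @param start_time wall-clock start of the first file.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_channels = 64, fs = 500, file_length_s = 3600,
                         n_files = 24, seed = 1L,
                         conscious = list(), unconscious = list(),
                         background_gain = 0.3, amplitude_scale = 10,
                         noisy_channels = 0, noisy_multiplier = 5,
                         unit = "mV",
                         start_time = as.POSIXct("2022-06-01 00:34:00", tz = "UTC")) {
  cons <- utils::modifyList(
    list(theta_gain = 2.0, beta_gain = 1.2, broadband_gain = 1.0,
         coupling_strength = 0.8, coupling_lag = 10), conscious)
  uncons <- utils::modifyList(
    list(slow_wave_gain = 0.3, alpha_gain = 2.5, noise_gain = 0.15,
         coupling_strength = 0.9), unconscious)
  stopifnot(all(unlist(cons) >= 0), all(unlist(uncons) >= 0),
            n_channels >= 1, fs > 0, noisy_channels < n_channels)
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 file_length_s = file_length_s, n_files = as.integer(n_files),
                 seed = as.integer(seed), conscious = cons, unconscious = uncons,
                 background_gain = background_gain,
                 amplitude_scale = amplitude_scale,
                 noisy_channels = as.integer(noisy_channels),
                 noisy_multiplier = noisy_multiplier,
                 unit = unit, start_time = start_time),
            class = "synth_config")
}

# band-limited Gaussian noise of unit variance via FFT masking
bl_noise <- function(n, fs, f1, f2) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  X[f < f1 | f > f2] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stats::rnorm(n) else y / s
}

# pink (1/f amplitude above f0) background noise, unit variance
pink_noise <- function(n, fs, f0 = 0.5) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  shape <- 1 / sqrt(pmax(f, f0))
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

circ_shift <- function(x, lag) {
  n <- length(x)
  lag <- lag %% n
  if (lag == 0) return(x)
  c(x[(n - lag + 1L):n], x[seq_len(n - lag)])
}

#' Generate synthetic multichannel recordings with a planted state schedule
#'
#' Fully seeded; the same `(cfg, schedule)` always yields sample-identical
#' output.
#'
#' @param cfg a [synth_config()].
#' @param schedule a [state_schedule()] covering
#'   `cfg$n_files * cfg$file_length_s` seconds.
#' @return List of `ecog_recording`s, one per file.
#' @export
synth_generate <- function(cfg, schedule) {
  total <- cfg$n_files * cfg$file_length_s
  if (abs(max(schedule$end_s) - total) > 1e-6) {
    stop("schedule must cover exactly n_files * file_length_s seconds", call. = FALSE)
  }
  set.seed(cfg$seed)
  noisy_idx <- if (cfg$noisy_channels > 0) {
    unique(as.integer(round(seq(2, cfg$n_channels, length.out = cfg$noisy_channels))))
  } else integer()
  labels <- sprintf("G%03d", seq_len(cfg$n_channels))
  recs <- vector("list", cfg$n_files)
  for (fi in seq_len(cfg$n_files)) {
    n <- as.integer(round(cfg$file_length_s * cfg$fs))
    data <- matrix(0, cfg$n_channels, n)
    for (ch in seq_len(cfg$n_channels)) {
      data[ch, ] <- sqrt(cfg$background_gain) * pink_noise(n, cfg$fs)
    }
    file_t0 <- (fi - 1L) * cfg$file_length_s
    # schedule segments intersecting this file
    for (si in seq_len(nrow(schedule))) {
      a <- max(schedule$start_s[si], file_t0)
      b <- min(schedule$end_s[si], file_t0 + cfg$file_length_s)
      if (b <= a) next
      i0 <- as.integer(round((a - file_t0) * cfg$fs)) + 1L
      i1 <- as.integer(round((b - file_t0) * cfg$fs))
      m <- i1 - i0 + 1L
      cols <- i0:i1
      if (schedule$state[si] == "conscious") {
        p <- cfg$conscious
        th_shared <- bl_noise(m, cfg$fs, 2, 4)
        be_shared <- bl_noise(m, cfg$fs, 15, 25)
        for (ch in seq_len(cfg$n_channels)) {
          lag <- p$coupling_lag * (ch - 1L)
          th <- sqrt(p$coupling_strength) * circ_shift(th_shared, lag) +
            sqrt(1 - p$coupling_strength) * bl_noise(m, cfg$fs, 2, 4)
          be <- sqrt(p$coupling_strength) * circ_shift(be_shared, lag) +
            sqrt(1 - p$coupling_strength) * bl_noise(m, cfg$fs, 15, 25)
          data[ch, cols] <- data[ch, cols] +
            sqrt(p$theta_gain) * th + sqrt(p$beta_gain) * be +
            sqrt(p$broadband_gain) * stats::rnorm(m)
        }
      } else {
        p <- cfg$unconscious
        sw_shared <- bl_noise(m, cfg$fs, 0.5, 1.5)
        al_shared <- bl_noise(m, cfg$fs, 9, 13)
        for (ch in seq_len(cfg$n_channels)) {
          sw <- sqrt(p$coupling_strength) * sw_shared +
            sqrt(1 - p$coupling_strength) * bl_noise(m, cfg$fs, 0.5, 1.5)
          al <- sqrt(p$coupling_strength) * al_shared +
            sqrt(1 - p$coupling_strength) * bl_noise(m, cfg$fs, 9, 13)
          data[ch, cols] <- data[ch, cols] +
            sqrt(p$slow_wave_gain) * sw + sqrt(p$alpha_gain) * al +
            sqrt(p$noise_gain) * stats::rnorm(m)
        }
      }
    }
    data <- data * cfg$amplitude_scale
    if (length(noisy_idx)) {
      data[noisy_idx, ] <- data[noisy_idx, ] * cfg$noisy_multiplier
    }
    recs[[fi]] <- new_recording(data, fs = cfg$fs, channel_labels = labels,
                                start_time = cfg$start_time + file_t0,
                                unit = cfg$unit)
  }
  recs
}

#' Planted state label for each analysis window
#'
#' A window is labelled with the state of the schedule interval containing
#' its midpoint.
#'
#' @param schedule a [state_schedule()].
#' @param times POSIXct window start times (or an `ecog_windows` object).
#' @param window_s window length in seconds.
#' @param origin wall-clock time corresponding to schedule second 0 (the
#'   first file's start); defaults to the earliest window time for windows
#'   from the first file.
#' @return Character vector of `"conscious"`/`"unconscious"` labels.
#' @export
ground_truth_labels <- function(schedule, times, window_s = 3, origin = NULL) {
  if (inherits(times, "ecog_windows")) {
    window_s <- times$n_window_samples / times$recording$fs
    times <- times$timestamps
  }
  if (is.null(origin)) origin <- min(times)
  mid <- as.numeric(difftime(times, origin, units = "secs")) + window_s / 2
  idx <- findInterval(pmin(mid, max(schedule$end_s) - 1e-9), schedule$start_s)
  schedule$state[idx]
}
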