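FEATURE_NAMES <- c("Ptheta", "Pbeta", "SEF95", "ERR", "LZC", "iCOHtheta", "wSMI")

#' Extract the seven-feature matrix from a set of recordings
#'
#' Runs the full feature stage: high-amplitude channel rejection (a channel
#' exceeding the threshold in any file is dropped everywhere), zero-phase
#' band-pass filtering, sliding-window segmentation (windows never cross
#' file boundaries), and per-window computation of relative theta and beta
#' power, normalised 95% spectral edge, Poincare SD1/SD2 ratio, Lempel-Ziv
#' complexity, theta-band imaginary coherency and wSMI. Spectral and
#' complexity features are averaged across retained channels; connectivity
#' features are the lower-triangle mean of the pairwise matrix. wSMI is
#' computed on a polyphase-resampled copy of the signal at `cfg$wsmi_fs`.
#'
#' The Poincare delay is calibrated once per run as `tau_rule` times the
#' dominant cycle period of the first file (first retained channel), unless
#' `poincare$tau` is given or `tau_mode = "per-window"`.
#'
#' @param recs list of `ecog_recording`s, or character vector of file paths
#'   (`.edf`, or raw-binary payloads with JSON sidecars).
#' @param cfg a [preprocess_config()].
#' @param bands named band list as from [default_bands()].
#' @param spectral a [spectral_params()].
#' @param poincare a [poincare_params()].
#' @param lzc_p an [lzc_params()].
#' @param wsmi a [wsmi_params()].
#' @param verbose print per-file progress.
#' @return An `ecog_features` object: `times` (POSIXct per window), `raw`
#'   (T x 7 matrix), `normalized` (T x 7, column-wise min-max), `names`,
#'   `rejected_channels`, `retained_channels`, `tau_samples`, `n_imputed`.
#' @export
extract_features <- function(recs, cfg = preprocess_config(),
                             bands = default_bands(),
                             spectral = spectral_params(),
                             poincare = poincare_params(),
                             lzc_p = lzc_params(),
                             wsmi = wsmi_params(),
                             verbose = FALSE) {
  loader <- function(r) if (is.character(r)) load_recording(r) else r
  n_files <- length(recs)
  if (!n_files) stop("no input recordings", call. = FALSE)

  # pass 1: per-channel peak amplitude across all files -> global rejection
  first <- loader(recs[[1]])
  labels <- first$channel_labels
  peaks <- apply(abs(first$data), 1L, max)
  if (n_files > 1L) {
    for (i in 2:n_files) {
      r <- loader(recs[[i]])
      if (!identical(r$channel_labels, labels)) {
        stop("all files must share the same channel set", call. = FALSE)
      }
      peaks <- pmax(peaks, apply(abs(r$data), 1L, max))
    }
  }
  bad <- peaks > cfg$amp_threshold
  if (all(bad)) stop("all channels exceed the amplitude threshold", call. = FALSE)
  rejected <- labels[bad]
  if (length(rejected)) {
    message("rejected ", length(rejected), " channel(s): ",
            paste(rejected, collapse = ", "))
  }

  # calibration of the Poincare delay on the first file
  first_f <- bandpass(subset_channels(first, labels[!bad]), cfg)
  tau <- poincare$tau
  if (is.null(tau) && poincare$tau_mode == "fixed") {
    calib <- first_f$data[1L, seq_len(min(ncol(first_f$data),
                                          as.integer(120 * first_f$fs)))]
    period <- dominant_period(calib, first_f$fs,
                              f_range = c(cfg$f_low, cfg$f_high),
                              default_period = poincare$default_period)
    tau <- max(1L, as.integer(round(poincare$tau_rule * period * first_f$fs)))
  }

  times <- list()
  feats <- list()
  for (i in seq_len(n_files)) {
    rec <- if (i == 1L) first else loader(recs[[i]])
    filt <- if (i == 1L) first_f else bandpass(subset_channels(rec, labels[!bad]), cfg)
    if (verbose) message(sprintf("file %d/%d: %d windows", i, n_files,
                                 count_windows(rec_duration(filt), cfg$window_s, cfg$stride_s)))
    ds <- downsample(filt, cfg$wsmi_fs)
    ws_hi <- window_recording(filt, cfg, source_file = i)
    ws_lo <- window_recording(ds, cfg, source_file = i)
    stopifnot(length(ws_hi$starts) == length(ws_lo$starts))
    fm <- window_features(ws_hi, ws_lo, tau, bands, spectral, poincare, lzc_p, wsmi)
    times[[i]] <- ws_hi$timestamps
    feats[[i]] <- fm
  }
  raw <- do.call(rbind, feats)
  assemble_features(raw, do.call(c, times), rejected = rejected,
                    retained = labels[!bad], tau = tau)
}

load_recording <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path) else read_raw_recording(path)
}

subset_channels <- function(rec, keep) {
  out <- rec
  out$data <- rec$data[keep, , drop = FALSE]
  out$channel_labels <- keep
  out
}

# per-window feature rows for one file
window_features <- function(ws_hi, ws_lo, tau, bands, spectral, poincare,
                            lzc_p, wsmi) {
  n <- length(ws_hi$starts)
  fs <- ws_hi$recording$fs
  out <- matrix(NA_real_, n, 7L, dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(n)) {
    out[i, ] <- tryCatch({
      blk <- window_block(ws_hi, i)
      wf <- welch_fft(blk, fs, spectral)
      psd <- psd_from_fft(wf)
      tau_i <- if (poincare$tau_mode == "per-window") {
        per <- suppressWarnings(
          dominant_period(blk[1L, ], fs, default_period = poincare$default_period))
        max(1L, as.integer(round(poincare$tau_rule * per * fs)))
      } else tau
      err <- vapply(seq_len(nrow(blk)), function(ch)
        suppressWarnings(poincare_err(blk[ch, ], tau_i)), numeric(1))
      lz <- vapply(seq_len(nrow(blk)), function(ch)
        lzc(binarize(blk[ch, ], lzc_p), lzc_p), numeric(1))
      blk_lo <- window_block(ws_lo, i)
      c(mean(relative_power(psd, bands$theta, bands$total)),
        mean(relative_power(psd, bands$beta, bands$total)),
        mean(spectral_edge(psd, spectral)),
        mean(err[is.finite(err)]),
        mean(lz),
        reduce_matrix(icoh_matrix_from_fft(wf, bands$theta)),
        reduce_matrix(connectivity_matrix(blk_lo, "wsmi", wsmi = wsmi)))
    }, error = function(e) rep(NA_real_, 7L))
  }
  out
}

#' Assemble, impute and normalise a raw feature matrix
#'
#' Missing rows/cells (windows where a feature errored) are imputed by
#' carrying the previous window's value forward (the first valid value is
#' carried backward over a missing head). Each column is then min-max
#' normalised over the full recording so it attains 0 and 1.
#'
#' @param raw T x 7 numeric matrix with columns in the canonical feature
#'   order (`Ptheta`, `Pbeta`, `SEF95`, `ERR`, `LZC`, `iCOHtheta`, `wSMI`).
#' @param times POSIXct vector of window start times (length T).
#' @param rejected,retained channel-label bookkeeping (optional).
#' @param tau calibrated Poincare delay in samples (optional).
#' @return An `ecog_features` object.
#' @export
assemble_features <- function(raw, times, rejected = character(),
                              retained = character(), tau = NA_integer_) {
  stopifnot(ncol(raw) == 7L, nrow(raw) == length(times))
  colnames(raw) <- FEATURE_NAMES
  n_imputed <- sum(!is.finite(raw))
  if (n_imputed) {
    message("imputing ", n_imputed, " missing feature value(s) by carry-forward")
    raw <- apply(raw, 2L, impute_locf)
  }
  normalized <- raw
  for (j in seq_len(ncol(raw))) {
    rng <- range(raw[, j])
    if (rng[2] - rng[1] <= 0) {
      stop("feature '", FEATURE_NAMES[j],
           "' is constant; min-max normalisation undefined", call. = FALSE)
    }
    normalized[, j] <- (raw[, j] - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(times = times, names = FEATURE_NAMES, raw = raw,
                 normalized = normalized, rejected_channels = rejected,
                 retained_channels = retained, tau_samples = tau,
                 n_imputed = n_imputed),
            class = "ecog_features")
}

impute_locf <- function(col) {
  ok <- is.finite(col)
  if (!any(ok)) stop("a feature column has no finite values", call. = FALSE)
  idx <- cummax(ifelse(ok, seq_along(col), 0L))
  first_ok <- which(ok)[1]
  idx[idx == 0L] <- first_ok
  col[idx]
}

#' @export
print.ecog_features <- function(x, ...) {
  cat(sprintf("<ecog_features> %d windows x %d features (%d channels retained)\n",
              nrow(x$raw), ncol(x$raw), length(x$retained_channels)))
  invisible(x)
}
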