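#' Poincare-plot parameters
#'
#' The Poincare plot scatters `x[k]` against `x[k + tau]`. The delay `tau`
#' is taken as `tau_rule` (between 1/5 and 1/4) of the dominant cycle period
#' of the signal. By default one fixed `tau` is calibrated per recording
#' (from the first file) so the feature is comparable across windows;
#' `tau_mode = "per-window"` re-estimates it in every window.
#'
#' @param tau delay in samples; when `NULL` it is derived from the dominant
#'   period at feature-extraction time.
#' @param tau_rule fraction of the dominant cycle period (in `[1/5, 1/4]`).
#' @param tau_mode `"fixed"` (calibrated once) or `"per-window"`.
#' @param default_period fallback dominant period in seconds used when a
#'   signal has no identifiable spectral peak.
#' @return A `poincare_params` list.
#' @export
poincare_params <- function(tau = NULL, tau_rule = 1 / 4, tau_mode = c("fixed", "per-window"),
                            default_period = 0.25) {
  tau_mode <- match.arg(tau_mode)
  if (tau_rule < 1 / 5 - 1e-12 || tau_rule > 1 / 4 + 1e-12) {
    stop("`tau_rule` must lie in [1/5, 1/4]", call. = FALSE)
  }
  if (!is.null(tau) && tau < 1) stop("`tau` must be >= 1 sample", call. = FALSE)
  structure(list(tau = tau, tau_rule = tau_rule, tau_mode = tau_mode,
                 default_period = default_period),
            class = "poincare_params")
}

#' Dominant cycle period of a signal stretch
#'
#' Period of the strongest spectral peak (Welch PSD restricted to
#' `f_range`). When no clear peak stands out — the peak is less than
#' `peak_ratio` times the median in-range density, as for white noise or a
#' flat spectrum — the configured `default_period` is returned with a
#' warning.
#'
#' @param x single-channel numeric vector.
#' @param fs sampling rate in Hz.
#' @param f_range frequency range in Hz searched for the peak.
#' @param default_period fallback period in seconds.
#' @param peak_ratio peak-to-median density ratio required to accept a peak.
#' @return Dominant period in seconds.
#' @export
dominant_period <- function(x, fs, f_range = c(0.5, 45), default_period = 0.25,
                            peak_ratio = 4) {
  if (all(x == 0) || stats::sd(x) == 0) {
    warning("flat signal: falling back to the default dominant period")
    return(default_period)
  }
  psd <- welch_psd(x, fs)
  keep <- psd$freqs >= f_range[1] & psd$freqs <= f_range[2]
  pw <- psd$power[keep, 1]
  fr <- psd$freqs[keep]
  if (!length(pw) || max(pw) <= 0 || max(pw) < peak_ratio * stats::median(pw)) {
    warning("no dominant spectral peak: falling back to the default period")
    return(default_period)
  }
  1 / fr[which.max(pw)]
}

#' Poincare-plot ellipsoid radius ratio (SD1/SD2)
#'
#' `SD1 = sqrt(Var(x[k] - x[k+tau]) / 2)` measures dispersion perpendicular
#' to the identity line; `SD2 = sqrt(2 Var(x) - SD1^2)` along it. Their
#' ratio is ~1 for uncorrelated noise (round cloud) and tends to 0 for
#' linear/smooth signals (elongated cloud). Invariant under amplitude
#' scaling and offset.
#'
#' @param x single-channel numeric vector.
#' @param tau delay in samples (`length(x) > tau + 1`).
#' @return The ratio `SD1/SD2` (non-negative scalar).
#' @export
poincare_err <- function(x, tau) {
  tau <- as.integer(tau)
  n <- length(x)
  if (n <= tau + 1L) stop("window too short for the requested tau", call. = FALSE)
  d <- x[seq_len(n - tau)] - x[(tau + 1L):n]
  sd1_sq <- stats::var(d) / 2
  sd2_sq <- 2 * stats::var(x) - sd1_sq
  if (sd2_sq <= 0) {
    if (stats::var(x) == 0) stop("constant signal: SD2 = 0, ratio undefined", call. = FALSE)
    warning("negative SD2 radicand clamped to 0 (finite-sample artifact)")
    return(Inf)
  }
  sqrt(sd1_sq / sd2_sq)
}

#' Lempel-Ziv parameters
#' @param binarization binarization rule; only `"median"` (1 where the
#'   sample exceeds the window median) is implemented.
#' @param normalization `"normalized"` reports `c(n) log2(n) / n`,
#'   `"raw"` the plain phrase count `c(n)`.
#' @return An `lzc_params` list.
#' @export
lzc_params <- function(binarization = "median",
                       normalization = c("normalized", "raw")) {
  if (!identical(binarization, "median")) {
    stop("only median binarization is implemented", call. = FALSE)
  }
  structure(list(binarization = binarization,
                 normalization = match.arg(normalization)),
            class = "lzc_params")
}

#' Median binarization
#'
#' Maps a signal to the binary sequence `1` where `x > median(x)`, `0`
#' otherwise; length is preserved. A constant signal maps to all zeros.
#'
#' @param x single-channel numeric vector.
#' @param p an [lzc_params()] (rule selector).
#' @return Integer vector of 0/1 of the same length.
#' @export
binarize <- function(x, p = lzc_params()) {
  as.integer(x > stats::median(x))
}

#' Lempel-Ziv (LZ76) complexity of a binary sequence
#'
#' Counts the phrases of the exhaustive production history of the sequence
#' (the classic LZ76 scheme). The normalised form `c(n) log2(n) / n`
#' compensates for the growth of the raw count with sequence length.
#'
#' @param s integer 0/1 vector (from [binarize()]).
#' @param p an [lzc_params()].
#' @return Complexity value (raw count or normalised, per `p`).
#' @export
lzc <- function(s, p = lzc_params()) {
  n <- length(s)
  if (n < 2L) stop("sequence too short for LZ76 parsing", call. = FALSE)
  cn <- lz76_count(as.integer(s))
  if (p$normalization == "normalized") cn * log2(n) / n else cn
}
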