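#' Welch estimation parameters
#'
#' Settings for the averaged-periodogram spectral estimator used throughout:
#' sub-windows of `window_fraction` of the data segment, Hamming-tapered,
#' with `overlap` fractional overlap. `sef_fraction` and `sef_norm` control
#' the spectral-edge feature: the edge is the lowest frequency containing
#' `sef_fraction` of total power, reported normalised by `sef_norm` Hz (the
#' band-pass ceiling).
#'
#' @param window_fraction sub-window length as a fraction of the segment.
#' @param overlap fractional overlap between consecutive sub-windows.
#' @param taper taper name; only `"hamming"` is implemented.
#' @param sef_fraction cumulative power fraction defining the spectral edge.
#' @param sef_norm normalisation frequency in Hz for the spectral edge.
#' @return A `spectral_params` list.
#' @export
spectral_params <- function(window_fraction = 1 / 8, overlap = 0.5,
                            taper = "hamming", sef_fraction = 0.95,
                            sef_norm = 45) {
  stopifnot(overlap > 0, overlap < 1, sef_fraction > 0, sef_fraction <= 1,
            window_fraction > 0, window_fraction <= 1)
  if (!identical(taper, "hamming")) stop("only the Hamming taper is implemented", call. = FALSE)
  structure(list(window_fraction = window_fraction, overlap = overlap,
                 taper = taper, sef_fraction = sef_fraction, sef_norm = sef_norm),
            class = "spectral_params")
}

#' Frequency band definition
#' @param name band name.
#' @param f1,f2 lower and upper band edges in Hz (`0 <= f1 < f2`). Band sums
#'   include both edge bins.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, f1, f2) {
  stopifnot(f1 >= 0, f1 < f2)
  structure(list(name = name, f1 = f1, f2 = f2), class = "band_definition")
}

#' Default analysis bands
#'
#' Theta here is 0-4 Hz and beta 12-30 Hz, with the total band 0-45 Hz
#' matching the band-pass ceiling. These are configuration values: the
#' conventional 4-8 Hz theta is one edit away.
#' @return Named list of [band_definition()]s (`theta`, `beta`, `total`).
#' @export
default_bands <- function() {
  list(theta = band_definition("theta", 0, 4),
       beta  = band_definition("beta", 12, 30),
       total = band_definition("total", 0, 45))
}

# Tapered-segment FFTs shared by the PSD and cross-spectral estimators.
# Returns complex array nfreq x nseg x nchan (one-sided grid) plus the
# density normalisation so that mean(|X|^2) is a PSD in unit^2/Hz.
welch_fft <- function(block, fs, p = spectral_params()) {
  if (is.vector(block)) block <- matrix(block, nrow = 1L)
  n <- ncol(block)
  L <- floor(n * p$window_fraction)
  if (L < 2L) stop("segment too short for Welch estimation", call. = FALSE)
  step <- max(1L, floor(L * (1 - p$overlap)))
  nseg <- floor((n - L) / step) + 1L
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  nchan <- nrow(block)
  X <- array(0 + 0i, dim = c(nf, nseg, nchan))
  for (s in seq_len(nseg)) {
    idx <- ((s - 1L) * step + 1L):((s - 1L) * step + L)
    seg <- t(block[, idx, drop = FALSE]) * w     # L x nchan
    F <- stats::mvfft(seg)
    X[, s, ] <- F[seq_len(nf), , drop = FALSE]
  }
  list(freqs = (seq_len(nf) - 1L) * fs / L, X = X, scale = 1 / (fs * U),
       L = L, nseg = nseg)
}

#' Welch power spectral density of a window block
#'
#' Averaged modified periodogram: Hamming sub-windows of 1/8 of the segment
#' length with 50% overlap by default. One-sided density scaling (interior
#' bins doubled), so the PSD integrates to the signal variance.
#'
#' @param block channels-by-samples numeric matrix (or a vector for one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param p a [spectral_params()].
#' @return A `psd_estimate` with fields `freqs` (Hz grid), `power`
#'   (frequencies-by-channels density matrix), `resolution` (Hz).
#' @export
welch_psd <- function(block, fs, p = spectral_params()) {
  psd_from_fft(welch_fft(block, fs, p))
}

psd_from_fft <- function(wf) {
  nf <- length(wf$freqs)
  pwr <- apply(abs(wf$X)^2, c(1L, 3L), mean) * wf$scale
  pwr <- matrix(pwr, nrow = nf)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (wf$L %% 2 == 0) dbl[nf] <- 1
  pwr <- pwr * dbl
  structure(list(freqs = wf$freqs, power = pwr, resolution = wf$freqs[2]),
            class = "psd_estimate")
}

band_bins <- function(freqs, band) which(freqs >= band$f1 & freqs <= band$f2)

#' Relative band power
#'
#' Fraction of spectral power inside `band` relative to `total`:
#' `sum(S(f), f in band) / sum(S(f), f in total)`, computed on the discrete
#' Welch grid with both band edges included.
#'
#' @param psd a `psd_estimate` from [welch_psd()].
#' @param band numerator [band_definition()].
#' @param total denominator [band_definition()].
#' @return Numeric vector (one fraction per channel), each in `[0, 1]`.
#' @export
relative_power <- function(psd, band, total) {
  bi <- band_bins(psd$freqs, band)
  ti <- band_bins(psd$freqs, total)
  if (!length(ti)) stop("total band contains no grid frequencies", call. = FALSE)
  denom <- colSums(psd$power[ti, , drop = FALSE])
  if (any(denom <= 0)) {
    stop("total band power is zero; relative power undefined", call. = FALSE)
  }
  num <- if (length(bi)) colSums(psd$power[bi, , drop = FALSE]) else 0
  num / denom
}

#' Normalised spectral edge frequency
#'
#' Smallest grid frequency below which `sef_fraction` (default 95%) of the
#' total power lies, divided by `sef_norm` (default 45 Hz, the filter
#' ceiling). Cumulative sums run on the discrete grid without interpolation;
#' ties resolve to the lower frequency.
#'
#' @param psd a `psd_estimate`.
#' @param p a [spectral_params()].
#' @return Numeric vector (one normalised edge per channel).
#' @export
spectral_edge <- function(psd, p = spectral_params()) {
  tot <- colSums(psd$power)
  if (any(tot <= 0)) stop("zero total power; spectral edge undefined", call. = FALSE)
  vapply(seq_len(ncol(psd$power)), function(ch) {
    cum <- cumsum(psd$power[, ch])
    f <- psd$freqs[which(cum >= p$sef_fraction * tot[ch] - 1e-12)[1]]
    f / p$sef_norm
  }, numeric(1))
}
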