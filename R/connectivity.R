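#' Weighted symbolic mutual information parameters
#'
#' Signals are mapped to sequences of ordinal patterns of `k` samples spaced
#' `tau` samples apart (`k!` possible symbols; `k = 3` gives 6). The weight
#' rule discards symbol pairs that could arise from a common source: weight 0
#' for identical and for rank-reversed (sign-opposite) patterns, 1 otherwise.
#'
#' @param k pattern length (>= 2); default 3.
#' @param tau symbol lag in samples at the symbolic-analysis sampling rate.
#'   The default of 8 samples at 200 Hz spans `(k-1)*tau` = 80 ms, placing
#'   the pattern scale in the theta range.
#' @param weight_rule `"opposite"` (the rule above) or `"uniform"`
#'   (all weights 1, plain symbolic mutual information).
#' @return A `wsmi_params` list.
#' @export
wsmi_params <- function(k = 3, tau = 8, weight_rule = c("opposite", "uniform")) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (tau < 1) stop("`tau` must be >= 1 sample", call. = FALSE)
  structure(list(k = k, tau = as.integer(tau),
                 weight_rule = match.arg(weight_rule)),
            class = "wsmi_params")
}

# all permutations of 1:k in lexicographic order (k! rows)
perm_list <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_list(k - 1L)
  out <- NULL
  for (first in seq_len(k)) {
    rest <- sub + (sub >= first)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# lookup vector: base-(k+1) encoded rank tuple -> symbol id in 1..k!
perm_lookup <- function(k) {
  pm <- perm_list(k)
  keys <- as.integer(pm %*% (k + 1)^((k - 1):0))
  lut <- integer((k + 1)^k)
  lut[keys] <- seq_len(nrow(pm))
  lut
}

#' Ordinal-pattern symbolization
#'
#' Position `t` of the output is the rank pattern (permutation symbol) of
#' `(x[t], x[t + tau], ..., x[t + (k-1) tau])`; ties take the earlier sample
#' first. Symbols are integers in `1..k!`.
#'
#' @param x single-channel numeric vector with `length(x) > (k-1)*tau`.
#' @param p a [wsmi_params()].
#' @return Integer symbol vector of length `length(x) - (k-1)*tau`.
#' @export
symbolize <- function(x, p = wsmi_params()) {
  k <- p$k; tau <- p$tau
  m <- length(x) - (k - 1L) * tau
  if (m < 1L) stop("window too short to symbolize with these (k, tau)", call. = FALSE)
  lag <- vapply(0:(k - 1L), function(j) x[(1L + j * tau):(m + j * tau)],
                numeric(m))
  lag <- matrix(lag, nrow = m)
  # ranks with ties broken by position (earlier sample ranks lower)
  ranks <- matrix(1L, m, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      ranks[, i] <- ranks[, i] +
        (if (j < i) lag[, j] <= lag[, i] else lag[, j] < lag[, i])
    }
  }
  lut <- perm_lookup(k)
  key <- as.integer(ranks %*% (k + 1)^((k - 1):0))
  lut[key]
}

# k! x k! weight matrix for the configured rule
wsmi_weights <- function(p) {
  pm <- perm_list(p$k)
  nsym <- nrow(pm)
  w <- matrix(1, nsym, nsym)
  diag(w) <- 0
  if (p$weight_rule == "opposite") {
    rev_ranks <- (p$k + 1L) - pm            # pattern of the sign-flipped signal
    keys <- as.integer(pm %*% (p$k + 1)^((p$k - 1):0))
    opp <- match(as.integer(rev_ranks %*% (p$k + 1)^((p$k - 1):0)), keys)
    w[cbind(seq_len(nsym), opp)] <- 0
  }
  w
}

# core wSMI from two aligned symbol sequences
wsmi_from_symbols <- function(sx, sy, p) {
  nsym <- factorial(p$k)
  n <- length(sx)
  joint <- matrix(tabulate((sx - 1L) * nsym + sy, nsym * nsym),
                  nrow = nsym, byrow = TRUE) / n
  px <- tabulate(sx, nsym) / n
  py <- tabulate(sy, nsym) / n
  w <- wsmi_weights(p)
  idx <- which(joint > 0, arr.ind = TRUE)
  terms <- w[idx] * joint[idx] *
    log(joint[idx] / (px[idx[, 1]] * py[idx[, 2]]))
  sum(terms) / log(nsym)
}

#' Weighted symbolic mutual information between two signals
#'
#' Mutual information between the ordinal-symbol sequences of `x` and `y`,
#' with common-source-suspect symbol pairs (identical or rank-reversed)
#' weighted out and the result normalised by `log(k!)`. Joint probabilities
#' are raw co-occurrence frequencies; empty cells contribute 0.
#'
#' @param x,y single-channel numeric vectors of equal length, sampled at the
#'   symbolic-analysis rate.
#' @param p a [wsmi_params()].
#' @return A scalar; 0 for identical inputs, near 0 for independent ones.
#' @export
wsmi_pair <- function(x, y, p = wsmi_params()) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  sx <- symbolize(x, p)
  sy <- symbolize(y, p)
  if (length(unique(sx)) < 2L || length(unique(sy)) < 2L) {
    warning("degenerate (single-symbol) sequence: wSMI set to 0")
    return(0)
  }
  wsmi_from_symbols(sx, sy, p)
}

#' Theta-band imaginary coherency between two signals
#'
#' Complex coherency `Cxy(f) = Sxy / sqrt(Sxx Syy)` from Welch auto- and
#' cross-spectra; the statistic is the mean over in-band frequency bins of
#' `|Im(Cxy)|`. Zero-lag (volume-conducted) coupling is purely real and does
#' not register.
#'
#' @param x,y single-channel numeric vectors of equal length.
#' @param fs sampling rate in Hz.
#' @param band a [band_definition()]; default theta.
#' @param p a [spectral_params()].
#' @return Scalar in `[0, 1]`.
#' @export
icoh_pair <- function(x, y, fs, band = default_bands()$theta,
                      p = spectral_params()) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  m <- icoh_matrix_from_fft(welch_fft(rbind(x, y), fs, p), band)
  m[2, 1]
}

icoh_matrix_from_fft <- function(wf, band) {
  bi <- band_bins(wf$freqs, band)
  if (!length(bi)) stop("band contains no grid frequencies", call. = FALSE)
  nchan <- dim(wf$X)[3]
  nseg <- dim(wf$X)[2]
  vals <- matrix(NA_real_, nchan, nchan)
  # cross-spectral matrices per in-band frequency, averaged over segments
  auto <- matrix(0, length(bi), nchan)
  for (c1 in seq_len(nchan)) {
    auto[, c1] <- rowMeans(abs(wf$X[bi, , c1, drop = FALSE])^2)
  }
  if (any(auto <= 0)) stop("zero in-band auto-spectrum: coherency undefined", call. = FALSE)
  for (c1 in seq_len(nchan - 1L)) {
    X1 <- matrix(wf$X[bi, , c1], nrow = length(bi))
    for (c2 in (c1 + 1L):nchan) {
      X2 <- matrix(wf$X[bi, , c2], nrow = length(bi))
      sxy <- rowMeans(X1 * Conj(X2))
      coh <- sxy / sqrt(auto[, c1] * auto[, c2])
      vals[c1, c2] <- vals[c2, c1] <- mean(abs(Im(coh)))
    }
  }
  vals
}

#' Pairwise connectivity matrix for one window
#'
#' Fills all unordered channel pairs with the chosen measure; the diagonal
#' is `NA` (a sentinel excluded from every reduction).
#'
#' @param block channels-by-samples matrix (at the measure's expected
#'   sampling rate: `fs` for `icoh`, the symbolic rate for `wsmi`).
#' @param measure `"icoh"` or `"wsmi"`.
#' @param fs sampling rate of `block` in Hz (used by `icoh`).
#' @param band [band_definition()] for `icoh`.
#' @param wsmi a [wsmi_params()] for `wsmi`.
#' @param spectral a [spectral_params()] for `icoh`.
#' @return A `connectivity_matrix` object (`values`, `measure`, `band`).
#' @export
connectivity_matrix <- function(block, measure = c("icoh", "wsmi"), fs = NULL,
                                band = default_bands()$theta,
                                wsmi = wsmi_params(),
                                spectral = spectral_params()) {
  measure <- match.arg(measure)
  nchan <- nrow(block)
  if (nchan < 2L) stop("need at least 2 channels", call. = FALSE)
  if (measure == "icoh") {
    if (is.null(fs)) stop("`fs` is required for icoh", call. = FALSE)
    vals <- icoh_matrix_from_fft(welch_fft(block, fs, spectral), band)
  } else {
    syms <- lapply(seq_len(nchan), function(ch) symbolize(block[ch, ], wsmi))
    vals <- matrix(NA_real_, nchan, nchan)
    for (c1 in seq_len(nchan - 1L)) {
      for (c2 in (c1 + 1L):nchan) {
        vals[c1, c2] <- vals[c2, c1] <-
          wsmi_from_symbols(syms[[c1]], syms[[c2]], wsmi)
      }
    }
  }
  dimnames(vals) <- list(rownames(block), rownames(block))
  structure(list(values = vals, measure = measure, band = band),
            class = "connectivity_matrix")
}

#' Reduce a connectivity matrix to one scalar
#'
#' Arithmetic mean of the strictly-lower-triangle entries (the diagonal is
#' never included); by symmetry this equals the upper-triangle mean.
#'
#' @param m a `connectivity_matrix` (or a plain symmetric matrix).
#' @return Scalar mean coupling.
#' @export
reduce_matrix <- function(m) {
  v <- if (inherits(m, "connectivity_matrix")) m$values else m
  mean(v[lower.tri(v)])
}
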