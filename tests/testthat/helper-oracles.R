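# Independent reference implementations used to validate the package's
# primitives. Each is written from the defining property, not from the
# package code path it checks.

# LZ76 exhaustive-history phrase count, definitional form: a phrase grows
# while it occurs as a substring of everything before its last character.
lz76_oracle <- function(s) {
  n <- length(s)
  str <- paste(s, collapse = "")
  c <- 0L
  l <- 1L
  while (l <= n) {
    k <- 1L
    while (l + k - 1L <= n) {
      w <- substr(str, l, l + k - 1L)
      hist <- substr(str, 1L, l + k - 2L)
      if (nchar(hist) > 0 && grepl(w, hist, fixed = TRUE)) k <- k + 1L else break
    }
    c <- c + 1L
    l <- l + k
  }
  c
}

# ordinal symbolization via base rank(), matched against an explicitly
# enumerated permutation alphabet
symbolize_oracle <- function(x, k, tau) {
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))[, k:1, drop = FALSE]
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == k), , drop = FALSE]
  perms <- perms[do.call(order, as.data.frame(perms)), , drop = FALSE]
  keys <- apply(perms, 1, paste, collapse = "")
  m <- length(x) - (k - 1) * tau
  vapply(seq_len(m), function(t) {
    v <- x[t + (0:(k - 1)) * tau]
    match(paste(rank(v, ties.method = "first"), collapse = ""), keys)
  }, integer(1))
}

# wSMI from explicit joint count tables over every symbol pair
wsmi_oracle <- function(x, y, k, tau) {
  sx <- symbolize_oracle(x, k, tau)
  sy <- symbolize_oracle(y, k, tau)
  nsym <- factorial(k)
  n <- length(sx)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))[, k:1, drop = FALSE]
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == k), , drop = FALSE]
  perms <- perms[do.call(order, as.data.frame(perms)), , drop = FALSE]
  keys <- apply(perms, 1, paste, collapse = "")
  opp <- match(apply(k + 1 - perms, 1, paste, collapse = ""), keys)
  total <- 0
  for (a in seq_len(nsym)) {
    for (b in seq_len(nsym)) {
      w <- if (a == b || b == opp[a]) 0 else 1
      pxy <- sum(sx == a & sy == b) / n
      if (pxy == 0 || w == 0) next
      px <- sum(sx == a) / n
      py <- sum(sy == b) / n
      total <- total + w * pxy * log(pxy / (px * py))
    }
  }
  total / log(nsym)
}

# sliding-window count by brute-force enumeration of valid starts
count_windows_oracle <- function(duration_s, window_s, stride_s) {
  n <- 0L
  t <- 0
  while (t + window_s <= duration_s + 1e-9) {
    n <- n + 1L
    t <- t + stride_s
  }
  n
}

# Spearman rho as rank-then-Pearson
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# analytic squared-magnitude response of an order-n Butterworth band-pass
# (applied twice for zero-phase filtering)
butter_bp_mag2 <- function(f, f1, f2, n) {
  q <- (f^2 - f1 * f2) / (f * (f2 - f1))
  1 / (1 + q^(2 * n))
}

# small deterministic multichannel recording for structural tests
toy_recording <- function(n_channels = 4, fs = 500, dur_s = 10, seed = 42,
                          unit = "mV") {
  set.seed(seed)
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  data <- t(vapply(seq_len(n_channels), function(ch) {
    sin(2 * pi * (3 + ch) * t) + 0.5 * rnorm(length(t))
  }, numeric(length(t))))
  new_recording(data, fs = fs, unit = unit)
}
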