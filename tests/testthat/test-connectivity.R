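test_that("ordinal symbolization matches direct rank evaluation", {
  p <- wsmi_params(k = 3, tau = 1)
  # strictly increasing series: all symbols identical (ascending pattern)
  s <- symbolize(1:20, p)
  expect_equal(length(unique(s)), 1)
  # alphabet size is k! = 6 and a long random series uses all of it
  set.seed(12)
  expect_setequal(unique(symbolize(rnorm(5000), p)), 1:6)
  # series (1, 3, 2): single symbol, pattern (low, high, mid)
  s1 <- symbolize(c(1, 3, 2), p)
  expect_length(s1, 1)
  mid_high <- symbolize(c(1, 2, 3), p)  # ascending reference
  expect_false(s1 == mid_high)
  # equals the independently coded oracle on random data, several (k, tau)
  for (k in 2:4) {
    for (tau in c(1, 3)) {
      x <- rnorm(60)
      expect_equal(symbolize(x, wsmi_params(k = k, tau = tau)),
                   symbolize_oracle(x, k, tau),
                   info = sprintf("k=%d tau=%d", k, tau))
    }
  }
  expect_error(symbolize(rnorm(5), wsmi_params(k = 3, tau = 8)), "too short")
})

test_that("wSMI is zero for identical inputs and matches the joint-count oracle", {
  p <- wsmi_params()
  set.seed(13)
  x <- rnorm(1000)
  expect_equal(wsmi_pair(x, x, p), 0)
  # brute-force oracle equivalence on short random pairs
  for (i in 1:20) {
    a <- rnorm(30 + i)
    b <- rnorm(30 + i)
    expect_equal(wsmi_pair(a, b, wsmi_params(k = 3, tau = 2)),
                 wsmi_oracle(a, b, 3, 2), tolerance = 1e-12)
  }
  # hand-sized toy pair with partial pattern overlap
  a <- c(1, 2, 3, 1, 0, 2, 4, 1, 3, 2)
  b <- c(a[3:10], 1, 0)             # a delayed: some patterns coincide
  expect_equal(wsmi_pair(a, b, wsmi_params(k = 3, tau = 1)),
               wsmi_oracle(a, b, 3, 1), tolerance = 1e-12)
  # independent long sequences: near zero
  set.seed(14)
  v <- wsmi_pair(rnorm(5000), rnorm(5000), p)
  expect_lt(abs(v), 0.02)
  # degenerate single-symbol input
  expect_warning(z <- wsmi_pair(1:50, rnorm(50), wsmi_params(tau = 1)), "degenerate")
  expect_equal(z, 0)
})

test_that("wSMI is symmetric and invariant under monotone transformations", {
  set.seed(15)
  p <- wsmi_params(k = 3, tau = 2)
  for (i in 1:10) {
    x <- rnorm(200)
    y <- 0.5 * x + rnorm(200)
    base <- wsmi_pair(x, y, p)
    expect_equal(wsmi_pair(y, x, p), base, tolerance = 1e-12)
    expect_equal(wsmi_pair(exp(x), y, p), base, tolerance = 1e-12)
    expect_equal(wsmi_pair(x, y^3 + 2 * y, p), base, tolerance = 1e-12)
  }
})

test_that("imaginary coherency nulls common-source signals and detects
           quadrature coupling", {
  fs <- 500
  set.seed(16)
  x <- as.vector(arima.sim(list(ar = 0.8), 1500))
  theta <- default_bands()$theta
  expect_equal(icoh_pair(x, x, fs, theta), 0, tolerance = 1e-10)
  expect_equal(icoh_pair(x, 2 * x, fs, theta), 0, tolerance = 1e-10)

  # 90-degree-shifted narrowband pair: strong imaginary coherency
  t <- (0:1499) / fs
  f0 <- 3
  a <- sin(2 * pi * f0 * t)
  b <- cos(2 * pi * f0 * t)
  vals <- replicate(10, {
    icoh_pair(a + 0.3 * rnorm(1500), b + 0.3 * rnorm(1500), fs,
              band_definition("theta", 2, 4))
  })
  expect_gt(mean(vals), 0.5)
  # bounded in [0, 1]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(icoh_pair(rep(0, 1500), rnorm(1500), fs, theta), "zero")
})

test_that("connectivity matrices are symmetric, equivariant, and reduce to the
           lower-triangle mean", {
  set.seed(17)
  fs <- 500
  block <- matrix(rnorm(4 * 1500), 4, 1500,
                  dimnames = list(paste0("C", 1:4), NULL))
  for (meas in c("icoh", "wsmi")) {
    blk <- if (meas == "wsmi") block[, 1:600] else block
    m <- connectivity_matrix(blk, meas, fs = fs)
    expect_true(all(is.na(diag(m$values))))
    expect_equal(m$values, t(m$values))
    # permutation equivariance
    perm <- c(3, 1, 4, 2)
    mp <- connectivity_matrix(blk[perm, ], meas, fs = fs)
    expect_equal(mp$values, m$values[perm, perm], tolerance = 1e-12)
    # lower- and upper-triangle means agree
    expect_equal(reduce_matrix(m), mean(t(m$values)[lower.tri(m$values)]))
  }
  # identical channels: icoh off-diagonal 0
  two <- rbind(block[1, ], block[1, ])
  m2 <- connectivity_matrix(two, "icoh", fs = fs)
  expect_equal(m2$values[2, 1], 0, tolerance = 1e-10)
  # plain-number reductions
  v <- matrix(0.4, 3, 3); diag(v) <- NA
  expect_equal(reduce_matrix(v), 0.4)
  v[lower.tri(v)] <- c(0.1, 0.2, 0.3)
  expect_equal(reduce_matrix(v), 0.2)
  expect_error(connectivity_matrix(block[1, , drop = FALSE], "icoh", fs = fs),
               "2 channels")
})

test_that("a planted coupled pair stands out of the connectivity null", {
  set.seed(18)
  fs <- 500
  t <- (0:1499) / fs
  n_null <- 40
  carrier <- sin(2 * pi * 3 * t)
  make_block <- function(coupled) {
    ch1 <- carrier + 0.5 * rnorm(1500)
    ch2 <- if (coupled) cos(2 * pi * 3 * t) + 0.5 * rnorm(1500) else rnorm(1500)
    ch3 <- rnorm(1500)
    rbind(ch1, ch2, ch3)
  }
  obs <- connectivity_matrix(make_block(TRUE), "icoh", fs = fs)$values[2, 1]
  null_vals <- replicate(n_null,
    connectivity_matrix(make_block(FALSE), "icoh", fs = fs)$values[2, 1])
  expect_gt(obs, quantile(null_vals, 0.95))
})
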