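make_blobs <- function(n_per = 200, d = 7, sep = 6, sd = 0.5, seed = 20) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per, d),
             matrix(rnorm(n_per * d, sep, sd), n_per, d))
  colnames(x) <- c("Ptheta", "Pbeta", "SEF95", "ERR", "LZC", "iCOHtheta", "wSMI")
  list(x = x, labels = rep(1:2, each = n_per))
}

test_that("FCM memberships are valid, symmetric and sharp where they must be", {
  blobs <- make_blobs()
  fit <- fcm_fit(blobs$x, cluster_config(seed = 5))
  expect_equal(rowSums(fit$memberships), rep(1, nrow(blobs$x)), tolerance = 1e-9)
  expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))

  # well-separated blobs: >= 99% of points majority-assigned to their blob
  assign_to <- apply(fit$memberships, 1, which.max)
  # match fitted clusters to generating blobs by centroid proximity
  c1 <- which.min(rowSums(fit$centroids^2))
  mapped <- ifelse(assign_to == c1, 1, 2)
  expect_gt(mean(mapped == blobs$labels), 0.99)

  # a point coincident with a centroid has membership 1 there
  u <- fcm_memberships(fit$centroids[1, , drop = FALSE], fit$centroids)
  expect_equal(u[1, 1], 1)
  # equidistant point: (0.5, 0.5) by symmetry
  centres <- rbind(rep(0, 7), rep(1, 7))
  u2 <- fcm_memberships(matrix(0.5, 1, 7), centres)
  expect_equal(as.vector(u2), c(0.5, 0.5))
})

test_that("FCM agrees with an independent fuzzy c-means implementation", {
  skip_if_not_installed("e1071")
  blobs <- make_blobs(n_per = 150, sep = 4)
  fit <- fcm_fit(blobs$x, cluster_config(seed = 6))
  set.seed(6)
  ref <- e1071::cmeans(blobs$x, centers = 2, m = 2, iter.max = 200)
  # centroids agree up to label order
  ord_fit <- order(rowMeans(fit$centroids))
  ord_ref <- order(rowMeans(ref$centers))
  expect_equal(unname(fit$centroids[ord_fit, ]),
               unname(ref$centers[ord_ref, ]), tolerance = 0.02)
  expect_equal(unname(fit$memberships[, ord_fit]),
               unname(ref$membership[, ord_ref]), tolerance = 0.02)
})

test_that("GMM posteriors obey symmetry, sharpness and recover parameters", {
  # symmetric two-component mixture: midpoint posterior is (0.5, 0.5)
  means <- rbind(rep(-2, 3), rep(2, 3))
  covs <- list(diag(3), diag(3))
  post_mid <- gmm_posterior(matrix(0, 1, 3), means, covs)
  expect_equal(as.vector(post_mid), c(0.5, 0.5))
  # point at a component mean with separation >> spread: posterior > 0.99
  post_at <- gmm_posterior(means[1, , drop = FALSE], means, covs)
  expect_gt(post_at[1, 1], 0.99)

  # parameter recovery within 3 standard errors on simulated data
  set.seed(21)
  n <- 600
  mu1 <- c(0, 0); mu2 <- c(4, 3)
  x <- rbind(matrix(rnorm(n * 2, sd = 1), n, 2) + rep(mu1, each = n),
             matrix(rnorm(n * 2, sd = 1), n, 2) + rep(mu2, each = n))
  fit <- gmm_fit(x, cluster_config(seed = 22))
  expect_equal(rowSums(fit$memberships), rep(1, 2 * n), tolerance = 1e-9)
  ord <- order(fit$centroids[, 1])
  se <- 1 / sqrt(n)
  expect_lt(max(abs(fit$centroids[ord[1], ] - mu1)), 3 * se)
  expect_lt(max(abs(fit$centroids[ord[2], ] - mu2)), 3 * se)

  # package posterior evaluation matches the fitted responsibilities
  z <- gmm_posterior(x, fit$centroids, fit$model_params$covs,
                     fit$model_params$weights)
  expect_equal(z, unname(fit$memberships), tolerance = 1e-6)
})

test_that("conscious-cluster identification follows the higher-centroid rule", {
  mk <- function(c1, c2) {
    u <- matrix(0.5, 4, 2)
    p <- ecogstate:::new_soft_partition("fcm", u, rbind(c1, c2))
    identify_conscious(p)
  }
  expect_equal(mk(rep(0.2, 7), rep(0.8, 7))$conscious_index, 2L)
  expect_equal(mk(rep(0.8, 7), rep(0.2, 7))$conscious_index, 1L)
  # mixed centroid: higher on 6 of 7 coordinates wins on the mean
  hi <- c(rep(0.9, 6), 0.1)
  expect_equal(mk(hi, rep(0.3, 7))$conscious_index, 1L)
  # exact mean tie broken by the Pbeta coordinate (position 2)
  a <- c(0.9, 0.1, rep(0.5, 5))
  b <- c(0.1, 0.9, rep(0.5, 5))
  expect_equal(mk(a, b)$conscious_index, 2L)
  expect_error(mk(rep(0.5, 7), rep(0.5, 7)), "degenerate")
})

test_that("the ensemble is the element-wise mean and respects bounds", {
  tmes <- as.POSIXct("2022-06-01", tz = "UTC") + 0:9
  t1 <- structure(list(times = tmes, values = seq(0, 0.9, by = 0.1), method = "fcm"),
                  class = "consciousness_trace")
  t2 <- structure(list(times = tmes, values = rep(c(0.4, 0.6), 5), method = "gmm"),
                  class = "consciousness_trace")
  e <- ensemble_trace(t1, t2)
  expect_equal(e$values, (t1$values + t2$values) / 2)
  expect_equal(ensemble_trace(t2, t1)$values, e$values)
  expect_equal(ensemble_trace(t1, t1)$values, t1$values)
  expect_true(all(e$values >= pmin(t1$values, t2$values) &
                  e$values <= pmax(t1$values, t2$values)))
  t3 <- t2
  t3$times <- tmes + 5
  expect_error(ensemble_trace(t1, t3), "aligned")
})

test_that("pre-defined centres reproduce the membership formula without fitting", {
  set.seed(23)
  centres <- rbind(runif(7), runif(7) + 1)
  x <- matrix(runif(50 * 7), 50, 7)
  feats <- list(normalized = x, times = as.POSIXct("2022-06-01", tz = "UTC") + 1:50,
                names = c("Ptheta", "Pbeta", "SEF95", "ERR", "LZC", "iCOHtheta", "wSMI"))
  class(feats) <- "ecog_features"
  cfg <- cluster_config(predefined_centroids = centres)
  res <- predefined_partition(feats, cfg)
  # membership formula oracle: u_ic = 1 / sum_k (d_ic/d_ik)^2 for m = 2
  d1 <- sqrt(rowSums((x - matrix(centres[1, ], 50, 7, byrow = TRUE))^2))
  d2 <- sqrt(rowSums((x - matrix(centres[2, ], 50, 7, byrow = TRUE))^2))
  u1 <- 1 / (1 + (d1 / d2)^2)
  ci <- res$fcm$conscious_index
  expect_equal(res$trace$values, if (ci == 1) u1 else 1 - u1, tolerance = 1e-12)
  expect_equal(res$trace$method, "predefined")

  # a point at a predefined centre gets membership 1
  feats1 <- feats
  feats1$normalized <- centres[2, , drop = FALSE]
  feats1$times <- feats$times[1]
  r1 <- predefined_partition(feats1, cfg)
  expect_equal(max(r1$fcm$memberships), 1)

  # symmetric centres, midpoint: (0.5, 0.5)
  cfg2 <- cluster_config(predefined_centroids = rbind(rep(0, 7), rep(1, 7)))
  feats2 <- feats1
  feats2$normalized <- matrix(0.5, 1, 7)
  r2 <- predefined_partition(feats2, cfg2)
  expect_equal(as.vector(r2$fcm$memberships), c(0.5, 0.5))
  expect_error(predefined_partition(feats, cluster_config()), "missing")
})

test_that("pre-defined GMM leg matches fixed-parameter posteriors and ensembles", {
  set.seed(24)
  x <- matrix(runif(30 * 7), 30, 7)
  feats <- list(normalized = x, times = as.POSIXct("2022-06-01", tz = "UTC") + 1:30,
                names = c("Ptheta", "Pbeta", "SEF95", "ERR", "LZC", "iCOHtheta", "wSMI"))
  class(feats) <- "ecog_features"
  g <- list(means = rbind(rep(0.2, 7), rep(0.8, 7)),
            covs = list(diag(0.05, 7), diag(0.05, 7)),
            weights = c(0.5, 0.5))
  cfg <- cluster_config(predefined_centroids = g$means, predefined_gmm = g)
  res <- predefined_partition(feats, cfg)
  u <- fcm_memberships(x, g$means)
  z <- gmm_posterior(x, g$means, g$covs, g$weights)
  ci_f <- res$fcm$conscious_index
  ci_g <- res$gmm$conscious_index
  expect_equal(res$trace$values, (u[, ci_f] + z[, ci_g]) / 2, tolerance = 1e-12)
})

test_that("feature-trace Spearman correlations match the rank-Pearson oracle", {
  set.seed(25)
  x <- matrix(rnorm(20 * 7), 20, 7)
  feats <- list(raw = x, names = c("Ptheta", "Pbeta", "SEF95", "ERR", "LZC",
                                   "iCOHtheta", "wSMI"))
  class(feats) <- "ecog_features"
  tr <- structure(list(values = rnorm(20), method = "ensemble"),
                  class = "consciousness_trace")
  out <- feature_correlations(feats, list(ensemble = tr))
  for (j in 1:7) {
    expect_equal(out$rho_ensemble[j], spearman_oracle(x[, j], tr$values),
                 tolerance = 1e-12)
  }
  # perfect monotone relations
  tr2 <- structure(list(values = x[, 3], method = "t"), class = "consciousness_trace")
  out2 <- feature_correlations(feats, list(t = tr2))
  expect_equal(out2$rho_t[3], 1)
  tr3 <- structure(list(values = -x[, 3], method = "t"), class = "consciousness_trace")
  expect_equal(feature_correlations(feats, list(t = tr3))$rho_t[3], -1)
  # constant column flagged as undefined
  featsc <- feats
  featsc$raw[, 5] <- 1
  expect_warning(outc <- feature_correlations(featsc, list(t = tr2)), "constant")
  expect_true(is.na(outc$rho_t[5]))
})
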