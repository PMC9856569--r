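#' Clustering configuration
#'
#' Parameters shared by the fuzzy c-means and Gaussian-mixture legs:
#' two clusters, fuzzifier `m = 2`, at most 1000 iterations, and a minimum
#' objective improvement of 1e-5 between consecutive iterations.
#'
#' @param n_clusters number of clusters (the method is defined for 2).
#' @param m FCM fuzzifier (> 1).
#' @param max_iter iteration cap for both algorithms.
#' @param tol minimum objective/log-likelihood improvement.
#' @param seed integer seed driving FCM membership initialisation and any
#'   stochastic step.
#' @param gmm_covariance mclust model name for the component covariances
#'   (`"VVV"` = full, per-component).
#' @param predefined_centroids optional 2 x 7 matrix of FCM cluster centres
#'   for the no-refit mode; see [predefined_partition()].
#' @param predefined_gmm optional list(`means` 2 x 7, `covs` list of two 7 x 7,
#'   `weights` length-2) for the no-refit GMM leg.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(n_clusters = 2, m = 2, max_iter = 1000, tol = 1e-5,
                           seed = 1L, gmm_covariance = "VVV",
                           predefined_centroids = NULL, predefined_gmm = NULL) {
  if (m <= 1) stop("fuzzifier `m` must be > 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  structure(list(n_clusters = as.integer(n_clusters), m = m,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), gmm_covariance = gmm_covariance,
                 predefined_centroids = predefined_centroids,
                 predefined_gmm = predefined_gmm),
            class = "cluster_config")
}

#' Fuzzy c-means soft clustering
#'
#' Standard FCM alternating updates: memberships
#' `u_ic = 1 / sum_k (d_ic / d_ik)^(2/(m-1))`, centres as the
#' `u^m`-weighted data means. Iterations stop when the objective
#' `J = sum u^m d^2` improves by less than `tol` or at `max_iter` (with a
#' warning). Initialisation is a seeded random membership matrix.
#'
#' @param x numeric data matrix (rows = observations); typically the
#'   `normalized` field of an `ecog_features`.
#' @param cfg a [cluster_config()].
#' @return A `soft_partition`: `method`, `memberships` (rows sum to 1),
#'   `centroids` (clusters x features), `objective`, `iterations`,
#'   `conscious_index` (`NA` until [identify_conscious()]).
#' @export
fcm_fit <- function(x, cfg = cluster_config()) {
  x <- as.matrix(x)
  n <- nrow(x); k <- cfg$n_clusters
  if (n < k) stop("need at least as many points as clusters", call. = FALSE)
  set.seed(cfg$seed)
  u <- matrix(stats::runif(n * k), n, k)
  u <- u / rowSums(u)
  J_prev <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    um <- u^cfg$m
    centres <- t(um) %*% x / colSums(um)
    d2 <- sq_dist(x, centres)
    u <- memberships_from_dist(d2, cfg$m)
    J <- sum((u^cfg$m) * d2)
    if (is.finite(J_prev) && abs(J_prev - J) < cfg$tol) break
    if (iter >= cfg$max_iter) {
      warning("FCM did not converge within max_iter; returning current partition")
      break
    }
    J_prev <- J
  }
  new_soft_partition("fcm", u, centres,
                     model_params = list(m = cfg$m, objective = J, iterations = iter))
}

# squared Euclidean distances, points x centres
sq_dist <- function(x, centres) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centres))) +
    outer(rep(1, nrow(x)), rowSums(centres^2)) - 2 * x %*% t(centres)
  pmax(d2, 0)
}

# FCM membership formula at given squared distances; a point coincident
# with a centre gets full membership there (the update-rule limit)
memberships_from_dist <- function(d2, m) {
  w <- d2^(-1 / (m - 1))
  u <- w / rowSums(w)
  zero_rows <- which(apply(d2 <= .Machine$double.eps, 1L, any))
  for (i in zero_rows) {
    z <- d2[i, ] <= .Machine$double.eps
    u[i, ] <- as.numeric(z) / sum(z)
  }
  u
}

#' Evaluate FCM memberships against fixed cluster centres
#'
#' The FCM membership formula with no fitting — the core of the
#' pre-defined-centres mode.
#'
#' @param x data matrix (rows = observations).
#' @param centres clusters x features matrix.
#' @param m fuzzifier.
#' @return Memberships matrix (rows sum to 1).
#' @export
fcm_memberships <- function(x, centres, m = 2) {
  memberships_from_dist(sq_dist(as.matrix(x), as.matrix(centres)), m)
}

#' Gaussian-mixture soft clustering
#'
#' Two-component Gaussian mixture fitted by EM (via mclust), full
#' per-component covariances by default; memberships are the posterior
#' responsibilities. The iteration cap and tolerance mirror the FCM leg.
#'
#' @param x data matrix (rows = observations).
#' @param cfg a [cluster_config()].
#' @return A `soft_partition` with `method = "gmm"`; `centroids` are the
#'   component means, `model_params` carries weights and covariances.
#' @export
gmm_fit <- function(x, cfg = cluster_config()) {
  x <- as.matrix(x)
  set.seed(cfg$seed)
  ctrl <- mclust::emControl(itmax = cfg$max_iter, tol = cfg$tol)
  cl <- stats::kmeans(x, cfg$n_clusters, nstart = 10)$cluster
  mstep_f <- getExportedValue("mclust", paste0("mstep", cfg$gmm_covariance))
  em_f <- getExportedValue("mclust", paste0("em", cfg$gmm_covariance))
  ms <- mstep_f(data = x, z = mclust::unmap(cl))
  fit <- em_f(data = x, parameters = ms$parameters, control = ctrl)
  if (is.null(fit$z) || anyNA(fit$z)) stop("GMM fit failed (EM degenerate)", call. = FALSE)
  means <- t(fit$parameters$mean)
  covs <- lapply(seq_len(cfg$n_clusters), function(g) fit$parameters$variance$sigma[, , g])
  new_soft_partition("gmm", fit$z, means,
                     model_params = list(weights = fit$parameters$pro,
                                         covs = covs,
                                         loglik = utils::tail(fit$loglik, 1)))
}

#' Posterior responsibilities under fixed Gaussian-mixture parameters
#'
#' @param x data matrix.
#' @param means components x features matrix.
#' @param covs list of covariance matrices (one per component).
#' @param weights mixing proportions.
#' @param reg diagonal regularisation added to a singular covariance.
#' @return Posterior matrix (rows sum to 1).
#' @export
gmm_posterior <- function(x, means, covs, weights = NULL, reg = 1e-6) {
  x <- as.matrix(x)
  G <- nrow(means)
  if (is.null(weights)) weights <- rep(1 / G, G)
  logd <- vapply(seq_len(G), function(g) {
    S <- covs[[g]]
    ch <- tryCatch(chol(S), error = function(e) {
      chol(S + diag(reg, nrow(S)))
    })
    centred <- sweep(x, 2L, means[g, ])
    q <- colSums(backsolve(ch, t(centred), transpose = TRUE)^2)
    -0.5 * q - sum(log(diag(ch))) - 0.5 * ncol(x) * log(2 * pi) + log(weights[g])
  }, numeric(nrow(x)))
  logd <- matrix(logd, nrow = nrow(x))
  mx <- apply(logd, 1L, max)
  p <- exp(logd - mx)
  p / rowSums(p)
}

new_soft_partition <- function(method, memberships, centroids, model_params = list(),
                               conscious_index = NA_integer_) {
  structure(list(method = method, memberships = unname(memberships),
                 centroids = unname(as.matrix(centroids)),
                 model_params = model_params,
                 conscious_index = conscious_index),
            class = "soft_partition")
}

#' @export
print.soft_partition <- function(x, ...) {
  cat(sprintf("<soft_partition> %s: %d points, %d clusters (conscious = %s)\n",
              x$method, nrow(x$memberships), ncol(x$memberships),
              ifelse(is.na(x$conscious_index), "?", x$conscious_index)))
  invisible(x)
}

#' Identify the conscious cluster of a fitted partition
#'
#' Under the working hypothesis that higher feature values accompany higher
#' consciousness, the conscious cluster is the one whose centroid has the
#' larger mean over the (normalised) feature coordinates; an exact tie is
#' broken towards the larger beta-power coordinate, and a tie on both is an
#' error (degenerate clustering).
#'
#' @param partition a `soft_partition` on the canonical 7-feature space.
#' @return The partition with `conscious_index` set.
#' @export
identify_conscious <- function(partition) {
  cm <- rowMeans(partition$centroids)
  if (abs(diff(cm)) > 0) {
    idx <- which.max(cm)
  } else {
    pb <- partition$centroids[, match("Pbeta", FEATURE_NAMES)]
    if (abs(diff(pb)) == 0) {
      stop("degenerate clustering: centroids tie on mean and on Pbeta", call. = FALSE)
    }
    idx <- which.max(pb)
  }
  partition$conscious_index <- idx
  partition
}

#' Consciousness trace of a partition
#'
#' Per-window membership degree to the conscious cluster.
#'
#' @param partition a `soft_partition` with `conscious_index` set (run
#'   [identify_conscious()] first).
#' @param times POSIXct window times.
#' @return A `consciousness_trace`: `times`, `values` in `[0, 1]`, `method`.
#' @export
conscious_trace <- function(partition, times) {
  if (is.na(partition$conscious_index)) {
    partition <- identify_conscious(partition)
  }
  structure(list(times = times,
                 values = partition$memberships[, partition$conscious_index],
                 method = partition$method),
            class = "consciousness_trace")
}

#' Average-ensemble of two consciousness traces
#'
#' Element-wise mean of two membership traces; the standard average-ensemble
#' rule for combining soft partitions.
#'
#' @param p1,p2 `consciousness_trace`s on identical time grids.
#' @return A `consciousness_trace` with `method = "ensemble"`.
#' @export
ensemble_trace <- function(p1, p2) {
  if (length(p1$values) != length(p2$values) ||
      any(abs(as.numeric(p1$times) - as.numeric(p2$times)) > 1e-6)) {
    stop("traces are not aligned on the same time grid", call. = FALSE)
  }
  structure(list(times = p1$times, values = (p1$values + p2$values) / 2,
                 method = "ensemble"),
            class = "consciousness_trace")
}

#' @export
print.consciousness_trace <- function(x, ...) {
  cat(sprintf("<consciousness_trace> %s: %d windows, mean %.4f\n",
              x$method, length(x$values), mean(x$values)))
  invisible(x)
}

#' Consciousness trace from pre-defined cluster parameters
#'
#' Evaluates memberships against fixed FCM centres (and, when provided,
#' posteriors under a fixed Gaussian-mixture parameter set) with no fitting,
#' then ensembles the legs. Useful when cluster parameters from a reference
#' dataset are applied to a new recording.
#'
#' @param feats an `ecog_features`.
#' @param cfg a [cluster_config()] with `predefined_centroids` (2 x 7) and
#'   optionally `predefined_gmm`.
#' @return A list with `fcm`, `gmm` (or `NULL`), and `trace` (the ensemble
#'   when both legs exist, otherwise the FCM trace re-tagged
#'   `"predefined"`).
#' @export
predefined_partition <- function(feats, cfg) {
  centres <- cfg$predefined_centroids
  if (is.null(centres)) stop("`predefined_centroids` missing from config", call. = FALSE)
  centres <- as.matrix(centres)
  if (ncol(centres) != 7L) stop("pre-defined centroids must be 2 x 7", call. = FALSE)
  u <- fcm_memberships(feats$normalized, centres, cfg$m)
  p_fcm <- identify_conscious(
    new_soft_partition("fcm", u, centres, list(m = cfg$m, predefined = TRUE)))
  t_fcm <- conscious_trace(p_fcm, feats$times)
  p_gmm <- NULL
  if (!is.null(cfg$predefined_gmm)) {
    g <- cfg$predefined_gmm
    z <- gmm_posterior(feats$normalized, as.matrix(g$means), g$covs, g$weights)
    p_gmm <- identify_conscious(
      new_soft_partition("gmm", z, as.matrix(g$means), list(predefined = TRUE)))
  }
  if (!is.null(p_gmm)) {
    tr <- ensemble_trace(t_fcm, conscious_trace(p_gmm, feats$times))
    tr$method <- "predefined"
    list(fcm = p_fcm, gmm = p_gmm, trace = tr)
  } else {
    t_fcm$method <- "predefined"
    list(fcm = p_fcm, gmm = NULL, trace = t_fcm)
  }
}

#' Fit both clustering legs and build the ensemble trace
#'
#' Convenience wrapper: FCM and GMM on the normalised features, conscious
#' cluster identified in each, and the average ensemble of the two traces.
#'
#' @param feats an `ecog_features`.
#' @param cfg a [cluster_config()].
#' @return List with `fcm`, `gmm` (`soft_partition`s), `trace_fcm`,
#'   `trace_gmm`, `trace` (ensemble).
#' @export
cluster_features <- function(feats, cfg = cluster_config()) {
  p_fcm <- identify_conscious(fcm_fit(feats$normalized, cfg))
  p_gmm <- identify_conscious(gmm_fit(feats$normalized, cfg))
  t_fcm <- conscious_trace(p_fcm, feats$times)
  t_gmm <- conscious_trace(p_gmm, feats$times)
  list(fcm = p_fcm, gmm = p_gmm, trace_fcm = t_fcm, trace_gmm = t_gmm,
       trace = ensemble_trace(t_fcm, t_gmm))
}
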