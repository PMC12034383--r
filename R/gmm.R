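#' Gaussian-mixture clustering of a phasor distribution
#'
#' Fits a `K`-component Gaussian mixture to the per-pixel phasor coordinates
#' (the `(G, S)` pair of each selected harmonic, concatenated) by
#' expectation–maximisation with full covariances. The fitted model can be
#' applied to other datasets ([apply_gmm()]), persisted as JSON
#' ([write_gmm()]), and summarised as confidence ellipses
#' ([cluster_ellipse()]).
#'
#' Initialisation uses the user-supplied means (with identity-scaled
#' covariances) when given, otherwise k-means++ seeding under the fixed
#' `seed`; the seed is recorded in the model so fits are reproducible.
#' Convergence: relative log-likelihood change below `tol` or `max_iter`
#' iterations; a diagonal floor keeps covariances positive definite. The
#' log-likelihood is non-decreasing at every EM iteration (tracked in
#' `fit_log$loglik_trace`).
#'
#' @param x A `phasor_field`, or a numeric matrix of observations (rows =
#'   points) for direct fitting.
#' @param k Number of clusters (`>= 1`, at most the number of points).
#' @param harmonics Harmonics whose coordinates form the feature space
#'   (default 1, i.e. 2-D).
#' @param init_means Optional `k x d` matrix of initial cluster means.
#' @param seed Integer RNG seed (recorded in the model).
#' @param max_iter,tol,cov_floor EM settings: iteration cap (500), relative
#'   log-likelihood tolerance (1e-7), diagonal covariance floor (1e-8).
#' @param colors Cluster colours (defaults to a qualitative palette).
#' @return A `gmm_model`: `weights`, `means` (`k x d`), `covariances`
#'   (`d x d x k`), `colors`, `feature_harmonics`, and
#'   `fit_log` (`loglik`, `loglik_trace`, `iterations`, `seed`, `converged`).
#' @export
fit_gmm <- function(x, k, harmonics = 1L, init_means = NULL, seed = 1L,
                    max_iter = 500L, tol = 1e-7, cov_floor = 1e-8,
                    colors = NULL) {
  X <- gmm_features(x, harmonics)
  n <- nrow(X)
  d <- ncol(X)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (n < k) stop("fewer valid pixels than clusters", call. = FALSE)

  if (is.null(init_means)) {
    means <- with_seed(seed, kmeanspp(X, k))
  } else {
    means <- matrix(as.numeric(init_means), k, d)
  }
  # initial covariances: identity scaled to the average feature variance
  s2 <- mean(apply(X, 2L, stats::var))
  if (!is.finite(s2) || s2 <= 0) s2 <- cov_floor
  covs <- array(0, c(d, d, k))
  for (j in seq_len(k)) covs[, , j] <- diag(s2, d)
  weights <- rep(1 / k, k)

  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  logdens <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      logdens[, j] <- log(weights[j]) + dmvnorm_log(X, means[j, ], covs[, , j])
    }
    mx <- apply(logdens, 1L, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    new_ll <- sum(lse)
    resp <- exp(logdens - lse)
    nk <- colSums(resp)
    weights <- nk / n
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * X) / nk[j]
      Xc <- sweep(X, 2L, mu)
      sig <- crossprod(Xc * resp[, j], Xc) / nk[j] + diag(cov_floor, d)
      means[j, ] <- mu
      covs[, , j] <- sig
    }
    trace <- c(trace, new_ll)
    if (is.finite(loglik) &&
        abs(new_ll - loglik) <= tol * abs(loglik)) {
      loglik <- new_ll
      converged <- TRUE
      break
    }
    loglik <- new_ll
  }
  if (is.null(colors)) {
    colors <- grDevices::hcl.colors(max(k, 2L), "Dark 3")[seq_len(k)]
  }
  structure(
    list(k = k, weights = weights, means = means, covariances = covs,
         colors = colors,
         feature_harmonics = as.integer(harmonics),
         fit_log = list(loglik = loglik, loglik_trace = trace,
                        iterations = it, seed = seed, converged = converged)),
    class = "gmm_model"
  )
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> K=%d, %dd features (harmonics {%s}), logLik %.4f after %d EM iterations\n",
              x$k, ncol(x$means), paste(x$feature_harmonics, collapse = ","),
              x$fit_log$loglik, x$fit_log$iterations))
  for (j in seq_len(x$k)) {
    cat(sprintf("  %d: pi=%.3f, mean (%s)\n", j, x$weights[j],
                paste(sprintf("%.4f", x$means[j, ]), collapse = ", ")))
  }
  invisible(x)
}

# Feature matrix: valid-pixel (G,S) per harmonic, concatenated.
gmm_features <- function(x, harmonics) {
  if (inherits(x, "phasor_field")) {
    cols <- lapply(harmonics, function(n) {
      sl <- harmonic_slice(x, n)
      cbind(sl$G[x$valid], sl$S[x$valid])
    })
    do.call(cbind, cols)
  } else {
    as.matrix(x)
  }
}

# log-density of a multivariate normal via Cholesky
dmvnorm_log <- function(X, mu, sigma) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * ncol(X) * log(2 * pi)
}

# k-means++ seeding followed by a short Lloyd refinement
kmeanspp <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- colSums((t(X) - centers[1L, ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, colSums((t(X) - centers[j, ])^2))
    }
    km <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = 25L, algorithm = "Lloyd")
    )
    centers <- km$centers
  }
  centers
}

# Evaluate under a temporary seed, restoring RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Apply a fitted Gaussian mixture to a phasor field
#'
#' Runs the E-step of the fitted model on the field's valid pixels:
#' posterior probabilities per cluster (summing to 1 at every valid pixel)
#' and the hard segmentation by maximum posterior (ties resolved to the
#' lowest cluster index).
#'
#' @param model A `gmm_model`.
#' @param field A `phasor_field` covering the model's feature harmonics.
#' @return A `gmm_segmentation`: `posterior` (`H x W x K`), `labels`
#'   (`H x W` integer, 0 = invalid), `colors`, `valid`.
#' @export
apply_gmm <- function(model, field) {
  stopifnot(inherits(model, "gmm_model"), inherits(field, "phasor_field"))
  if (!all(model$feature_harmonics %in% field$harmonics)) {
    stop("field does not provide the model's feature harmonics", call. = FALSE)
  }
  X <- gmm_features(field, model$feature_harmonics)
  n <- nrow(X)
  k <- model$k
  logdens <- matrix(0, n, k)
  for (j in seq_len(k)) {
    logdens[, j] <- log(model$weights[j]) +
      dmvnorm_log(X, model$means[j, ], model$covariances[, , j])
  }
  mx <- apply(logdens, 1L, max)
  lse <- mx + log(rowSums(exp(logdens - mx)))
  resp <- exp(logdens - lse)
  d <- dim(field$valid)
  posterior <- array(NA_real_, c(d[1L], d[2L], k))
  labels <- matrix(0L, d[1L], d[2L])
  hard <- max.col(resp, ties.method = "first")
  labels[field$valid] <- hard
  for (j in seq_len(k)) {
    m <- matrix(NA_real_, d[1L], d[2L])
    m[field$valid] <- resp[, j]
    posterior[, , j] <- m
  }
  structure(
    list(posterior = posterior, labels = labels,
         colors = model$colors, valid = field$valid),
    class = "gmm_segmentation"
  )
}

#' Confidence ellipse of a Gaussian cluster
#'
#' The level-`level` ellipse of cluster `component` in a 2-D display plane:
#' for a bivariate Gaussian the squared Mahalanobis radius is
#' chi-square(2)-distributed, so the ellipse covering a fraction `level` of
#' the cluster's mass has Mahalanobis radius `r = sqrt(-2*log(1 - level))`.
#' Semi-axes are `r * sqrt(eigenvalues)` of the covariance, oriented along
#' its eigenvectors. The default display level is 0.88.
#'
#' @param model A `gmm_model`.
#' @param component Cluster index.
#' @param level Coverage fraction in (0, 1); default 0.88.
#' @param harmonic For models fitted on several harmonics, which harmonic's
#'   `(G, S)` plane to display (default the first).
#' @return A `cluster_ellipse`: `center`, `semi_axes`, `angle` (radians),
#'   `level`, `mahalanobis_radius`, and the 2x2 `covariance`.
#' @export
cluster_ellipse <- function(model, component = 1L, level = 0.88,
                            harmonic = NULL) {
  stopifnot(inherits(model, "gmm_model"))
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  if (is.null(harmonic)) harmonic <- model$feature_harmonics[1L]
  hj <- match(harmonic, model$feature_harmonics)
  if (is.na(hj)) stop("harmonic not in the model's feature space", call. = FALSE)
  dims <- (hj - 1L) * 2L + 1:2
  mu <- model$means[component, dims]
  sig <- model$covariances[dims, dims, component]
  r <- sqrt(-2 * log(1 - level))
  e <- eigen(sig, symmetric = TRUE)
  structure(
    list(center = mu, semi_axes = r * sqrt(e$values),
         angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
         level = level, mahalanobis_radius = r, covariance = sig),
    class = "cluster_ellipse"
  )
}

#' Test points for containment in a cluster ellipse
#'
#' Geometric containment: points are translated to the ellipse centre,
#' rotated by minus the orientation angle, scaled by the semi-axes, and
#' tested against the unit circle. (Independent of the Mahalanobis-distance
#' formulation.)
#'
#' @param ellipse A `cluster_ellipse`.
#' @param points An `n x 2` matrix of (G, S) points.
#' @return Logical vector.
#' @export
points_in_ellipse <- function(ellipse, points) {
  p <- sweep(as.matrix(points), 2L, ellipse$center)
  ca <- cos(-ellipse$angle)
  sa <- sin(-ellipse$angle)
  u <- p[, 1L] * ca - p[, 2L] * sa
  v <- p[, 1L] * sa + p[, 2L] * ca
  (u / ellipse$semi_axes[1L])^2 + (v / ellipse$semi_axes[2L])^2 <= 1
}

#' Persist a Gaussian-mixture model as JSON
#' @param model A `gmm_model`.
#' @param path File path.
#' @return `read_gmm` returns the `gmm_model`; `write_gmm` returns `path`
#'   invisibly.
#' @export
write_gmm <- function(model, path) {
  jsonlite::write_json(
    list(k = model$k, weights = model$weights, means = model$means,
         covariances = lapply(seq_len(model$k),
                              function(j) model$covariances[, , j]),
         colors = model$colors,
         feature_harmonics = model$feature_harmonics,
         fit_log = model$fit_log[c("loglik", "iterations", "seed", "converged")]),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- ncol(x$means)
  covs <- array(0, c(d, d, x$k))
  for (j in seq_len(x$k)) {
    # jsonlite may simplify the list of equal-sized matrices into an array
    covs[, , j] <- if (is.list(x$covariances)) x$covariances[[j]]
                   else x$covariances[j, , ]
  }
  structure(
    list(k = x$k, weights = x$weights, means = x$means, covariances = covs,
         colors = x$colors, feature_harmonics = as.integer(x$feature_harmonics),
         fit_log = as.list(x$fit_log)),
    class = "gmm_model"
  )
}
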