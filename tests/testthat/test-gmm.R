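# synthetic Gaussian phasor clusters with known parameters
make_clusters <- function(centers, sigma = 0.02, n = 2000L, seed = 101L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    cbind(rnorm(n, centers[j, 1], sigma), rnorm(j * 0 + n, centers[j, 2], sigma))
  }))
  X[sample(nrow(X)), ]
}

test_that("a single-component fit is the sample mean and covariance", {
  X <- make_clusters(matrix(c(0.4, 0.3), 1), sigma = 0.05, n = 3000L)
  m <- fit_gmm(X, k = 1, seed = 1)
  expect_equal(as.vector(m$means), colMeans(X), tolerance = 1e-6)
  n <- nrow(X)
  expect_equal(m$covariances[, , 1],
               stats::cov(X) * (n - 1) / n + diag(1e-8, 2),
               tolerance = 1e-6)
  expect_equal(m$weights, 1)
})

test_that("EM recovers well-separated synthetic clusters and is deterministic", {
  centers <- matrix(c(0.3, 0.4,
                      0.7, 0.3), 2, byrow = TRUE)
  X <- make_clusters(centers, sigma = 0.02, n = 5000L)
  m <- fit_gmm(X, k = 2, seed = 7)
  # permutation-match recovered means to the truth
  perm <- if (sum((m$means[1, ] - centers[1, ])^2) <
              sum((m$means[1, ] - centers[2, ])^2)) 1:2 else 2:1
  expect_lt(max(abs(m$means[perm, ] - centers)), 0.01)
  expect_lt(max(abs(m$weights - 0.5)), 0.02)
  # identical data and seed give an identical model
  m2 <- fit_gmm(X, k = 2, seed = 7)
  expect_identical(m$means, m2$means)
  expect_identical(m$fit_log$loglik, m2$fit_log$loglik)
  # log-likelihood is non-decreasing at every EM iteration
  expect_true(all(diff(m$fit_log$loglik_trace) >= -1e-8 * abs(m$fit_log$loglik)))
})

test_that("user-supplied initial means are honoured and fits agree with mclust", {
  centers <- matrix(c(0.25, 0.45,
                      0.55, 0.25,
                      0.8, 0.35), 3, byrow = TRUE)
  X <- make_clusters(centers, sigma = 0.02, n = 1500L, seed = 23L)
  m <- fit_gmm(X, k = 3, init_means = centers, seed = 1)
  ord <- apply(m$means, 1, function(mu) which.min(colSums((t(centers) - mu)^2)))
  expect_equal(sort(ord), 1:3)
  expect_lt(max(abs(m$means[order(ord), ] - centers)), 0.01)
  skip_if_not_installed("mclust")
  # independent EM implementation as cross-check
  mclustBIC <- mclust::mclustBIC
  mc <- mclust::Mclust(X, G = 3, modelNames = "VVV", verbose = FALSE)
  mc_means <- t(mc$parameters$mean)
  ord2 <- apply(mc_means, 1, function(mu) which.min(colSums((t(centers) - mu)^2)))
  expect_lt(max(abs(m$means[order(ord), ] - mc_means[order(ord2), ])), 0.005)
})

test_that("applying a model yields normalised posteriors and argmax labels", {
  centers <- matrix(c(0.3, 0.4, 0.7, 0.2), 2, byrow = TRUE)
  X <- make_clusters(centers, sigma = 0.02, n = 1000L, seed = 31L)
  m <- fit_gmm(X, k = 2, seed = 3)
  # a field whose pixels sit at the component means
  f <- field_from_coords(matrix(m$means[, 1], 1), matrix(m$means[, 2], 1))
  seg <- apply_gmm(m, f)
  post <- seg$posterior
  expect_equal(post[1, 1, 1] + post[1, 1, 2], 1, tolerance = 1e-12)
  expect_equal(post[1, 2, 1] + post[1, 2, 2], 1, tolerance = 1e-12)
  # a pixel exactly at a well-separated component's mean is assigned to it
  expect_gt(post[1, 1, 1], 0.99)
  expect_gt(post[1, 2, 2], 0.99)
  expect_equal(as.vector(seg$labels), c(1L, 2L))
  # invalid pixels keep label 0
  f$valid[1, 2] <- FALSE
  expect_equal(as.vector(apply_gmm(m, f)$labels), c(1L, 0L))
})

test_that("fitting on a phasor field uses the valid-pixel (G,S) features", {
  set.seed(41)
  G <- matrix(rnorm(900, 0.5, 0.02), 30)
  S <- matrix(rnorm(900, 0.3, 0.02), 30)
  f <- field_from_coords(G, S)
  f$valid[1:5, ] <- FALSE
  m <- fit_gmm(f, k = 1, seed = 1)
  expect_equal(as.vector(m$means),
               c(mean(G[f$valid]), mean(S[f$valid])), tolerance = 1e-6)
  expect_error(fit_gmm(f, k = 10000), "fewer valid pixels")
})

test_that("confidence ellipses use the chi-square Mahalanobis radius", {
  # 2-dof chi-square quantile oracle
  expect_equal(sqrt(-2 * log(1 - 0.88)), sqrt(stats::qchisq(0.88, df = 2)),
               tolerance = 1e-12)
  m <- list(k = 1, weights = 1, means = matrix(c(0.4, 0.3), 1),
            covariances = array(diag(0.01^2, 2), c(2, 2, 1)),
            colors = "red", feature_harmonics = 1L,
            fit_log = list())
  class(m) <- "gmm_model"
  e <- cluster_ellipse(m, 1, level = 0.88)
  expect_equal(e$mahalanobis_radius, 2.0593, tolerance = 1e-4)
  # isotropic covariance -> circle of radius r*sigma
  expect_equal(e$semi_axes, rep(2.0593 * 0.01, 2), tolerance = 1e-4)
  expect_error(cluster_ellipse(m, 1, level = 1.2), "level")
})

test_that("Monte-Carlo ellipse coverage matches the requested level", {
  set.seed(55)
  n <- 1e5
  sigma <- matrix(c(4e-4, 1e-4, 1e-4, 2e-4), 2)
  ch <- chol(sigma)
  X <- matrix(rnorm(2 * n), n) %*% ch
  X <- sweep(X, 2, c(0.45, 0.3), "+")
  m <- fit_gmm(X, k = 1, seed = 1)
  for (level in c(0.5, 0.88, 0.95)) {
    e <- cluster_ellipse(m, 1, level = level)
    frac <- mean(points_in_ellipse(e, X))  # geometric containment route
    se <- sqrt(level * (1 - level) / n)
    expect_lt(abs(frac - level), 3 * se)
  }
})

test_that("models persist through JSON faithfully", {
  X <- make_clusters(matrix(c(0.3, 0.4, 0.7, 0.3), 2, byrow = TRUE),
                     n = 500L, seed = 61L)
  m <- fit_gmm(X, k = 2, seed = 2)
  p <- withr::local_tempfile(fileext = ".json")
  write_gmm(m, p)
  m2 <- read_gmm(p)
  expect_equal(m2$means, m$means, ignore_attr = TRUE)
  expect_equal(m2$covariances, m$covariances, ignore_attr = TRUE)
  expect_equal(m2$weights, m$weights, ignore_attr = TRUE)
  # the reloaded model segments identically
  f <- field_from_coords(matrix(X[1:10, 1], 1), matrix(X[1:10, 2], 1))
  expect_identical(apply_gmm(m, f)$labels, apply_gmm(m2, f)$labels)
})
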