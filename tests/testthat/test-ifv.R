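# small synthetic local-descriptor sets for codebook fitting
make_sift_like <- function(n, d = 128, seed = 1) {
  withr::with_seed(seed, list(descriptors = matrix(runif(n * d), n, d)))
}

test_that("codebook dimensions and determinism", {
  sets <- lapply(1:3, function(i) make_sift_like(300, seed = i))
  cb <- fit_ifv_codebook(sets, pca_dim = 16L, n_components = 8L, seed = 7)
  expect_equal(ncol(cb$pca_basis), 16)
  expect_equal(dim(cb$means), c(8L, 16L))
  expect_equal(dim(cb$variances), c(8L, 16L))
  expect_equal(sum(cb$weights), 1, tolerance = 1e-12)
  expect_true(all(cb$weights >= 0))
  expect_true(all(cb$variances > 0))
  # orthonormal projection columns (no whitening)
  expect_equal(crossprod(cb$pca_basis), diag(16), tolerance = 1e-8,
               ignore_attr = TRUE)
  cb2 <- fit_ifv_codebook(sets, pca_dim = 16L, n_components = 8L, seed = 7)
  expect_identical(cb$means, cb2$means)
  expect_identical(cb$weights, cb2$weights)
})

test_that("codebook fit errors on too few descriptors", {
  tiny <- make_sift_like(10)
  expect_error(fit_ifv_codebook(tiny, pca_dim = 64L, n_components = 4L),
               "pca_dim")
  expect_error(fit_ifv_codebook(make_sift_like(70), pca_dim = 64L,
                                n_components = 128L), "n_components")
})

test_that("GMM recovers well-separated isotropic clusters", {
  # clusters are planted directly in descriptor space; with a spread far
  # exceeding the noise the PCA projection keeps them well separated
  G <- 64L; d <- 128L; n_per <- 30L; sigma <- 0.05
  withr::with_seed(11, {
    centers <- matrix(rnorm(G * d, sd = 3), G, d)
    X <- centers[rep(seq_len(G), each = n_per), ] +
      matrix(rnorm(G * n_per * d, sd = sigma), G * n_per, d)
  })
  cb <- fit_ifv_codebook(list(list(descriptors = X)), pca_dim = 64L,
                         n_components = G, seed = 2)
  expect_true(cb$converged)
  proj_centers <- sweep(centers, 2, cb$pca_mean) %*% cb$pca_basis
  # match each true centre to its nearest recovered mean
  for (g in seq_len(G)) {
    d2 <- colSums((t(cb$means) - proj_centers[g, ])^2)
    nearest <- which.min(d2)
    # within 3 standard errors per coordinate (aggregated over dims)
    se <- sigma / sqrt(n_per)
    expect_lt(sqrt(d2[nearest] / ncol(cb$means)), 3 * se)
  }
})

test_that("Fisher encoding matches the brute-force gradient formulas", {
  # tiny configured codebook: 3 components, 4 projected dims
  withr::with_seed(7, {
    cb <- structure(list(
      pca_mean = rnorm(6), pca_basis = qr.Q(qr(matrix(rnorm(24), 6, 4))),
      pca_sdev = rep(1, 4), whiten = FALSE,
      weights = c(0.5, 0.3, 0.2),
      means = matrix(rnorm(12), 3, 4),
      variances = matrix(runif(12, 0.5, 2), 3, 4),
      seed = 1L, n_fit = 0L, loglik = NA_real_, converged = TRUE
    ), class = "ifv_codebook")
    X <- matrix(rnorm(60), 10, 6)
  })
  enc <- encode_ifv(list(descriptors = X), cb, normalize = "none")
  expect_equal(dim(enc$values), c(6L, 4L)) # 2 * 3 blocks of 4 dims

  P <- sweep(X, 2, cb$pca_mean) %*% cb$pca_basis
  n <- nrow(P)
  dens <- sapply(1:3, function(g) {
    cb$weights[g] * apply(P, 1, function(p) {
      prod(stats::dnorm(p, cb$means[g, ], sqrt(cb$variances[g, ])))
    })
  })
  q <- dens / rowSums(dens)
  for (g in 1:3) {
    z <- sweep(sweep(P, 2, cb$means[g, ]), 2, sqrt(cb$variances[g, ]), "/")
    first <- colSums(q[, g] * z) / (n * sqrt(cb$weights[g]))
    second <- colSums(q[, g] * (z^2 - 1)) / (n * sqrt(2 * cb$weights[g]))
    expect_equal(enc$values[g, ], first, tolerance = 1e-12)
    expect_equal(enc$values[3 + g, ], second, tolerance = 1e-12)
  }

  # improved normalisation: signed sqrt then global unit norm
  enc_i <- encode_ifv(list(descriptors = X), cb, normalize = "improved")
  v <- as.vector(t(enc$values))
  v <- sign(v) * sqrt(abs(v))
  v <- v / sqrt(sum(v^2))
  expect_equal(as.vector(t(enc_i$values)), v, tolerance = 1e-12)
})

test_that("a single descriptor at a component mean has a zero first-order block", {
  cb <- structure(list(
    pca_mean = rep(0, 4), pca_basis = diag(4), pca_sdev = rep(1, 4),
    whiten = FALSE, weights = c(0.9, 0.1),
    means = rbind(rep(0, 4), rep(50, 4)),
    variances = matrix(1, 2, 4),
    seed = 1L, n_fit = 0L, loglik = NA_real_, converged = TRUE
  ), class = "ifv_codebook")
  enc <- encode_ifv(list(descriptors = matrix(0, 1, 4)), cb, normalize = "none")
  expect_equal(enc$values[1, ], rep(0, 4)) # first-order block of component 1
  expect_error(encode_ifv(list(descriptors = NULL), cb), "empty")
})

test_that("IFV block count and dimension follow the codebook size", {
  sets <- lapply(1:2, function(i) make_sift_like(200, seed = i))
  cb <- fit_ifv_codebook(sets, pca_dim = 8L, n_components = 4L, seed = 1)
  enc <- encode_ifv(sets[[1]], cb)
  expect_equal(nrow(enc$values), 2 * 4)
  expect_equal(ncol(enc$values), 8)
  expect_equal(length(as.vector(enc$values)), 4 * 8 * 2)
})

test_that("codebook JSON round-trip is lossless", {
  sets <- list(make_sift_like(150, seed = 5))
  cb <- fit_ifv_codebook(sets, pca_dim = 6L, n_components = 3L, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_ifv_codebook(cb, path)
  cb2 <- read_ifv_codebook(path)
  expect_equal(cb2$means, cb$means, tolerance = 1e-12)
  expect_equal(cb2$variances, cb$variances, tolerance = 1e-12)
  expect_equal(cb2$weights, cb$weights, tolerance = 1e-12)
  expect_equal(cb2$pca_basis, cb$pca_basis, tolerance = 1e-12,
               ignore_attr = TRUE)
  enc1 <- encode_ifv(sets[[1]], cb)
  enc2 <- encode_ifv(sets[[1]], cb2)
  expect_equal(enc1$values, enc2$values, tolerance = 1e-12)
})
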