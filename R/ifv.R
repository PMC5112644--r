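#' Fit the PCA + GMM codebook for Fisher-vector encoding
#'
#' Pools local SIFT descriptors from the training images, reduces them to
#' `pca_dim` dimensions with PCA, and fits a diagonal-covariance Gaussian
#' mixture (seeded k-means initialisation followed by EM) on the projected
#' descriptors.  The fit is deterministic given `seed`.
#'
#' @param training_sifts A `dense_sift` object or a list of them.
#' @param pca_dim Projected dimensionality (64 in the full-size profile).
#' @param n_components Number of mixture components (64 in the full-size
#'   profile; smaller values give a cheaper profile for small studies).
#' @param seed Integer seed controlling subsampling and initialisation.
#' @param max_samples Upper bound on the number of pooled descriptors used
#'   for fitting (subsampled without replacement when exceeded).
#' @param whiten Divide projected coordinates by the PCA standard
#'   deviations?  Off by default.
#' @param em_iter Maximum EM iterations.
#' @return An `ifv_codebook`: PCA mean/basis, mixture weights, means and
#'   diagonal variances (component by dimension), plus fit metadata.
#' @export
fit_ifv_codebook <- function(training_sifts, pca_dim = 64L, n_components = 64L,
                             seed = 1L, max_samples = 100000L, whiten = FALSE,
                             em_iter = 100L) {
  if (inherits(training_sifts, "dense_sift") ||
      !is.null(training_sifts$descriptors)) {
    training_sifts <- list(training_sifts)
  }
  X <- do.call(rbind, lapply(training_sifts, function(s) s$descriptors))
  if (is.null(X) || nrow(X) < pca_dim) {
    abort(sprintf(
      "need at least pca_dim = %d pooled descriptors, got %d",
      pca_dim, if (is.null(X)) 0L else nrow(X)
    ))
  }
  if (nrow(X) < n_components) {
    abort(sprintf(
      "need at least n_components = %d pooled descriptors, got %d",
      n_components, nrow(X)
    ))
  }
  if (nrow(X) > max_samples) {
    idx <- withr::with_seed(seed, sample.int(nrow(X), max_samples))
    X <- X[idx, , drop = FALSE]
  }

  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  basis <- pca$rotation[, seq_len(pca_dim), drop = FALSE]
  sdev <- pca$sdev[seq_len(pca_dim)]
  if (whiten) basis <- sweep(basis, 2, pmax(sdev, 1e-12), "/")
  proj <- sweep(X, 2, pca$center) %*% basis

  km <- withr::with_seed(seed, kmeanspp(proj, n_components, nstart = 5L))
  fit <- tryCatch(
    mclust::meVVI(
      data = proj, z = mclust::unmap(km$cluster),
      control = mclust::emControl(itmax = em_iter)
    ),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && is.finite(fit$loglik %||% NA_real_) &&
    !anyNA(fit$parameters$mean)
  if (converged) {
    weights <- fit$parameters$pro
    means <- unname(t(fit$parameters$mean)) # G x d
    variances <- unname(t(apply(fit$parameters$variance$sigma, 3, diag)))
    if (pca_dim == 1L) variances <- matrix(variances, ncol = 1L)
    loglik <- fit$loglik
  } else {
    warn("GMM EM did not converge; falling back to k-means moment estimates")
    weights <- as.numeric(table(factor(km$cluster, levels = seq_len(n_components))))
    weights <- weights / sum(weights)
    means <- unname(km$centers)
    variances <- t(vapply(seq_len(n_components), function(g) {
      rows <- proj[km$cluster == g, , drop = FALSE]
      if (nrow(rows) > 1L) apply(rows, 2, stats::var) else rep(1, pca_dim)
    }, numeric(pca_dim)))
    if (pca_dim == 1L) variances <- matrix(variances, ncol = 1L)
    loglik <- NA_real_
  }
  floor_var <- 1e-6 * mean(variances[is.finite(variances) & variances > 0])
  if (!is.finite(floor_var) || floor_var <= 0) floor_var <- 1e-12
  variances[!is.finite(variances) | variances < floor_var] <- floor_var
  weights <- pmax(weights, 1e-12)
  weights <- weights / sum(weights)

  structure(
    list(
      pca_mean = pca$center, pca_basis = basis, pca_sdev = sdev,
      whiten = whiten, weights = weights, means = means,
      variances = variances, seed = as.integer(seed),
      n_fit = nrow(X), loglik = loglik, converged = converged
    ),
    class = "ifv_codebook"
  )
}

#' Improved-Fisher-vector encoding of a local descriptor set
#'
#' Encodes a set of local descriptors against a fitted codebook as the
#' per-component first- and second-order Fisher statistics, one block of
#' `pca_dim` values per (component, order) pair — `2 * n_components` blocks
#' in total.  With `normalize = "improved"` (default) the concatenated
#' vector is signed-square-rooted and globally L2-normalised before being
#' cut back into blocks.
#'
#' @param sifts A `dense_sift` object (non-empty).
#' @param codebook An `ifv_codebook`.
#' @param normalize `"improved"` or `"none"`.
#' @return A `descriptor_part` whose `values` matrix has one row per block:
#'   rows `1..G` are the first-order blocks, rows `G+1..2G` second-order.
#' @export
encode_ifv <- function(sifts, codebook, normalize = c("improved", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(codebook, "ifv_codebook"))
  X <- sifts$descriptors
  if (is.null(X) || nrow(X) == 0L) {
    abort("cannot encode an empty local descriptor set")
  }
  P <- sweep(X, 2, codebook$pca_mean) %*% codebook$pca_basis # n x d
  G <- length(codebook$weights)
  d <- ncol(P)
  n <- nrow(P)

  # log posterior up to a constant: log w_g - 1/2 sum(log var) - 1/2 maha
  logp <- matrix(0, n, G)
  for (g in seq_len(G)) {
    v <- codebook$variances[g, ]
    diff <- sweep(P, 2, codebook$means[g, ])
    logp[, g] <- log(codebook$weights[g]) - 0.5 * sum(log(2 * pi * v)) -
      0.5 * rowSums(sweep(diff^2, 2, v, "/"))
  }
  mx <- apply(logp, 1, max)
  q <- exp(logp - mx)
  q <- q / rowSums(q)

  first <- matrix(0, G, d)
  second <- matrix(0, G, d)
  for (g in seq_len(G)) {
    sg <- sqrt(codebook$variances[g, ])
    z <- sweep(sweep(P, 2, codebook$means[g, ]), 2, sg, "/")
    first[g, ] <- colSums(q[, g] * z) / (n * sqrt(codebook$weights[g]))
    second[g, ] <- colSums(q[, g] * (z^2 - 1)) / (n * sqrt(2 * codebook$weights[g]))
  }
  vec <- c(t(first), t(second)) # blocks in row order, elements contiguous
  if (normalize == "improved") {
    vec <- sign(vec) * sqrt(abs(vec))
    nrm <- sqrt(sum(vec^2))
    if (nrm > 0) vec <- vec / nrm
  }
  descriptor_part("IFV", matrix(vec, nrow = 2L * G, ncol = d, byrow = TRUE))
}

#' @export
print.ifv_codebook <- function(x, ...) {
  cat(sprintf(
    "<ifv_codebook> %d components x %d dims, fitted on %d descriptors (seed %d)%s\n",
    length(x$weights), ncol(x$means), x$n_fit, x$seed,
    if (x$converged) "" else " [EM fallback]"
  ))
  invisible(x)
}

#' Persist / restore an IFV codebook as JSON
#'
#' @param codebook An `ifv_codebook`.
#' @param path File path.
#' @return `read_ifv_codebook()` returns the restored `ifv_codebook`.
#' @export
write_ifv_codebook <- function(codebook, path) {
  obj <- unclass(codebook)
  obj$pca_basis <- as.list(as.data.frame(obj$pca_basis))
  obj$means <- as.list(as.data.frame(t(obj$means)))
  obj$variances <- as.list(as.data.frame(t(obj$variances)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ifv_codebook
#' @export
read_ifv_codebook <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cb <- list(
    pca_mean = as.numeric(obj$pca_mean),
    pca_basis = as.matrix(as.data.frame(obj$pca_basis)),
    pca_sdev = as.numeric(obj$pca_sdev),
    whiten = isTRUE(obj$whiten),
    weights = as.numeric(obj$weights),
    means = t(as.matrix(as.data.frame(obj$means))),
    variances = t(as.matrix(as.data.frame(obj$variances))),
    seed = as.integer(obj$seed), n_fit = as.integer(obj$n_fit),
    loglik = as.numeric(obj$loglik %||% NA_real_),
    converged = isTRUE(obj$converged)
  )
  dimnames(cb$pca_basis) <- NULL
  dimnames(cb$means) <- NULL
  dimnames(cb$variances) <- NULL
  structure(cb, class = "ifv_codebook")
}

# k-means with D^2-weighted (k-means++) seeding: robust initialisation for
# many well-separated components; relies on the caller's RNG state
kmeanspp <- function(x, k, nstart = 5L, iter.max = 100L) {
  n <- nrow(x)
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- integer(k)
    centers[1] <- sample.int(n, 1)
    d2 <- colSums((t(x) - x[centers[1], ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers[j] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, colSums((t(x) - x[centers[j], ])^2))
    }
    km <- suppressWarnings(kmeans(
      x, centers = x[centers, , drop = FALSE], iter.max = iter.max
    ))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}
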