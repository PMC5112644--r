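#' LLC reconstruction affinity matrix
#'
#' Builds the N x N affinity used for subcategory clustering: each
#' descriptor is reconstructed by locality-constrained linear coding over
#' its `sparsity` nearest neighbours (self excluded) under a sum-to-one
#' constraint with regulariser `balance * trace(G)` on the shifted local
#' Gram matrix `G`; row `n` of the coefficient matrix holds those
#' coefficients at the neighbour positions and zeros elsewhere.  The matrix
#' is returned symmetrised as `W = (|A| + |A^T|) / 2`.
#'
#' @param x N x H numeric matrix of descriptors (or a `descriptor_set`).
#' @param sparsity Number of nearest neighbours used as the local basis
#'   (default 20).
#' @param balance Regularisation weight (default 1e-4).
#' @return Symmetric non-negative N x N affinity matrix with zero diagonal.
#' @export
llc_affinity <- function(x, sparsity = 20L, balance = 1e-4) {
  if (inherits(x, "descriptor_set")) x <- x$x
  stopifnot(is.matrix(x))
  n <- nrow(x)
  stopifnot(sparsity >= 1L, balance > 0)
  if (n < sparsity + 1L) {
    abort(sprintf("need at least sparsity + 1 = %d descriptors, got %d",
                  sparsity + 1L, n))
  }
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  diag(d2) <- Inf
  A <- matrix(0, n, n)
  warned <- FALSE
  for (i in seq_len(n)) {
    nn <- order(d2[i, ])[seq_len(sparsity)]
    B <- sweep(x[nn, , drop = FALSE], 2, x[i, ])
    G <- tcrossprod(B)
    tr <- sum(diag(G))
    if (tr <= .Machine$double.eps) {
      if (!warned) {
        warn("duplicate descriptors produced a zero local Gram matrix; using uniform coefficients")
        warned <- TRUE
      }
      A[i, nn] <- 1 / sparsity
      next
    }
    w <- tryCatch(
      solve(G + balance * tr * diag(sparsity), rep(1, sparsity)),
      error = function(e) {
        if (!warned) {
          warn("singular local Gram matrix; increasing ridge by balance * trace")
          warned <<- TRUE
        }
        solve(G + 10 * balance * tr * diag(sparsity), rep(1, sparsity))
      }
    )
    A[i, nn] <- w / sum(w)
  }
  (abs(A) + abs(t(A))) / 2
}

#' Spectral clustering of an affinity matrix
#'
#' Normalised-Laplacian spectral clustering: the top `n_clusters`
#' eigenvectors of `D^{-1/2} W D^{-1/2}` are row-normalised and clustered
#' with seeded k-means (10 restarts).
#'
#' @param affinity Symmetric non-negative N x N matrix.
#' @param n_clusters Number of clusters (`<= N`).
#' @param seed Integer seed for k-means.
#' @param nstart k-means restarts.
#' @return Integer vector of cluster assignments in `1..n_clusters`.
#' @export
spectral_cluster <- function(affinity, n_clusters, seed = 1L, nstart = 10L) {
  stopifnot(is.matrix(affinity), nrow(affinity) == ncol(affinity))
  n <- nrow(affinity)
  stopifnot(n_clusters >= 1L, n_clusters <= n)
  if (max(abs(affinity - t(affinity))) > 1e-8 || min(affinity) < 0) {
    abort("affinity must be symmetric and non-negative")
  }
  if (n_clusters == n) return(seq_len(n))
  comp <- graph_components(affinity > 0)
  if (comp > n_clusters) {
    inform(sprintf(
      "affinity graph has %d connected components for %d clusters",
      comp, n_clusters
    ))
  }
  d <- rowSums(affinity)
  d[d <= 0] <- .Machine$double.eps
  s <- 1 / sqrt(d)
  M <- affinity * (s %o% s)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  emb <- eg$vectors[, seq_len(n_clusters), drop = FALSE]
  rn <- sqrt(rowSums(emb^2))
  rn[rn <= 0] <- 1
  emb <- emb / rn
  # duplicate embedding rows routinely trip k-means' Quick-TRANSfer warning
  km <- withr::with_seed(seed, suppressWarnings(kmeans(
    emb, centers = n_clusters, nstart = nstart, iter.max = 100L
  )))
  as.integer(km$cluster)
}

# connected components of an undirected adjacency (logical matrix), BFS
graph_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Form subcategories from cluster assignments and class labels
#'
#' Each non-empty (cluster, class) intersection becomes one subcategory
#' `S_{l,k}`; `k` indexes the non-empty intersections of class `l` (in
#' cluster order).  By construction, clustering is run
#' with `n_clusters = L` (the class count) so that each class typically
#' splits into up to `L` subcategories.
#'
#' @param assignments Integer cluster assignments of the training items.
#' @param labels Integer (or factor) class labels, same length.
#' @return A `subcategory_set`: list with `table` (tibble: class, k,
#'   cluster, size), `members` (list of index vectors, aligned with rows of
#'   `table`), `K` (subcategory count per class) and `N`.
#' @export
form_subcategories <- function(assignments, labels) {
  stopifnot(length(assignments) == length(labels))
  labels <- as.integer(factor(labels, levels = sort(unique(labels))))
  df <- tibble(index = seq_along(labels), cluster = as.integer(assignments),
               class = labels)
  groups <- df |>
    dplyr::group_by(.data$class, .data$cluster) |>
    dplyr::summarise(
      size = dplyr::n(), members = list(.data$index), .groups = "drop"
    ) |>
    dplyr::arrange(.data$class, .data$cluster) |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::ungroup()
  K <- groups |>
    dplyr::count(.data$class, name = "K")
  structure(
    list(
      table = dplyr::select(groups, "class", "k", "cluster", "size"),
      members = groups$members,
      K = stats::setNames(K$K, K$class),
      N = length(labels)
    ),
    class = "subcategory_set"
  )
}

#' Generate subcategories from a training descriptor set
#'
#' Convenience wrapper: LLC affinity, spectral clustering into `L` clusters
#' (the number of classes) and per-class splitting.
#'
#' @param x Descriptor matrix or `descriptor_set`.
#' @param labels Class labels.
#' @param sparsity,balance LLC parameters.
#' @param seed Seed for spectral clustering.
#' @param n_clusters Number of clusters; defaults to the class count.
#' @return A `subcategory_set`.
#' @export
generate_subcategories <- function(x, labels, sparsity = 20L, balance = 1e-4,
                                   seed = 1L, n_clusters = NULL) {
  if (inherits(x, "descriptor_set")) x <- x$x
  L <- length(unique(labels))
  n_clusters <- n_clusters %||% L
  sparsity <- min(sparsity, nrow(x) - 1L)
  W <- llc_affinity(x, sparsity = sparsity, balance = balance)
  cl <- spectral_cluster(W, n_clusters, seed = seed)
  form_subcategories(cl, labels)
}

#' @export
print.subcategory_set <- function(x, ...) {
  cat(sprintf(
    "<subcategory_set> N = %d, %d subcategories over %d classes (K: %s)\n",
    x$N, nrow(x$table), length(x$K), paste(x$K, collapse = ", ")
  ))
  invisible(x)
}
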