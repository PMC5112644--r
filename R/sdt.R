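#' Subcategory scatter statistics of one block
#'
#' `compute_gamma()` computes the 1 x D row vector `gamma` of one
#' subcategory for one block: the transformed mean element of the block is
#' then `theta = gamma %*% f` for any kernel `f`.  The window convention is
#' a zero-padded "same" convolution with vertical kernel flip: the length-D
#' window of the block vector is centred at each element, zeros outside
#' `[1, C]`, and reversed by the exchange matrix.
#'
#' @param block_vectors Members of one subcategory as a matrix with one row
#'   per member and `C` columns (a single vector is accepted).
#' @param D Odd kernel length, `D < C`.
#' @return Numeric vector of length `D`.
#' @export
compute_gamma <- function(block_vectors, D) {
  if (is.vector(block_vectors)) block_vectors <- matrix(block_vectors, nrow = 1L)
  stopifnot(is.matrix(block_vectors))
  n <- nrow(block_vectors)
  C <- ncol(block_vectors)
  if (n == 0L) abort("subcategory has no members")
  check_kernel_size(D, C)
  totals <- colSums(block_vectors)
  gamma_from_totals(totals, D) / (C * n)
}

# gamma (unnormalised, i.e. sum over members and elements) from the
# element-wise column totals of the member vectors: component j is the sum
# of the totals over the clipped index range shifted by s = r - j + 1
gamma_from_totals <- function(totals, D) {
  C <- length(totals)
  r <- (D - 1L) %/% 2L
  cs <- cumsum(totals)
  tot <- cs[C]
  vapply(seq_len(D), function(j) {
    s <- r - j + 1L
    if (s >= 0L) {
      if (s == 0L) tot else tot - cs[s]
    } else {
      cs[C + s]
    }
  }, numeric(1))
}

# per-row gammas (one per member) for FDT: rows x D
gamma_rows <- function(block_vectors, D) {
  C <- ncol(block_vectors)
  r <- (D - 1L) %/% 2L
  cs <- t(apply(block_vectors, 1L, cumsum))
  if (nrow(block_vectors) == 1L) cs <- matrix(cs, nrow = 1L)
  tot <- cs[, C]
  out <- matrix(0, nrow(block_vectors), D)
  for (j in seq_len(D)) {
    s <- r - j + 1L
    out[, j] <- if (s >= 0L) {
      if (s == 0L) tot else tot - cs[, s]
    } else {
      cs[, C + s]
    }
  }
  out / C
}

check_kernel_size <- function(D, C) {
  if (D %% 2L != 1L || D < 1L) abort("kernel length D must be odd and positive")
  if (D >= C) abort(sprintf("kernel length D = %d must be smaller than the block dimension C = %d", D, C))
  invisible(D)
}

#' Build the within- and between-class scatter pair of one block
#'
#' Accumulates the D x D scatter matrices over subcategory pairs:
#' within-class terms are weighted by `|S_{l,k}| / (K_l - 1)` (classes with
#' a single subcategory contribute zero), between-class terms by
#' `|S_{l,k}| / sum_l' K_l'`.
#'
#' @param gammas Matrix of subcategory `gamma` rows (rows aligned with
#'   `subcats$table`).
#' @param subcats A `subcategory_set`.
#' @return List with symmetric PSD matrices `U_with` and `U_betw`.
#' @export
build_scatter <- function(gammas, subcats) {
  tb <- subcats$table
  stopifnot(is.matrix(gammas), nrow(gammas) == nrow(tb))
  D <- ncol(gammas)
  L <- length(unique(tb$class))
  if (L < 2L) abort("between-class scatter is undefined with a single class")
  K_sum <- nrow(tb)
  U_with <- matrix(0, D, D)
  U_betw <- matrix(0, D, D)
  for (a in seq_len(nrow(tb))) {
    cls <- tb$class[a]
    K_l <- sum(tb$class == cls)
    size <- tb$size[a]
    same <- which(tb$class == cls)
    other <- which(tb$class != cls)
    if (K_l > 1L) {
      w <- size / (K_l - 1)
      for (b in same) {
        dif <- gammas[a, ] - gammas[b, ]
        U_with <- U_with + w * tcrossprod(dif)
      }
    }
    w <- size / K_sum
    for (b in other) {
      dif <- gammas[a, ] - gammas[b, ]
      U_betw <- U_betw + w * tcrossprod(dif)
    }
  }
  list(U_with = (U_with + t(U_with)) / 2, U_betw = (U_betw + t(U_betw)) / 2)
}

#' Solve for the convolution kernel of one block
#'
#' Returns the generalised eigenvector of `(U_betw, U_with + eps I)` with
#' the largest eigenvalue, where `eps = 1e-6 * trace(U_with) / D` ridges a
#' singular within-scatter.  The kernel is scaled to unit norm with its
#' largest-magnitude tap positive.  When both matrices are (numerically)
#' zero the block is degenerate and the delta kernel is returned with
#' `lambda = 0`.
#'
#' @param scatter List with `U_with` and `U_betw` (as from
#'   [build_scatter()]).
#' @param quiet Suppress the degenerate-block message?
#' @return List with `taps` (unit-norm length-D vector), `eigenvalue`, the
#'   `ridge` value `eps` actually applied, and a `degenerate` flag.
#' @export
solve_kernel <- function(scatter, quiet = FALSE) {
  U_w <- scatter$U_with
  U_b <- scatter$U_betw
  D <- nrow(U_w)
  scale_w <- sum(diag(U_w))
  scale_b <- sum(diag(U_b))
  if (scale_b <= .Machine$double.eps * D && scale_w <= .Machine$double.eps * D) {
    if (!quiet) inform("degenerate block (zero scatter); returning the delta kernel")
    return(list(taps = delta_kernel(D), eigenvalue = 0, ridge = 0,
                degenerate = TRUE))
  }
  eps <- 1e-6 * scale_w / D
  if (eps <= 0) eps <- 1e-12 * max(scale_b / D, 1)
  M <- U_w + diag(eps, D)
  R <- chol(M)
  S <- backsolve(R, t(backsolve(R, t(U_b), transpose = TRUE)), transpose = TRUE)
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  f <- backsolve(R, eg$vectors[, 1L])
  f <- f / sqrt(sum(f^2))
  imax <- which.max(abs(f))
  if (f[imax] < 0) f <- -f
  list(taps = f, eigenvalue = eg$values[1L], ridge = eps, degenerate = FALSE)
}

delta_kernel <- function(D) {
  f <- numeric(D)
  f[(D + 1L) %/% 2L] <- 1
  f
}

# Rayleigh quotient of the scatter pair at kernel f (no ridge)
scatter_quotient <- function(scatter, f) {
  vb <- drop(t(f) %*% scatter$U_betw %*% f)
  vw <- drop(t(f) %*% scatter$U_with %*% f)
  c(v_betw = vb, v_with = vw)
}

#' Transform one block by convolution with its kernel
#'
#' Computes the zero-padded "same" convolution of the block vector(s) with
#' the kernel (flip convention matching [compute_gamma()]), then rescales
#' each transformed vector to the Euclidean norm of its input.  A convolved
#' vector that is entirely zero is returned unchanged.
#'
#' @param x_b Block vector (length C) or matrix of block vectors (rows).
#' @param taps Kernel tap vector (odd length `< C`), or the list returned
#'   by [solve_kernel()].
#' @param rescale Rescale to the input norms (default) or return the raw
#'   convolution?
#' @return Same shape as `x_b`.
#' @export
transform_block <- function(x_b, taps, rescale = TRUE) {
  if (is.list(taps)) taps <- taps$taps
  vec_in <- is.vector(x_b)
  if (vec_in) x_b <- matrix(x_b, nrow = 1L)
  C <- ncol(x_b)
  D <- length(taps)
  check_kernel_size(D, C)
  r <- (D - 1L) %/% 2L
  Y <- matrix(0, nrow(x_b), C)
  # y[i] = sum_j f_j x[i + r + 1 - j], zero outside [1, C]
  for (j in seq_len(D)) {
    s <- r + 1L - j
    src <- seq_len(C) + s
    ok <- src >= 1L & src <= C
    Y[, which(ok)] <- Y[, which(ok), drop = FALSE] +
      taps[j] * x_b[, src[ok], drop = FALSE]
  }
  if (rescale) {
    nin <- sqrt(rowSums(x_b^2))
    nout <- sqrt(rowSums(Y^2))
    zero <- nout <= .Machine$double.eps * C
    scalef <- ifelse(zero, 1, nin / pmax(nout, .Machine$double.xmin))
    Y <- Y * scalef
    if (any(zero & nin > 0)) {
      inform(sprintf("%d convolved vector(s) were all-zero; returned unchanged", sum(zero & nin > 0)))
      Y[zero, ] <- x_b[zero, , drop = FALSE]
    }
  }
  if (vec_in) drop(Y) else Y
}

resolve_kernel_sizes <- function(layout, kernel_sizes) {
  if (length(kernel_sizes) == 1L && is.null(names(kernel_sizes))) {
    kernel_sizes <- stats::setNames(
      rep(kernel_sizes, nrow(layout)), layout$modality
    )
  }
  missing <- setdiff(layout$modality, names(kernel_sizes))
  if (length(missing)) {
    abort(paste0("no kernel size given for modality: ", paste(missing, collapse = ", ")))
  }
  sizes <- kernel_sizes[layout$modality]
  for (m in seq_len(nrow(layout))) {
    D <- sizes[[m]]
    if (!D %in% c(3L, 5L, 7L, 9L)) {
      abort(sprintf("kernel size for %s must be one of 3, 5, 7, 9 (got %s)",
                    layout$modality[m], D))
    }
    check_kernel_size(D, layout$dim[m])
  }
  stats::setNames(as.integer(sizes), layout$modality)
}

#' Fit the subcategory discriminant transform
#'
#' Learns one convolution kernel per descriptor block: for every block the
#' per-subcategory `gamma` rows are computed, the within/between scatter
#' pair is accumulated and the generalised eigenproblem solved.
#'
#' @param x A `descriptor_set` (or plain matrix plus `layout`).
#' @param subcats A `subcategory_set` over the same training items.
#' @param kernel_sizes Either a single kernel length or a named vector
#'   (modality -> D), values in {3, 5, 7, 9}.
#' @param layout Block layout (taken from `x` when it is a
#'   `descriptor_set`).
#' @return An `sdt_model`: kernels (one per block), layout, kernel sizes
#'   and mode (`"SDT"`).
#' @export
fit_sdt <- function(x, subcats, kernel_sizes = 3L, layout = NULL) {
  if (inherits(x, "descriptor_set")) {
    layout <- x$layout
    x <- x$x
  }
  if (is.null(layout)) abort("a block layout is required")
  if (subcats$N != nrow(x)) {
    abort(sprintf("subcategory set covers %d items but descriptor set has %d",
                  subcats$N, nrow(x)))
  }
  sizes <- resolve_kernel_sizes(layout, kernel_sizes)
  bt <- block_table(layout)
  # per-subcategory column totals over the full descriptor, computed once
  grp <- integer(nrow(x))
  for (i in seq_along(subcats$members)) grp[subcats$members[[i]]] <- i
  totals <- rowsum(x, grp, reorder = TRUE)
  sizes_s <- subcats$table$size

  kernels <- vector("list", nrow(bt))
  n_degenerate <- 0L
  for (b in seq_len(nrow(bt))) {
    D <- sizes[[bt$modality[b]]]
    cols <- bt$start[b]:bt$end[b]
    gam <- t(vapply(
      seq_len(nrow(totals)),
      function(s) gamma_from_totals(totals[s, cols], D) / (bt$dim[b] * sizes_s[s]),
      numeric(D)
    ))
    sc <- tryCatch(
      build_scatter(gam, subcats),
      error = function(e) abort(sprintf("block %d (%s): %s", b, bt$modality[b],
                                        conditionMessage(e)))
    )
    k <- solve_kernel(sc, quiet = TRUE)
    if (k$degenerate) n_degenerate <- n_degenerate + 1L
    kernels[[b]] <- k
  }
  if (n_degenerate > 0L) {
    inform(sprintf("%d of %d blocks were degenerate (delta kernel used)",
                   n_degenerate, nrow(bt)))
  }
  new_sdt_model(kernels, layout, sizes, mode = "SDT")
}

#' Fit the class-level Fisher discriminant transform (FDT) ablation
#'
#' Same convolutional machinery as [fit_sdt()] but with standard Fisher
#' scatter: the within-scatter accumulates (sample gamma - class-mean
#' gamma) outer products, the between-scatter accumulates class-size
#' weighted (class-mean gamma - overall-mean gamma) outer products.
#'
#' @param x A `descriptor_set` (or matrix plus `layout`).
#' @param labels Class labels of the training items.
#' @inheritParams fit_sdt
#' @return An `sdt_model` with mode `"FDT"`.
#' @export
fit_fdt <- function(x, labels, kernel_sizes = 3L, layout = NULL) {
  if (inherits(x, "descriptor_set")) {
    layout <- x$layout
    x <- x$x
  }
  if (is.null(layout)) abort("a block layout is required")
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) abort("FDT requires at least two classes")
  stopifnot(length(labels) == nrow(x))
  sizes <- resolve_kernel_sizes(layout, kernel_sizes)
  bt <- block_table(layout)
  classes <- sort(unique(labels))

  kernels <- vector("list", nrow(bt))
  n_degenerate <- 0L
  for (b in seq_len(nrow(bt))) {
    D <- sizes[[bt$modality[b]]]
    cols <- bt$start[b]:bt$end[b]
    G <- gamma_rows(x[, cols, drop = FALSE], D)
    overall <- colMeans(G)
    U_w <- matrix(0, D, D)
    U_b <- matrix(0, D, D)
    for (cl in classes) {
      rows <- G[labels == cl, , drop = FALSE]
      cm <- colMeans(rows)
      cen <- sweep(rows, 2, cm)
      U_w <- U_w + crossprod(cen)
      dif <- cm - overall
      U_b <- U_b + nrow(rows) * tcrossprod(dif)
    }
    k <- solve_kernel(list(U_with = U_w, U_betw = U_b), quiet = TRUE)
    if (k$degenerate) n_degenerate <- n_degenerate + 1L
    kernels[[b]] <- k
  }
  if (n_degenerate > 0L) {
    inform(sprintf("%d of %d blocks were degenerate (delta kernel used)",
                   n_degenerate, nrow(bt)))
  }
  new_sdt_model(kernels, layout, sizes, mode = "FDT")
}

new_sdt_model <- function(kernels, layout, kernel_sizes, mode) {
  structure(
    list(kernels = kernels, layout = layout,
         kernel_sizes = kernel_sizes, mode = mode),
    class = "sdt_model"
  )
}

#' Apply a fitted transform to descriptors
#'
#' Convolves every block with its learned kernel and rescales each
#' transformed block to the norm of its input, leaving the total dimension
#' `H` unchanged.
#'
#' @param x A `block_descriptor`, `descriptor_set`, or plain matrix with
#'   one descriptor per row.
#' @param model An `sdt_model` whose layout matches `x`.
#' @return Same container type as `x`.
#' @export
apply_sdt <- function(x, model) {
  stopifnot(inherits(model, "sdt_model"))
  if (inherits(x, "block_descriptor")) {
    check_layout_match(x$layout, model$layout)
    y <- apply_sdt_matrix(matrix(x$x, nrow = 1L), model)
    return(structure(list(x = drop(y), layout = x$layout),
                     class = "block_descriptor"))
  }
  if (inherits(x, "descriptor_set")) {
    check_layout_match(x$layout, model$layout)
    return(structure(list(x = apply_sdt_matrix(x$x, model), layout = x$layout),
                     class = "descriptor_set"))
  }
  stopifnot(is.matrix(x))
  if (ncol(x) != layout_total_dim(model$layout)) {
    abort(sprintf("descriptor dimension %d does not match model layout H = %d",
                  ncol(x), layout_total_dim(model$layout)))
  }
  apply_sdt_matrix(x, model)
}

check_layout_match <- function(a, b) {
  if (!layouts_equal(a, b)) {
    abort(sprintf(
      "layout mismatch: descriptor has [%s], model expects [%s]",
      paste(sprintf("%s:%dx%d", a$modality, a$n_blocks, a$dim), collapse = ", "),
      paste(sprintf("%s:%dx%d", b$modality, b$n_blocks, b$dim), collapse = ", ")
    ))
  }
}

apply_sdt_matrix <- function(x, model) {
  bt <- block_table(model$layout)
  y <- x
  for (b in seq_len(nrow(bt))) {
    cols <- bt$start[b]:bt$end[b]
    y[, cols] <- suppressMessages(
      transform_block(x[, cols, drop = FALSE], model$kernels[[b]]$taps)
    )
  }
  y
}

#' Per-block scatter-ratio diagnostics
#'
#' Computes the ratio `V_betw / V_with` for every block, evaluated through
#' the `gamma` statistics of the convolved (pre-rescaling) blocks: with no
#' model the delta kernel is used (the raw descriptor), with a model both
#' the raw and the transformed ratios are reported.  Blocks with zero
#' within-variation are flagged and reported as `Inf`.
#'
#' @param x A `descriptor_set` (or matrix plus `layout`).
#' @param subcats A `subcategory_set` for the same items.
#' @param model Optional `sdt_model`.
#' @param D Kernel length used to build the scatter pair when no model is
#'   given.
#' @param layout Block layout when `x` is a plain matrix.
#' @return A tibble with one row per block: `block`, `modality`,
#'   `v_with`, `v_betw`, `ratio` (raw descriptor), and with a model also
#'   `ratio_after` plus `improved = ratio_after >= ratio`.
#' @export
scatter_ratios <- function(x, subcats, model = NULL, D = 3L, layout = NULL) {
  if (inherits(x, "descriptor_set")) {
    layout <- x$layout
    x <- x$x
  }
  if (is.null(layout)) abort("a block layout is required")
  if (!is.null(model)) check_layout_match(layout, model$layout)
  bt <- block_table(layout)
  grp <- integer(nrow(x))
  for (i in seq_along(subcats$members)) grp[subcats$members[[i]]] <- i
  totals <- rowsum(x, grp, reorder = TRUE)
  sizes_s <- subcats$table$size

  rows <- vector("list", nrow(bt))
  for (b in seq_len(nrow(bt))) {
    Db <- if (is.null(model)) D else model$kernel_sizes[[bt$modality[b]]]
    cols <- bt$start[b]:bt$end[b]
    gam <- t(vapply(
      seq_len(nrow(totals)),
      function(s) gamma_from_totals(totals[s, cols], Db) / (bt$dim[b] * sizes_s[s]),
      numeric(Db)
    ))
    sc <- build_scatter(gam, subcats)
    raw <- scatter_quotient(sc, delta_kernel(Db))
    tol <- .Machine$double.eps * max(sum(diag(sc$U_with)), sum(diag(sc$U_betw)), 1)
    degenerate <- raw[["v_with"]] <= tol
    ratio <- if (degenerate) Inf else raw[["v_betw"]] / raw[["v_with"]]
    row <- tibble(
      block = b, modality = bt$modality[b],
      v_with = raw[["v_with"]], v_betw = raw[["v_betw"]],
      ratio = ratio, degenerate = degenerate
    )
    if (!is.null(model)) {
      aft <- scatter_quotient(sc, model$kernels[[b]]$taps)
      row$ratio_after <- if (aft[["v_with"]] <= tol) Inf else aft[["v_betw"]] / aft[["v_with"]]
      row$improved <- row$ratio_after >= row$ratio
    }
    rows[[b]] <- row
  }
  dplyr::bind_rows(rows)
}

#' @export
print.sdt_model <- function(x, ...) {
  lam <- vapply(x$kernels, `[[`, numeric(1), "eigenvalue")
  cat(sprintf(
    "<sdt_model> mode %s, %d kernels (D: %s), median lambda %.3g\n",
    x$mode, length(x$kernels),
    paste(sprintf("%s=%d", names(x$kernel_sizes), x$kernel_sizes), collapse = ", "),
    stats::median(lam)
  ))
  invisible(x)
}

#' Persist / restore a fitted transform as JSON
#'
#' @param model An `sdt_model`.
#' @param path File path.
#' @return `read_sdt_model()` returns the restored `sdt_model`.
#' @export
write_sdt_model <- function(model, path) {
  obj <- list(
    mode = model$mode,
    kernel_sizes = as.list(model$kernel_sizes),
    layout = as.data.frame(model$layout),
    kernels = lapply(model$kernels, function(k) {
      list(taps = k$taps, eigenvalue = k$eigenvalue, degenerate = k$degenerate)
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sdt_model
#' @export
read_sdt_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  layout <- as_tibble(obj$layout)
  layout$n_blocks <- as.integer(layout$n_blocks)
  layout$dim <- as.integer(layout$dim)
  kernels <- lapply(seq_len(nrow(obj$kernels)), function(i) {
    list(
      taps = as.numeric(obj$kernels$taps[[i]]),
      eigenvalue = as.numeric(obj$kernels$eigenvalue[[i]]),
      degenerate = isTRUE(obj$kernels$degenerate[[i]])
    )
  })
  new_sdt_model(
    kernels, layout,
    stats::setNames(as.integer(unlist(obj$kernel_sizes)), names(obj$kernel_sizes)),
    mode = obj$mode
  )
}
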