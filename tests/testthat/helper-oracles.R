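# Independent brute-force oracles used to pin the conventions of the fast
# implementations.  These deliberately use naive per-pixel / per-element
# loops and no code paths from the package internals.

# census / LBP code of a single interior pixel: neighbour >= centre -> bit,
# clockwise from top-left, first neighbour = least significant bit
oracle_census_code <- function(img, r, c) {
  nb <- rbind(
    c(r - 1, c - 1), c(r - 1, c), c(r - 1, c + 1), c(r, c + 1),
    c(r + 1, c + 1), c(r + 1, c), c(r + 1, c - 1), c(r, c - 1)
  )
  bits <- as.integer(img[nb] >= img[r, c])
  sum(bits * 2^(0:7))
}

oracle_census_hist <- function(img) {
  h <- integer(256)
  for (r in 2:(nrow(img) - 1)) {
    for (c in 2:(ncol(img) - 1)) {
      code <- oracle_census_code(img, r, c)
      h[code + 1] <- h[code + 1] + 1
    }
  }
  h
}

# number of 0/1 transitions around the 8-bit circle
oracle_transitions <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  sum(bits != bits[c(2:8, 1)])
}

# 58-bin uniform LBP histogram over all interior pixels of a patch
oracle_lbp_hist <- function(img) {
  uniform_codes <- Filter(function(v) oracle_transitions(v) <= 2, 0:255)
  h <- integer(58)
  for (r in 2:(nrow(img) - 1)) {
    for (c in 2:(ncol(img) - 1)) {
      code <- oracle_census_code(img, r, c)
      pos <- match(code, uniform_codes)
      if (!is.na(pos)) h[pos] <- h[pos] + 1
    }
  }
  h
}

# unnormalised 18-bin directed gradient histogram of a pixel range
# (central differences, zero gradients at the image border)
oracle_hog_cell_hist <- function(img, rows, cols) {
  h <- numeric(18)
  for (r in rows) {
    for (c in cols) {
      gx <- if (c > 1 && c < ncol(img)) (img[r, c + 1] - img[r, c - 1]) / 2 else 0
      gy <- if (r > 1 && r < nrow(img)) (img[r + 1, c] - img[r - 1, c]) / 2 else 0
      m <- sqrt(gx^2 + gy^2)
      if (m == 0) next
      a <- atan2(gy, gx) %% (2 * pi)
      b <- (floor(a / (2 * pi) * 18 + 0.5) %% 18) + 1
      h[b] <- h[b] + m
    }
  }
  h
}

# zero-padded "same" convolution, per-element loop
oracle_same_conv <- function(x, f) {
  C <- length(x)
  D <- length(f)
  r <- (D - 1) / 2
  y <- numeric(C)
  for (i in seq_len(C)) {
    for (j in seq_len(D)) {
      s <- i + r + 1 - j
      if (s >= 1 && s <= C) y[i] <- y[i] + f[j] * x[s]
    }
  }
  y
}

# LLC coefficients by reduced-substitution constrained least squares:
# min ||x - B w||^2 + lambda ||w||^2  s.t.  sum(w) = 1, solved by
# eliminating w_k = 1 - sum(w_{-k}) and solving the unconstrained normal
# equations of the residual form directly
oracle_llc_weights <- function(x, B, lambda) {
  k <- nrow(B)
  # parameterise w = e_k + Z v, with Z spanning the sum-zero subspace
  Z <- rbind(diag(k - 1), -1)
  base <- B[k, ]
  R <- t(B) %*% Z # residual basis: B^T w = base + R v ... (columns)
  target <- x - base
  M <- t(R) %*% R + lambda * t(Z) %*% Z
  rhs <- t(R) %*% target - lambda * t(Z) %*% c(rep(0, k - 1), 1)
  v <- solve(M, rhs)
  as.numeric(c(v, 1 - sum(v)))
}

# normalised cut of a 2-partition
oracle_ncut <- function(W, part) {
  a <- which(part); b <- which(!part)
  cut <- sum(W[a, b])
  va <- sum(W[a, ]); vb <- sum(W[b, ])
  cut / va + cut / vb
}

# best 2-partition by exhaustive enumeration (N <= 12)
oracle_best_2cut <- function(W) {
  n <- nrow(W)
  best <- NULL; best_val <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    part <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(part) || all(part)) next
    v <- oracle_ncut(W, part)
    if (v < best_val) { best_val <- v; best <- part }
  }
  list(partition = best, value = best_val)
}

# valid dense-SIFT grid positions for one dimension and scale
oracle_sift_centers <- function(n, w, step) {
  centers <- c()
  for (x in seq_len(n)) {
    # outer bin centre at 1.5 w, triangular support of half-width w - 1
    if (x - 1.5 * w - (w - 1) >= 1 && x + 1.5 * w + (w - 1) <= n) {
      centers <- c(centers, x)
    }
  }
  centers[seq(1, length(centers), by = step)]
}

# small deterministic random image
random_image <- function(h, w, seed = 1) {
  withr::with_seed(seed, matrix(round(runif(h * w, 0, 255)), h, w))
}
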