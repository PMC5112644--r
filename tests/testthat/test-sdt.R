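test_that("gamma with the delta kernel reproduces the plain mean element", {
  withr::with_seed(1, x <- matrix(rnorm(3 * 10), 3, 10))
  for (D in c(3L, 5L)) {
    g <- compute_gamma(x, D)
    delta <- sdtimage:::delta_kernel(D)
    expect_equal(sum(g * delta), mean(x), tolerance = 1e-12)
  }
})

test_that("gamma . f equals the mean element of the same convolution (oracle)", {
  x <- c(1, 2, 3, 4, 5)
  withr::with_seed(2, f <- rnorm(3))
  g <- compute_gamma(x, 3L)
  expect_equal(sum(g * f), mean(oracle_same_conv(x, f)), tolerance = 1e-12)
  # property over random pairs pins padding + flip conventions
  withr::with_seed(3, {
    for (rep in 1:50) {
      C <- sample(8:20, 1)
      D <- sample(c(3L, 5L, 7L), 1)
      xv <- rnorm(C)
      fv <- rnorm(D)
      expect_equal(sum(compute_gamma(xv, D) * fv),
                   mean(oracle_same_conv(xv, fv)), tolerance = 1e-10)
    }
  })
})

test_that("gamma is linear in the members", {
  withr::with_seed(4, {
    a <- rnorm(12); b <- rnorm(12)
  })
  g_ab <- compute_gamma(rbind(a, b), 5L)
  g_a <- compute_gamma(a, 5L)
  g_b <- compute_gamma(b, 5L)
  expect_equal(g_ab, (g_a + g_b) / 2, tolerance = 1e-12)
})

test_that("gamma validates kernel length and membership", {
  expect_error(compute_gamma(rnorm(5), 4L), "odd")
  expect_error(compute_gamma(rnorm(5), 5L), "smaller")
  expect_error(compute_gamma(matrix(numeric(0), 0, 5), 3L), "members")
})

test_that("scatter matrices match an exhaustive pair-summation oracle", {
  # 2 classes x 2 subcategories with hand-set gamma rows at D = 3
  gam <- rbind(
    c(1, 0, 0), c(0, 1, 0),   # class 1, k = 1, 2
    c(0, 0, 1), c(1, 1, 1)    # class 2, k = 1, 2
  )
  sizes <- c(3L, 5L, 2L, 4L)
  sub <- form_subcategories(c(1, 2, 1, 2), c(1, 1, 2, 2))
  sub$table$size <- sizes
  sc <- build_scatter(gam, sub)
  # oracle: loop over all (l, k, l', k') quadruples
  cls <- c(1, 1, 2, 2)
  U_w <- matrix(0, 3, 3); U_b <- matrix(0, 3, 3)
  for (a in 1:4) {
    K_l <- sum(cls == cls[a])
    for (b in 1:4) {
      dif <- gam[a, ] - gam[b, ]
      if (cls[b] == cls[a]) {
        U_w <- U_w + sizes[a] / (K_l - 1) * (dif %o% dif)
      } else {
        U_b <- U_b + sizes[a] / 4 * (dif %o% dif)
      }
    }
  }
  expect_equal(sc$U_with, U_w, tolerance = 1e-12)
  expect_equal(sc$U_betw, U_b, tolerance = 1e-12)
})

test_that("degenerate scatter cases behave as specified", {
  # one subcategory per class: no within pairs
  gam <- rbind(c(1, 2, 3), c(4, 5, 6))
  sub <- form_subcategories(c(1, 2), c(1, 2))
  sc <- build_scatter(gam, sub)
  expect_equal(sc$U_with, matrix(0, 3, 3))
  expect_gt(sum(sc$U_betw^2), 0)
  # identical gamma rows: both zero
  sub2 <- form_subcategories(c(1, 2, 1, 2), c(1, 1, 2, 2))
  sc2 <- build_scatter(matrix(1, 4, 3), sub2)
  expect_equal(sc2$U_with, matrix(0, 3, 3))
  expect_equal(sc2$U_betw, matrix(0, 3, 3))
  # single class: error
  sub1 <- form_subcategories(c(1, 2), c(1, 1))
  expect_error(build_scatter(gam, sub1), "single class")
})

test_that("solve_kernel satisfies the (ridged) eigen-equation", {
  k <- solve_kernel(list(U_with = diag(3), U_betw = diag(3)))
  resid <- diag(3) %*% k$taps -
    k$eigenvalue * (diag(3) + diag(k$ridge, 3)) %*% k$taps
  expect_lt(sqrt(sum(resid^2)), 1e-8)
  expect_equal(k$eigenvalue, 1, tolerance = 1e-5)
  expect_equal(sqrt(sum(k$taps^2)), 1, tolerance = 1e-12)
})

test_that("solve_kernel maximises the Rayleigh quotient (random-search oracle)", {
  withr::with_seed(10, {
    for (rep in 1:10) {
      D <- sample(c(3L, 5L), 1)
      A <- matrix(rnorm(D * D), D); U_b <- crossprod(A)
      B <- matrix(rnorm(D * D), D); U_w <- crossprod(B)
      k <- solve_kernel(list(U_with = U_w, U_betw = U_b))
      M <- U_w + diag(k$ridge, D)
      q_hat <- drop(t(k$taps) %*% U_b %*% k$taps) /
        drop(t(k$taps) %*% M %*% k$taps)
      V <- matrix(rnorm(1e4 * D), 1e4, D)
      V <- V / sqrt(rowSums(V^2))
      q_rand <- rowSums((V %*% U_b) * V) / rowSums((V %*% M) * V)
      expect_gte(q_hat + 1e-8, max(q_rand))
      expect_equal(q_hat, k$eigenvalue, tolerance = 1e-8)
    }
  })
})

test_that("rank-1 between-scatter with identity within gives the planted direction", {
  v <- c(1, 2, 3) / sqrt(14)
  k <- solve_kernel(list(U_with = diag(3), U_betw = 5 * (v %o% v)))
  expect_equal(abs(sum(k$taps * v)), 1, tolerance = 1e-6)
})

test_that("zero scatter returns the delta kernel with lambda 0", {
  expect_message(
    k <- solve_kernel(list(U_with = matrix(0, 3, 3), U_betw = matrix(0, 3, 3))),
    "degenerate"
  )
  expect_true(k$degenerate)
  expect_equal(k$taps, c(0, 1, 0))
  expect_equal(k$eigenvalue, 0)
})

test_that("transform_block matches the sliding-window oracle and conserves norms", {
  x <- c(1, 2, 3, 4, 5)
  f <- c(0.3, -0.2, 0.8)
  y_raw <- transform_block(x, f, rescale = FALSE)
  expect_equal(y_raw, oracle_same_conv(x, f), tolerance = 1e-12)
  y <- transform_block(x, f)
  expect_equal(sqrt(sum(y^2)), sqrt(sum(x^2)), tolerance = 1e-12)
  # delta kernel is the identity
  expect_equal(transform_block(x, c(0, 1, 0)), x, tolerance = 1e-12)
  # matrix form consistent with vector form
  X <- rbind(x, 2 * x)
  Y <- transform_block(X, f)
  expect_equal(Y[1, ], y, tolerance = 1e-12)
})

test_that("an all-delta model makes apply_sdt the identity", {
  pb <- generate_planted_blocks(planted_block_spec(seed = 1), n_per_subcat = 3)
  bt <- block_table(pb$x$layout)
  kernels <- lapply(seq_len(nrow(bt)), function(b) {
    list(taps = sdtimage:::delta_kernel(3L), eigenvalue = 0, ridge = 0,
         degenerate = TRUE)
  })
  model <- sdtimage:::new_sdt_model(
    kernels, pb$x$layout, c(SIG = 3L, NOISE = 3L), "SDT"
  )
  y <- apply_sdt(pb$x, model)
  expect_equal(y$x, pb$x$x, tolerance = 1e-12)
})

test_that("apply_sdt conserves dimension and per-block norms", {
  pb <- generate_planted_blocks(planted_block_spec(seed = 2), n_per_subcat = 4)
  sub <- generate_subcategories(pb$x, pb$labels, sparsity = 8, seed = 1)
  model <- suppressMessages(fit_sdt(pb$x, sub, c(SIG = 5L, NOISE = 3L)))
  y <- apply_sdt(pb$x, model)
  expect_equal(dim(y$x), dim(pb$x$x))
  bt <- block_table(pb$x$layout)
  for (b in seq_len(nrow(bt))) {
    cols <- bt$start[b]:bt$end[b]
    expect_equal(sqrt(rowSums(y$x[, cols, drop = FALSE]^2)),
                 sqrt(rowSums(pb$x$x[, cols, drop = FALSE]^2)),
                 tolerance = 1e-10)
  }
  # layout mismatch errors name the modalities
  other <- generate_planted_blocks(
    planted_block_spec(n_informative = 2L, n_noise = 1L, seed = 3),
    n_per_subcat = 2
  )
  expect_error(apply_sdt(other$x, model), "layout mismatch")
})

test_that("identical descriptors give an all-degenerate model (identity transform)", {
  x <- matrix(rep(c(1, 2, 3, 4, 5, 6, 7, 8), times = 6), 6, 8, byrow = TRUE)
  layout <- tibble::tibble(modality = "SIG", n_blocks = 2L, dim = 4L)
  set <- structure(list(x = x, layout = layout), class = "descriptor_set")
  sub <- form_subcategories(c(1, 1, 2, 2, 1, 2), rep(1:2, 3))
  expect_message(model <- fit_sdt(set, sub, 3L), "degenerate")
  expect_true(all(vapply(model$kernels, `[[`, logical(1), "degenerate")))
  y <- apply_sdt(set, model)
  expect_equal(y$x, x, tolerance = 1e-12)
})

test_that("informative blocks achieve larger eigenvalues than noise blocks", {
  hits <- vapply(1:50, function(s) {
    pb <- generate_planted_blocks(
      planted_block_spec(n_informative = 3L, n_noise = 3L, seed = s),
      n_per_subcat = 5
    )
    sub <- form_subcategories(pb$subcategories, pb$labels)
    model <- suppressMessages(fit_sdt(pb$x, sub, 3L))
    td <- tidy(model)
    mean(td$eigenvalue[td$modality == "SIG"]) >
      mean(td$eigenvalue[td$modality == "NOISE"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("FDT agrees with SDT when each class is one noise-free subcategory", {
  cosines <- vapply(1:20, function(s) {
    pb <- generate_planted_blocks(
      planted_block_spec(n_classes = 2L, n_subcats = 1L, noise_sd = 0,
                         n_noise = 0L, seed = s),
      n_per_subcat = 6
    )
    sub <- form_subcategories(rep(1, 12), pb$labels)
    msdt <- suppressMessages(fit_sdt(pb$x, sub, 3L))
    mfdt <- suppressMessages(fit_fdt(pb$x, pb$labels, 3L))
    min(mapply(function(a, b) abs(sum(a$taps * b$taps)),
               msdt$kernels, mfdt$kernels))
  }, numeric(1))
  expect_true(all(cosines >= 0.99))
})

test_that("FDT handles singleton classes and stores one kernel per block", {
  pb <- generate_planted_blocks(planted_block_spec(seed = 4), n_per_subcat = 3)
  model <- suppressMessages(fit_fdt(pb$x, pb$labels, 3L))
  expect_equal(length(model$kernels), sum(pb$x$layout$n_blocks))
  expect_equal(model$mode, "FDT")
  # one sample per class: within-scatter zero, degenerate handling kicks in
  x <- pb$x$x[c(1, 20), ]
  set <- structure(list(x = x, layout = pb$x$layout), class = "descriptor_set")
  model1 <- suppressMessages(fit_fdt(set, c(1, 2), 3L))
  expect_equal(length(model1$kernels), sum(pb$x$layout$n_blocks))
  expect_error(fit_fdt(set, c(1, 1), 3L), "two classes")
})

test_that("scatter ratios never decrease after fitting the transform", {
  pb <- generate_planted_blocks(planted_block_spec(seed = 6), n_per_subcat = 5)
  sub <- form_subcategories(pb$subcategories, pb$labels)
  model <- suppressMessages(fit_sdt(pb$x, sub, c(SIG = 5L, NOISE = 3L)))
  r <- scatter_ratios(pb$x, sub, model)
  expect_equal(nrow(r), sum(pb$x$layout$n_blocks))
  nondeg <- !r$degenerate & is.finite(r$ratio)
  expect_true(all(r$ratio_after[nondeg] >= r$ratio[nondeg]))
  # delta-kernel model: ratios equal raw ratios
  bt <- block_table(pb$x$layout)
  kernels <- lapply(seq_len(nrow(bt)), function(b) {
    list(taps = sdtimage:::delta_kernel(3L), eigenvalue = 0, ridge = 0,
         degenerate = FALSE)
  })
  dmodel <- sdtimage:::new_sdt_model(kernels, pb$x$layout,
                                     c(SIG = 3L, NOISE = 3L), "SDT")
  rd <- scatter_ratios(pb$x, sub, dmodel)
  expect_equal(rd$ratio_after, rd$ratio, tolerance = 1e-12)
})

test_that("fitted models survive a JSON round-trip", {
  pb <- generate_planted_blocks(planted_block_spec(seed = 7), n_per_subcat = 3)
  sub <- form_subcategories(pb$subcategories, pb$labels)
  model <- suppressMessages(fit_sdt(pb$x, sub, 3L))
  path <- withr::local_tempfile(fileext = ".json")
  write_sdt_model(model, path)
  model2 <- read_sdt_model(path)
  expect_equal(model2$kernel_sizes, model$kernel_sizes)
  y1 <- apply_sdt(pb$x, model)
  y2 <- apply_sdt(pb$x, model2)
  expect_equal(y1$x, y2$x, tolerance = 1e-12)
})
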