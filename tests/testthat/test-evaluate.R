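separable_data <- function(n = 20, gap = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(2 * n), n, 2),
               matrix(rnorm(2 * n, mean = gap), n, 2))
  })
  list(x = x, y = rep(c("a", "b"), each = n))
}

test_that("linearly separable clouds are fit perfectly; margins retrievable", {
  d <- separable_data()
  clf <- train_classifier(d$x, d$y)
  expect_equal(mean(as.character(predict(clf, d$x)) == d$y), 1)
  m <- svm_margins(clf)
  expect_equal(nrow(m), 2)
  expect_true(all(m$margin > 0))
  expect_error(train_classifier(d$x, rep("a", nrow(d$x))), "two classes")
})

test_that("duplicating every training point leaves the decision function unchanged", {
  d <- separable_data(seed = 2)
  clf1 <- train_classifier(d$x, d$y)
  clf2 <- train_classifier(rbind(d$x, d$x), c(d$y, d$y))
  withr::with_seed(3, probe <- matrix(rnorm(40), 20, 2))
  expect_equal(predict(clf1, probe, type = "decision"),
               predict(clf2, probe, type = "decision"), tolerance = 1e-6)
})

test_that("three-class one-vs-rest classification works on descriptor sets", {
  pb <- generate_planted_blocks(planted_block_spec(seed = 5), n_per_subcat = 6)
  clf <- train_classifier(pb$x, pb$labels)
  expect_equal(mean(as.character(predict(clf, pb$x)) == as.character(pb$labels)), 1)
  dv <- predict(clf, pb$x$x, type = "decision")
  expect_equal(dim(dv), c(nrow(pb$x$x), 3L))
})

test_that("paired comparison handles ties, shifts and hand-computed t", {
  same <- c(0.9, 0.8, 0.85)
  r <- paired_comparison(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$flag, "exact_tie")

  d <- c(0.02, 0.03, 0.01, 0.02)
  r2 <- paired_comparison(0.5 + d, rep(0.5, 4))
  expect_equal(r2$statistic, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_equal(r2$df, 3)
  # shift invariance
  r3 <- paired_comparison(0.7 + d, rep(0.7, 4))
  expect_equal(r3$statistic, r2$statistic, tolerance = 1e-12)
  # zero variance, non-zero mean
  r4 <- paired_comparison(c(0.8, 0.8), c(0.7, 0.7))
  expect_equal(r4$p_value, 0)
  expect_equal(r4$flag, "zero_variance")
})

test_that("stratified folds cover every class in every fold", {
  labels <- rep(1:3, times = c(10, 7, 12))
  folds <- stratified_folds(labels, 5, seed = 4)
  for (f in 1:5) {
    expect_equal(sort(unique(labels[folds == f])), 1:3)
  }
  expect_error(stratified_folds(rep(1:2, c(10, 3)), 5), "2")
})

test_that("kernel-size search obeys the range contract and tie-break rule", {
  pb <- generate_planted_blocks(
    planted_block_spec(n_informative = 2L, n_noise = 1L, seed = 8),
    n_per_subcat = 6
  )
  cfg <- pipeline_config(llc_sparsity = 8L, search_runs = 2L)
  prot <- eval_protocol(seed = 3)
  sizes <- select_kernel_sizes(pb$x, pb$labels, cfg, prot)
  expect_equal(sort(names(sizes)), sort(unique(pb$x$layout$modality)))
  expect_true(all(sizes %in% c(3L, 5L, 7L, 9L)))
  # deterministic given the seed
  sizes2 <- select_kernel_sizes(pb$x, pb$labels, cfg, prot)
  expect_identical(sizes, sizes2)
  # when every candidate ties (identical descriptors -> constant accuracy)
  # the tie-break picks the smallest D
  x <- matrix(rep(seq_len(24), times = 16), 16, 24, byrow = FALSE)
  x <- x + 0 # constant columns per row pattern: identical for all samples
  x <- matrix(rep(c(1:24), each = 16), 16, 24)
  layout <- tibble::tibble(modality = "SIG", n_blocks = 2L, dim = 12L)
  set <- structure(list(x = x, layout = layout), class = "descriptor_set")
  labels <- rep(1:2, each = 8)
  cfg2 <- pipeline_config(llc_sparsity = 4L, search_runs = 2L, transform = "fdt")
  sizes3 <- suppressMessages(select_kernel_sizes(set, labels, cfg2,
                                                 eval_protocol(seed = 1)))
  expect_equal(unname(sizes3), 3L)
})

test_that("split standard error matches the hand formula", {
  accs <- c(0.8, 0.9, 0.85)
  expect_equal(sd(accs) / sqrt(3), sqrt(sum((accs - mean(accs))^2) / 2) / sqrt(3))
})

test_that("the protocol report is consistent and leak-free with an oracle classifier", {
  ds <- generate_texture_dataset(
    texture_spec(noise_sd = 4, seed = 21), n_per_class = 10
  )
  truth <- ds$labels
  oracle <- function(x_train, y_train, train_idx) {
    function(x_test, test_idx) truth[test_idx]
  }
  cfg <- pipeline_config(modalities = c("LBP", "CENTRIST"), transform = "none")
  rep <- run_protocol(ds$images, ds$labels, cfg,
                      eval_protocol(n_splits = 2L, seed = 5),
                      classifier_fn = oracle)
  expect_equal(rep$mean_accuracy, 1)
  expect_true(all(rep$folds$accuracy == 1))
  cm <- rep$confusion
  expect_equal(sum(cm), 2 * length(ds$images)) # 2 splits x every image once
  expect_equal(sum(diag(cm)), sum(cm))
  # confusion row sums equal per-class test counts
  expect_equal(unname(rowSums(cm)), as.vector(2 * table(ds$labels)),
               ignore_attr = TRUE)
})

test_that("the protocol is reproducible given identical seeds", {
  ds <- generate_texture_dataset(
    texture_spec(noise_sd = 4, seed = 22), n_per_class = 6
  )
  cfg <- pipeline_config(modalities = c("LBP", "HOG"), transform = "fdt",
                         svm_cost = 1)
  prot <- eval_protocol(n_folds = 3L, n_splits = 2L, seed = 9)
  r1 <- suppressMessages(run_protocol(ds$images, ds$labels, cfg, prot))
  r2 <- suppressMessages(run_protocol(ds$images, ds$labels, cfg, prot))
  expect_equal(r1$folds, r2$folds)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(r1$mean_accuracy, r2$mean_accuracy)
})

test_that("protocol errors when a class has fewer samples than folds", {
  ds <- generate_texture_dataset(texture_spec(seed = 23), n_per_class = 3)
  expect_error(
    run_protocol(ds$images, ds$labels,
                 pipeline_config(modalities = "LBP", transform = "none"),
                 eval_protocol(n_folds = 5L, n_splits = 1L)),
    "fewer samples"
  )
})
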