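#' Evaluation protocol and pipeline configuration
#'
#' `eval_protocol()` fixes the repeated stratified cross-validation scheme
#' (5-fold, 10 splits by default, with 4-fold inner
#' cross-validation for the sequential kernel-size search).
#' `pipeline_config()` collects every tunable of the descriptor + SDT +
#' SVM pipeline with its standard defaults; unknown fields are rejected.
#'
#' @param n_folds Outer cross-validation folds (stratified by class).
#' @param n_splits Number of repeated splits.
#' @param inner_folds Folds of the inner search cross-validation.
#' @param seed Base seed; every random stage derives its seed from it.
#' @param kernel_size_range Candidate kernel lengths for the search.
#' @return A list of class `eval_protocol` / `pipeline_config`.
#' @export
eval_protocol <- function(n_folds = 5L, n_splits = 10L, inner_folds = 4L,
                          seed = 1L, kernel_size_range = c(3L, 5L, 7L, 9L)) {
  stopifnot(n_folds >= 2L, n_splits >= 1L, inner_folds >= 2L)
  structure(
    list(
      n_folds = as.integer(n_folds), n_splits = as.integer(n_splits),
      inner_folds = as.integer(inner_folds), seed = as.integer(seed),
      kernel_size_range = as.integer(kernel_size_range)
    ),
    class = "eval_protocol"
  )
}

#' @rdname eval_protocol
#' @param ... Overrides of the default configuration fields (see Details).
#' @details Configuration fields: `modalities` (subset of IFV, LBP, HOG,
#'   CENTRIST, GIST), `sift_bin_widths`, `sift_step`, `pca_dim`,
#'   `n_components` (GMM size), `ifv_max_samples` (pooled SIFT cap for the
#'   codebook fit), `whiten`, `ifv_normalize`, `llc_sparsity` (20),
#'   `llc_balance` (1e-4), `kernel_sizes` (scalar or modality-named, in
#'   {3,5,7,9}), `search_kernel_sizes` (run the sequential search inside
#'   each training fold), `search_runs` (inner-CV repetitions per
#'   candidate), `transform` ("sdt", "fdt" or "none") and `svm_cost`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    modalities = c("IFV", "LBP", "HOG", "CENTRIST", "GIST"),
    sift_bin_widths = c(2L, 4L, 6L, 8L, 10L),
    sift_step = 2L,
    pca_dim = 64L,
    n_components = 64L,
    ifv_max_samples = 100000L,
    whiten = FALSE,
    ifv_normalize = "improved",
    llc_sparsity = 20L,
    llc_balance = 1e-4,
    kernel_sizes = 3L,
    search_kernel_sizes = FALSE,
    search_runs = 5L,
    transform = "sdt",
    svm_cost = 1
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown configuration field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, override)
  stopifnot(
    all(cfg$modalities %in% MODALITY_ORDER),
    cfg$transform %in% c("sdt", "fdt", "none"),
    cfg$llc_sparsity >= 1L, cfg$llc_balance > 0
  )
  structure(cfg, class = "pipeline_config")
}

#' Stratified fold assignment
#'
#' @param labels Class labels.
#' @param n_folds Number of folds; every class must have at least
#'   `n_folds` members.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1L) {
  labels <- as.factor(labels)
  sizes <- table(labels)
  short <- names(sizes)[sizes < n_folds]
  if (length(short)) {
    abort(paste0(
      "class(es) with fewer samples than folds (", n_folds, "): ",
      paste(short, collapse = ", ")
    ))
  }
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Paired comparison of per-unit accuracies
#'
#' Two-sided paired t-test on the differences `acc_a - acc_b`, paired by
#' identical splits/folds.  Degenerate difference vectors are handled
#' explicitly: zero variance with non-zero mean reports `p = 0` with flag
#' `"zero_variance"`; all-zero differences report `t = 0`, `p = 1`.
#'
#' @param acc_a,acc_b Equal-length (>= 2) accuracy vectors.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_diff`,
#'   `flag`.
#' @export
paired_comparison <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2L)
  d <- acc_a - acc_b
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble(statistic = 0, df = n - 1L, p_value = 1,
                    mean_diff = 0, flag = "exact_tie"))
    }
    return(tibble(statistic = sign(mean(d)) * Inf, df = n - 1L, p_value = 0,
                  mean_diff = mean(d), flag = "zero_variance"))
  }
  tt <- t.test(acc_a, acc_b, paired = TRUE)
  tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_diff = mean(d), flag = "ok"
  )
}

#' Sequential kernel-size search
#'
#' The five modality kernel sizes are selected one at a time in the fixed
#' order IFV, LBP, HOG, CENTRIST, GIST: with the other sizes held fixed,
#' every candidate `D` is scored by `search_runs` seeded runs of
#' `inner_folds`-fold cross-validation (subcategories + SDT + linear SVM
#' refitted on every inner training portion) and the winner is chosen by
#' majority vote over runs, ties broken toward the smaller `D`.
#'
#' @param x Training `descriptor_set`.
#' @param labels Training class labels.
#' @param config A `pipeline_config` (LLC, transform and SVM settings).
#' @param protocol An `eval_protocol` (`inner_folds`, `kernel_size_range`,
#'   base seed).
#' @param seed Overrides the protocol seed when given.
#' @return Named integer vector, modality -> D.
#' @export
select_kernel_sizes <- function(x, labels, config = pipeline_config(),
                                protocol = eval_protocol(), seed = NULL) {
  stopifnot(inherits(x, "descriptor_set"))
  seed <- as.integer(seed %||% protocol$seed)
  modalities <- order_modalities(x$layout$modality)
  sizes <- stats::setNames(rep(min(protocol$kernel_size_range), length(modalities)),
                           modalities)
  bt <- x$layout
  for (m in modalities) {
    dim_m <- bt$dim[bt$modality == m][1]
    candidates <- protocol$kernel_size_range[protocol$kernel_size_range < dim_m]
    if (length(candidates) <= 1L) {
      if (length(candidates) == 1L) sizes[[m]] <- candidates
      next
    }
    votes <- stats::setNames(integer(length(candidates)), candidates)
    for (run in seq_len(config$search_runs)) {
      run_seed <- seed + 1009L * run
      folds <- stratified_folds(labels, protocol$inner_folds, seed = run_seed)
      acc <- vapply(candidates, function(Dc) {
        trial <- sizes
        trial[[m]] <- Dc
        mean(vapply(seq_len(protocol$inner_folds), function(f) {
          inner_fold_accuracy(x, labels, folds == f, trial, config, run_seed + f)
        }, numeric(1)))
      }, numeric(1))
      best <- candidates[which.max(acc)] # which.max: first max -> smaller D
      votes[[as.character(best)]] <- votes[[as.character(best)]] + 1L
    }
    sizes[[m]] <- candidates[which.max(votes)]
  }
  sizes
}

# accuracy of one inner fold: fit subcategories + transform + SVM on the
# inner training portion, classify the held-out portion
inner_fold_accuracy <- function(x, labels, test_mask, kernel_sizes, config, seed) {
  xt <- x$x[!test_mask, , drop = FALSE]
  yt <- labels[!test_mask]
  xe <- x$x[test_mask, , drop = FALSE]
  ye <- labels[test_mask]
  model <- fit_transform(xt, yt, x$layout, kernel_sizes, config, seed)
  if (!is.null(model)) {
    xt <- apply_sdt(xt, model)
    xe <- apply_sdt(xe, model)
  }
  clf <- train_classifier(xt, yt, cost = config$svm_cost)
  mean(as.character(predict(clf, xe)) == as.character(ye))
}

# fit the configured transform (or NULL for "none")
fit_transform <- function(x, labels, layout, kernel_sizes, config, seed) {
  if (config$transform == "none") return(NULL)
  set <- structure(list(x = x, layout = layout), class = "descriptor_set")
  if (config$transform == "fdt") {
    return(suppressMessages(fit_fdt(set, labels, kernel_sizes)))
  }
  subcats <- suppressMessages(generate_subcategories(
    set, labels,
    sparsity = min(config$llc_sparsity, nrow(x) - 1L),
    balance = config$llc_balance, seed = seed
  ))
  suppressMessages(fit_sdt(set, subcats, kernel_sizes))
}

#' Run the full cross-validated classification protocol
#'
#' For every split and fold the entire pipeline is refitted on the
#' training portion only — IFV codebook, subcategories, transform and
#' classifier — and the held-out fold is encoded with the training-fold
#' codebook, transformed and classified.  No information from a test fold
#' enters any fitting stage.  Texture descriptors and dense SIFT sets are
#' deterministic per-image quantities and are computed once up front.
#'
#' @param images List of gray-intensity matrices.
#' @param labels Class labels (length of `images`).
#' @param config A `pipeline_config`.
#' @param protocol An `eval_protocol`.
#' @param classifier_fn Optional testing hook replacing the classifier:
#'   called as `classifier_fn(x_train, y_train, train_idx)` and must return
#'   `function(x_test, test_idx)` yielding predicted labels.
#' @return An `sdt_eval` report: per-fold and per-split accuracy tibbles,
#'   mean accuracy, standard error (sd of split accuracies / sqrt of the
#'   number of splits), pooled confusion matrix (rows = true class) and
#'   the kernel sizes used per fold.
#' @export
run_protocol <- function(images, labels, config = pipeline_config(),
                         protocol = eval_protocol(), classifier_fn = NULL) {
  stopifnot(length(images) == length(labels))
  labels <- as.factor(labels)
  classes <- levels(labels)
  n <- length(images)

  use_ifv <- "IFV" %in% config$modalities
  sift_sets <- NULL
  if (use_ifv) {
    sift_sets <- lapply(images, extract_dense_sift,
                        bin_widths = config$sift_bin_widths,
                        step = config$sift_step)
  }
  texture_parts <- lapply(images, function(img) {
    parts <- list()
    if ("LBP" %in% config$modalities) parts$LBP <- extract_lbp_grid(img)
    if ("HOG" %in% config$modalities) parts$HOG <- extract_hog_grid(img)
    if ("CENTRIST" %in% config$modalities) parts$CENTRIST <- extract_centrist(img)
    if ("GIST" %in% config$modalities) parts$GIST <- extract_gist_grid(img)
    parts
  })

  fold_rows <- list()
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  for (split in seq_len(protocol$n_splits)) {
    split_seed <- protocol$seed + 7919L * split
    folds <- stratified_folds(labels, protocol$n_folds, seed = split_seed)
    for (f in seq_len(protocol$n_folds)) {
      fold_seed <- split_seed + 97L * f
      test_mask <- folds == f
      train_idx <- which(!test_mask)
      test_idx <- which(test_mask)

      codebook <- NULL
      if (use_ifv) {
        codebook <- fit_ifv_codebook(
          sift_sets[train_idx],
          pca_dim = config$pca_dim, n_components = config$n_components,
          seed = fold_seed, max_samples = config$ifv_max_samples,
          whiten = config$whiten
        )
      }
      descs <- lapply(seq_len(n), function(i) {
        parts <- texture_parts[[i]]
        if (use_ifv) {
          parts$IFV <- encode_ifv(sift_sets[[i]], codebook,
                                  normalize = config$ifv_normalize)
        }
        assemble_descriptor(parts, config$modalities)
      })
      set <- descriptor_set(descs)
      x_train <- set$x[train_idx, , drop = FALSE]
      y_train <- labels[train_idx]
      x_test <- set$x[test_idx, , drop = FALSE]

      kernel_sizes <- config$kernel_sizes
      if (config$search_kernel_sizes && config$transform != "none") {
        train_set <- structure(list(x = x_train, layout = set$layout),
                               class = "descriptor_set")
        kernel_sizes <- select_kernel_sizes(
          train_set, y_train, config, protocol, seed = fold_seed
        )
      }
      model <- fit_transform(x_train, y_train, set$layout, kernel_sizes,
                             config, fold_seed)
      if (!is.null(model)) {
        x_train <- apply_sdt(x_train, model)
        x_test <- apply_sdt(x_test, model)
      }
      if (is.null(classifier_fn)) {
        clf <- train_classifier(x_train, y_train, cost = config$svm_cost)
        pred <- as.character(predict(clf, x_test))
      } else {
        predictor <- classifier_fn(x_train, y_train, train_idx)
        pred <- as.character(predictor(x_test, test_idx))
      }
      truth <- as.character(labels[test_idx])
      for (i in seq_along(truth)) {
        confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
      }
      sizes_used <- if (is.null(model)) NA_character_ else {
        paste(sprintf("%s=%d", names(model$kernel_sizes), model$kernel_sizes),
              collapse = ",")
      }
      fold_rows[[length(fold_rows) + 1L]] <- tibble(
        split = split, fold = f, n_test = length(test_idx),
        n_correct = sum(pred == truth),
        accuracy = mean(pred == truth),
        kernel_sizes = sizes_used
      )
    }
  }
  folds_tb <- dplyr::bind_rows(fold_rows)
  splits_tb <- folds_tb |>
    dplyr::group_by(.data$split) |>
    dplyr::summarise(
      accuracy = sum(.data$n_correct) / sum(.data$n_test), .groups = "drop"
    )
  se <- if (nrow(splits_tb) > 1L) {
    sd(splits_tb$accuracy) / sqrt(nrow(splits_tb))
  } else {
    NA_real_
  }
  structure(
    list(
      folds = folds_tb, splits = splits_tb,
      mean_accuracy = mean(splits_tb$accuracy), std_error = se,
      confusion = confusion, config = config, protocol = protocol
    ),
    class = "sdt_eval"
  )
}

#' @export
print.sdt_eval <- function(x, ...) {
  cat(sprintf(
    "<sdt_eval> %d splits x %d folds (%s, %s): accuracy %.1f%% +/- %.1f%%\n",
    x$protocol$n_splits, x$protocol$n_folds,
    paste(x$config$modalities, collapse = "+"), toupper(x$config$transform),
    100 * x$mean_accuracy, 100 * (x$std_error %||% NA_real_)
  ))
  invisible(x)
}
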