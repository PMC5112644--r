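#' Tidy and glance methods
#'
#' `tidy()` on an `sdt_model` returns one row per learned kernel (block,
#' modality, kernel length, achieved eigenvalue, degeneracy flag, taps as a
#' list column); on an `sdt_eval` report one row per split/fold.
#' `glance()` returns one-row summaries.
#'
#' @param x An `sdt_model` or `sdt_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdt_model <- function(x, ...) {
  bt <- block_table(x$layout)
  tibble(
    block = bt$block,
    modality = bt$modality,
    kernel_size = vapply(x$kernels, function(k) length(k$taps), integer(1)),
    eigenvalue = vapply(x$kernels, `[[`, numeric(1), "eigenvalue"),
    degenerate = vapply(x$kernels, `[[`, logical(1), "degenerate"),
    taps = lapply(x$kernels, `[[`, "taps")
  )
}

#' @rdname tidy.sdt_model
#' @export
glance.sdt_model <- function(x, ...) {
  lam <- vapply(x$kernels, `[[`, numeric(1), "eigenvalue")
  tibble(
    mode = x$mode,
    n_kernels = length(x$kernels),
    n_degenerate = sum(vapply(x$kernels, `[[`, logical(1), "degenerate")),
    mean_eigenvalue = mean(lam),
    median_eigenvalue = stats::median(lam)
  )
}

#' @rdname tidy.sdt_model
#' @export
tidy.sdt_eval <- function(x, ...) {
  x$folds
}

#' @rdname tidy.sdt_model
#' @export
glance.sdt_eval <- function(x, ...) {
  tibble(
    mean_accuracy = x$mean_accuracy,
    std_error = x$std_error,
    n_splits = x$protocol$n_splits,
    n_folds = x$protocol$n_folds,
    transform = x$config$transform,
    modalities = paste(x$config$modalities, collapse = "+")
  )
}

#' Plot an evaluation report
#'
#' Split-level accuracies with the mean +/- one standard error.
#'
#' @param object An `sdt_eval` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sdt_eval <- function(object, ...) {
  ggplot2::ggplot(object$splits, ggplot2::aes(x = .data$split, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      x = "split", y = "accuracy",
      title = sprintf("%s (%s): %.1f%% +/- %.1f%%",
                      toupper(object$config$transform),
                      paste(object$config$modalities, collapse = "+"),
                      100 * object$mean_accuracy,
                      100 * (object$std_error %||% NA_real_))
    )
}

#' Plot per-block scatter ratios before and after the transform
#'
#' Mirrors the feature-space diagnostic: one point per block, raw ratio on
#' the x axis, transformed ratio on the y axis, the identity line for
#' reference.  Infinite (degenerate) ratios are dropped with a message.
#'
#' @param ratios Tibble from [scatter_ratios()] (with a model, so that
#'   `ratio_after` is present).
#' @return A ggplot object.
#' @export
plot_scatter_ratios <- function(ratios) {
  stopifnot("ratio_after" %in% names(ratios))
  keep <- is.finite(ratios$ratio) & is.finite(ratios$ratio_after)
  if (!all(keep)) {
    inform(sprintf("dropping %d block(s) with infinite ratio", sum(!keep)))
  }
  ggplot2::ggplot(ratios[keep, ],
                  ggplot2::aes(x = .data$ratio, y = .data$ratio_after,
                               colour = .data$modality)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "V_betw / V_with (raw)", y = "V_betw / V_with (after transform)",
      title = sprintf("%d of %d blocks improved",
                      sum(ratios$improved[keep]), sum(keep))
    )
}
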