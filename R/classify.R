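#' Linear-kernel multi-class SVM (one-vs-rest)
#'
#' Trains one binary linear SVM per class (positive class vs the rest,
#' `e1071::svm`, no feature scaling) and classifies by the maximum decision
#' value.  The geometric margin `2 / ||w||` of every binary hyperplane is
#' retained for diagnostics.
#'
#' @param x N x H feature matrix (or a `descriptor_set`).
#' @param labels Class labels (length N, at least two distinct values, at
#'   least one sample each).
#' @param cost Soft-margin constant C.
#' @return A `linear_svm` model.
#' @export
train_classifier <- function(x, labels, cost = 1) {
  if (inherits(x, "descriptor_set")) x <- x$x
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- as.factor(labels)
  classes <- levels(droplevels(labels))
  if (length(classes) < 2L) abort("need at least two classes to train a classifier")
  binaries <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(predict(m, x, decision.values = TRUE), "decision.values")[, 1]
    flip <- mean(dv[y == "pos"]) < mean(dv[y == "neg"])
    w <- t(m$coefs) %*% m$SV
    list(model = m, flip = flip, margin = 2 / sqrt(sum(w^2)))
  })
  structure(
    list(classes = classes, binaries = binaries, cost = cost),
    class = "linear_svm"
  )
}

#' @rdname train_classifier
#' @param object A `linear_svm`.
#' @param newdata Feature matrix (or `descriptor_set`) to classify.
#' @param type `"class"` for predicted labels, `"decision"` for the matrix
#'   of per-class decision values.
#' @param ... Unused.
#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "descriptor_set")) newdata <- newdata$x
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  dv <- vapply(object$binaries, function(b) {
    v <- attr(predict(b$model, newdata, decision.values = TRUE),
              "decision.values")[, 1]
    if (b$flip) -v else v
  }, numeric(nrow(newdata)))
  dv <- matrix(dv, nrow = nrow(newdata),
               dimnames = list(NULL, object$classes))
  if (type == "decision") return(dv)
  factor(object$classes[max.col(dv, ties.method = "first")],
         levels = object$classes)
}

#' Separation margins of the trained hyperplanes
#'
#' @param model A `linear_svm`.
#' @return Tibble with one row per binary (class vs rest) problem:
#'   `class`, `margin`.
#' @export
svm_margins <- function(model) {
  tibble(
    class = model$classes,
    margin = vapply(model$binaries, `[[`, numeric(1), "margin")
  )
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf(
    "<linear_svm> one-vs-rest, %d classes, C = %g, mean margin %.4g\n",
    length(x$classes), x$cost, mean(svm_margins(x)$margin)
  ))
  invisible(x)
}
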