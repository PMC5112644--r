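#' Grayscale image utilities
#'
#' Images are plain numeric matrices (rows = image rows, top-left origin)
#' with intensities in `[0, 255]`.  `rgb_to_gray()` collapses an RGB array
#' with the standard luma weights (0.2989, 0.5870, 0.1140);
#' `rescale_intensity()` linearly maps intensities onto `[0, 255]` when the
#' native range requires it (16-bit inputs, unit-scale floats).
#'
#' @param rgb A height x width x 3 (or more; extra channels ignored) numeric
#'   array, or a matrix (returned unchanged apart from rounding).
#' @param round Round the result to integer gray levels (8-bit convention)?
#' @return A numeric matrix of gray intensities.
#' @examples
#' px <- array(0, c(2, 2, 3)); px[, , 1] <- 255
#' rgb_to_gray(px)[1, 1] # pure red -> 76
#' @export
rgb_to_gray <- function(rgb, round = TRUE) {
  if (is.matrix(rgb)) {
    g <- rgb
  } else {
    stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] >= 3L)
    g <- 0.2989 * rgb[, , 1] + 0.5870 * rgb[, , 2] + 0.1140 * rgb[, , 3]
  }
  if (round) g <- round(g)
  g
}

#' @rdname rgb_to_gray
#' @param pixels Numeric matrix of intensities.
#' @export
rescale_intensity <- function(pixels) {
  rng <- range(pixels, finite = TRUE)
  if (rng[1] >= 0 && rng[2] <= 255 && rng[2] > 1) {
    return(pixels)
  }
  if (rng[2] == rng[1]) {
    return(matrix(0, nrow(pixels), ncol(pixels)))
  }
  (pixels - rng[1]) / (rng[2] - rng[1]) * 255
}

# validate the gray-image contract; min_size is per-operation (the gridded
# extractors need >= 32 px, the census transform only needs a 3x3 interior)
validate_gray_image <- function(image, min_size = 3L, what = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix of intensities", what))
  }
  if (nrow(image) < min_size || ncol(image) < min_size) {
    abort(sprintf(
      "`%s` is %d x %d but must be at least %d x %d",
      what, nrow(image), ncol(image), min_size, min_size
    ))
  }
  if (anyNA(image) || any(!is.finite(image))) {
    abort(sprintf("`%s` contains non-finite values", what))
  }
  if (min(image) < 0 || max(image) > 255) {
    abort(sprintf("`%s` has intensities outside [0, 255]; rescale_intensity() first", what))
  }
  invisible(image)
}

# half-open 4x4 grid partition: cell (i, j) covers rows
# floor((i-1)*H/4)+1 .. floor(i*H/4); boundary cells absorb remainders
grid_bounds <- function(n, cells = 4L) {
  lo <- floor((seq_len(cells) - 1L) * n / cells) + 1L
  hi <- floor(seq_len(cells) * n / cells)
  cbind(lo = lo, hi = hi)
}
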