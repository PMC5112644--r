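#' Dense multi-scale SIFT extraction
#'
#' Extracts 128-dimensional SIFT descriptors (4 x 4 spatial bins x 8
#' orientation bins) on a regular grid at several scales.  The scale of a
#' descriptor is the width of one spatial bin in pixels, so a descriptor's
#' support is `4 * bin_width` pixels wide with bilinear spatial weighting
#' extending `bin_width - 1` pixels beyond the outer bin centres.
#' Descriptors whose support would cross the image border are omitted.
#' Each descriptor is L2-normalised, clipped at 0.2 and renormalised (the
#' standard SIFT convention); all-zero descriptors (flat image regions) are
#' left at zero.
#'
#' @param image Numeric matrix, intensities in `[0, 255]`.
#' @param bin_widths Integer vector of spatial bin widths in pixels.
#' @param step Sampling stride of the descriptor grid in pixels.
#' @return An object of class `dense_sift`: a list with `descriptors`
#'   (n x 128 matrix), `positions` (n x 2 matrix of row/col centres) and
#'   `scale` (length-n vector of bin widths).
#' @export
extract_dense_sift <- function(image, bin_widths = c(2L, 4L, 6L, 8L, 10L),
                               step = 2L) {
  stopifnot(step >= 1L)
  bin_widths <- sort(unique(as.integer(bin_widths)))
  min_dim <- 5L * max(bin_widths) - 1L # full support of the largest scale
  if (nrow(image) < min_dim || ncol(image) < min_dim) {
    abort(sprintf(
      "image is %d x %d but dense SIFT with bin width %d needs at least %d x %d",
      nrow(image), ncol(image), max(bin_widths), min_dim, min_dim
    ))
  }
  validate_gray_image(image, min_size = 3L)

  omaps <- orientation_maps(image) # list of 8 weighted magnitude maps
  H <- nrow(image); W <- ncol(image)

  out_desc <- list(); out_pos <- list(); out_scale <- list()
  for (w in bin_widths) {
    # bilinearly pooled response of each orientation map at every pixel:
    # separable triangular kernel of half-width w
    Th <- triangle_band(H, w)
    Tw <- triangle_band(W, w)
    pooled <- lapply(omaps, function(m) Th %*% m %*% Tw)

    centers_r <- sift_grid_centers(H, w, step)
    centers_c <- sift_grid_centers(W, w, step)
    if (length(centers_r) == 0L || length(centers_c) == 0L) next
    nr <- length(centers_r); nc <- length(centers_c); n <- nr * nc
    # spatial bin centres at offsets -1.5w, -0.5w, 0.5w, 1.5w (integers for
    # even w); descriptor layout: spatial bins row-major, orientations fastest
    offs <- w * c(-1.5, -0.5, 0.5, 1.5)
    desc <- matrix(0, n, 128L)
    col0 <- 0L
    for (dr in offs) {
      for (dc in offs) {
        rr <- centers_r + dr
        cc <- centers_c + dc
        for (k in seq_len(8L)) {
          desc[, col0 + k] <- as.vector(pooled[[k]][rr, cc, drop = FALSE])
        }
        col0 <- col0 + 8L
      }
    }
    desc <- sift_normalize(desc)
    pos <- cbind(
      row = rep(centers_r, times = nc),
      col = rep(centers_c, each = nr)
    )
    out_desc[[length(out_desc) + 1L]] <- desc
    out_pos[[length(out_pos) + 1L]] <- pos
    out_scale[[length(out_scale) + 1L]] <- rep(w, n)
  }
  structure(
    list(
      descriptors = do.call(rbind, out_desc),
      positions = do.call(rbind, out_pos),
      scale = unlist(out_scale)
    ),
    class = "dense_sift"
  )
}

# valid descriptor centres for one scale: the outermost spatial bin centre
# (1.5 w away) plus its triangular support (w - 1) must stay inside the image
sift_grid_centers <- function(n, bin_width, step) {
  first <- ceiling(2.5 * bin_width)
  last <- n - first + 1L
  if (last < first) return(integer(0))
  seq.int(first, last, by = step)
}

# 8 orientation-binned gradient magnitude maps with bilinear orientation
# weighting; gradients by central differences, zero at the border
orientation_maps <- function(image) {
  H <- nrow(image); W <- ncol(image)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  if (W >= 3L) gx[, 2:(W - 1L)] <- (image[, 3:W] - image[, 1:(W - 2L)]) / 2
  if (H >= 3L) gy[2:(H - 1L), ] <- (image[3:H, ] - image[1:(H - 2L), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  a <- ang / (pi / 4)
  k0 <- floor(a)
  frac <- a - k0
  k0 <- as.integer(k0) %% 8L
  k1 <- (k0 + 1L) %% 8L
  maps <- lapply(seq_len(8L) - 1L, function(k) {
    m <- matrix(0, H, W)
    sel0 <- k0 == k
    sel1 <- k1 == k
    m[sel0] <- m[sel0] + mag[sel0] * (1 - frac[sel0])
    m[sel1] <- m[sel1] + mag[sel1] * frac[sel1]
    m
  })
  maps
}

# banded triangular (bilinear-weight) pooling matrix
triangle_band <- function(n, w) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- 1 - d / w
  k[k < 0] <- 0
  k
}

# SIFT normalisation: L2, clip at 0.2, renormalise; zero vectors stay zero
sift_normalize <- function(desc, clip = 0.2) {
  nrm <- sqrt(rowSums(desc^2))
  nz <- nrm > 0
  desc[nz, ] <- desc[nz, , drop = FALSE] / nrm[nz]
  desc[desc > clip] <- clip
  nrm2 <- sqrt(rowSums(desc^2))
  nz <- nrm2 > 0
  desc[nz, ] <- desc[nz, , drop = FALSE] / nrm2[nz]
  desc
}

#' @export
print.dense_sift <- function(x, ...) {
  cat(sprintf(
    "<dense_sift> %d descriptors, scales {%s}\n",
    nrow(x$descriptors), paste(sort(unique(x$scale)), collapse = ", ")
  ))
  invisible(x)
}
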