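#' Gridded texture descriptors: uniform LBP, 31-d HOG, GIST, CENTRIST
#'
#' The gridded extractors divide the image into a 4 x 4 grid of cells with
#' half-open boundaries at `floor(i * H / 4)` so the cells tile exactly, and
#' return blocks in row-major cell order.  `extract_lbp_grid()` computes the
#' 58-bin uniform local binary pattern histogram per cell (3 x 3
#' neighbourhood, non-uniform patterns discarded); `extract_hog_grid()`
#' the 31-dimensional HOG variant (18 directed + 9 undirected orientation
#' channels + 4 neighbourhood normalisation-energy features);
#' `extract_gist_grid()` mean magnitude responses of a 32-filter log-Gabor
#' bank (8 orientations x 4 scales) per cell; `extract_centrist()` the
#' global 256-bin census-transform histogram split into four contiguous
#' 64-bin blocks.
#'
#' Neighbour comparisons for LBP and the census transform use
#' `neighbour >= centre -> bit 1`, with bits ordered clockwise from the
#' top-left neighbour (first neighbour = least significant bit).
#'
#' @param image Numeric matrix, intensities in `[0, 255]`; the gridded
#'   extractors need at least 32 x 32 pixels, `extract_centrist()` at least
#'   3 x 3.
#' @return A `descriptor_part` with one row per block (16 blocks for the
#'   gridded extractors, 4 for CENTRIST).
#' @name texture_descriptors
NULL

# 8-neighbour census codes for interior pixels, clockwise from top-left;
# neighbour >= centre sets the bit, first neighbour is the LSB
census_codes <- function(image) {
  H <- nrow(image); W <- ncol(image)
  stopifnot(H >= 3L, W >= 3L)
  ctr <- image[2:(H - 1L), 2:(W - 1L)]
  shifts <- list( # (dr, dc) clockwise from top-left
    c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
    c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L)
  )
  code <- matrix(0L, H - 2L, W - 2L)
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1]; dc <- shifts[[k]][2]
    nb <- image[(2:(H - 1L)) + dr, (2:(W - 1L)) + dc]
    code <- code + as.integer(nb >= ctr) * 2L^(k - 1L)
  }
  code
}

# lookup 0..255 -> uniform-pattern bin 1..58, NA for non-uniform codes
lbp_uniform_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      codes <- 0:255
      trans <- vapply(codes, function(v) {
        bits <- as.integer(intToBits(v))[1:8]
        sum(bits != bits[c(2:8, 1)])
      }, integer(1))
      uni <- codes[trans <= 2L]
      m <- rep(NA_integer_, 256L)
      m[uni + 1L] <- seq_along(uni)
      lut <<- m
    }
    lut
  }
})

#' @rdname texture_descriptors
#' @export
extract_lbp_grid <- function(image) {
  validate_gray_image(image, min_size = 32L)
  codes <- census_codes(image)
  lut <- lbp_uniform_lut()
  bins <- matrix(lut[codes + 1L], nrow(codes), ncol(codes))
  hist_grid(bins, nrow(image), ncol(image), n_bins = 58L, modality = "LBP")
}

#' @rdname texture_descriptors
#' @export
extract_centrist <- function(image) {
  validate_gray_image(image, min_size = 3L)
  codes <- census_codes(image)
  h <- tabulate(as.vector(codes) + 1L, nbins = 256L)
  descriptor_part("CENTRIST", matrix(h, nrow = 4L, ncol = 64L, byrow = TRUE))
}

# histogram interior-pixel bin labels over the 4x4 grid of the full image;
# a pixel belongs to the cell containing it (offset +1: codes cover rows
# 2..H-1)
hist_grid <- function(bins, H, W, n_bins, modality) {
  rb <- grid_bounds(H); cb <- grid_bounds(W)
  out <- matrix(0, 16L, n_bins)
  blk <- 0L
  for (i in seq_len(4L)) {
    rows <- seq.int(max(rb[i, 1], 2L), min(rb[i, 2], H - 1L)) - 1L
    for (j in seq_len(4L)) {
      blk <- blk + 1L
      cols <- seq.int(max(cb[j, 1], 2L), min(cb[j, 2], W - 1L)) - 1L
      if (length(rows) && length(cols)) {
        v <- bins[rows, cols]
        v <- v[!is.na(v)]
        out[blk, ] <- tabulate(v, nbins = n_bins)
      }
    }
  }
  descriptor_part(modality, out)
}

#' @rdname texture_descriptors
#' @export
extract_hog_grid <- function(image) {
  validate_gray_image(image, min_size = 32L)
  H <- nrow(image); W <- ncol(image)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1L)] <- (image[, 3:W] - image[, 1:(W - 2L)]) / 2
  gy[2:(H - 1L), ] <- (image[3:H, ] - image[1:(H - 2L), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  # snap to the nearest of 18 directed orientation bins
  bin <- (floor(ang / (2 * pi) * 18 + 0.5) %% 18) + 1L

  rb <- grid_bounds(H); cb <- grid_bounds(W)
  directed <- array(0, c(4L, 4L, 18L))
  for (i in seq_len(4L)) {
    for (j in seq_len(4L)) {
      m <- mag[rb[i, 1]:rb[i, 2], cb[j, 1]:cb[j, 2]]
      b <- bin[rb[i, 1]:rb[i, 2], cb[j, 1]:cb[j, 2]]
      directed[i, j, ] <- vapply(
        seq_len(18L), function(k) sum(m[b == k]), numeric(1)
      )
    }
  }
  undirected <- directed[, , 1:9, drop = FALSE] + directed[, , 10:18, drop = FALSE]
  energy <- apply(undirected, c(1, 2), function(v) sum(v^2))

  # block normalisation over the 4 diagonal 2x2 neighbourhoods, with edge
  # clamping on the 4x4 cell grid; features truncated at 0.2
  clamp <- function(i) pmin(pmax(i, 1L), 4L)
  out <- matrix(0, 16L, 31L)
  blk <- 0L
  eps <- 1e-10
  for (i in seq_len(4L)) {
    for (j in seq_len(4L)) {
      blk <- blk + 1L
      d <- directed[i, j, ]; u <- undirected[i, j, ]
      feats_d <- numeric(18L); feats_u <- numeric(9L); tex <- numeric(4L)
      q <- 0L
      for (di in c(-1L, 1L)) {
        for (dj in c(-1L, 1L)) {
          q <- q + 1L
          nb <- expand.grid(r = clamp(c(i, i + di)), c = clamp(c(j, j + dj)))
          nrg <- sum(energy[cbind(nb$r, nb$c)])
          nd <- pmin(d / sqrt(nrg + eps), 0.2)
          nu <- pmin(u / sqrt(nrg + eps), 0.2)
          feats_d <- feats_d + nd
          feats_u <- feats_u + nu
          tex[q] <- sum(nd)
        }
      }
      out[blk, ] <- c(0.5 * feats_d, 0.5 * feats_u, 0.2357 * tex)
    }
  }
  descriptor_part("HOG", out)
}

# log-Gabor filter bank in the frequency domain, memoised per image size;
# 8 orientations x 4 scales, zero DC response
gist_bank_cache <- new.env(parent = emptyenv())

gist_filter_bank <- function(H, W, n_orient = 8L, n_scale = 4L) {
  key <- paste(H, W, n_orient, n_scale, sep = "x")
  if (!is.null(gist_bank_cache[[key]])) return(gist_bank_cache[[key]])
  fr <- (seq_len(H) - 1) / H; fr[fr >= 0.5] <- fr[fr >= 0.5] - 1
  fc <- (seq_len(W) - 1) / W; fc[fc >= 0.5] <- fc[fc >= 0.5] - 1
  FR <- matrix(fr, H, W); FC <- matrix(fc, H, W, byrow = TRUE)
  rad <- sqrt(FR^2 + FC^2)
  theta <- atan2(FR, FC)
  freqs <- 0.25 / 2^(seq_len(n_scale) - 1) # peak frequencies, cycles/pixel
  sigma_theta <- pi / n_orient
  filters <- vector("list", n_orient * n_scale)
  idx <- 0L
  for (s in seq_len(n_scale)) {
    lr <- log2(pmax(rad, 1e-12) / freqs[s])
    radial <- exp(-lr^2 / (2 * 0.55^2))
    radial[rad == 0] <- 0
    for (o in seq_len(n_orient)) {
      ang0 <- (o - 1) * pi / n_orient
      dth <- atan2(sin(theta - ang0), cos(theta - ang0))
      angular <- exp(-dth^2 / (2 * sigma_theta^2))
      idx <- idx + 1L
      filters[[idx]] <- radial * angular # one-sided (complex response)
    }
  }
  gist_bank_cache[[key]] <- filters
  filters
}

#' @rdname texture_descriptors
#' @export
extract_gist_grid <- function(image) {
  validate_gray_image(image, min_size = 32L)
  H <- nrow(image); W <- ncol(image)
  bank <- gist_filter_bank(H, W)
  FI <- fft(image)
  rb <- grid_bounds(H); cb <- grid_bounds(W)
  out <- matrix(0, 16L, 32L)
  for (f in seq_along(bank)) {
    resp <- Mod(fft(FI * bank[[f]], inverse = TRUE)) / (H * W)
    blk <- 0L
    for (i in seq_len(4L)) {
      for (j in seq_len(4L)) {
        blk <- blk + 1L
        out[blk, f] <- mean(resp[rb[i, 1]:rb[i, 2], cb[j, 1]:cb[j, 2]])
      }
    }
  }
  descriptor_part("GIST", out)
}
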