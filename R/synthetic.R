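#' Synthetic multi-class, multi-subcategory texture images
#'
#' Emulates the structure the method assumes in real microscopy data:
#' images of one class share a class-defining property (grating frequency)
#' but split into visually dominant subcategories (grating orientation and
#' blob density, shared across classes), so that within-class variation is
#' large and subcategories of different classes overlap in appearance —
#' clustering the images regardless of labels groups them by subcategory
#' mode, each cluster containing images of several classes.  Each image is
#' an oriented sinusoidal grating (random phase) plus Poisson-placed
#' Gaussian blobs plus additive Gaussian noise, clipped to `[0, 255]`.
#'
#' @param n_classes Number of classes; class `l` uses grating frequency
#'   `frequencies[l]`.
#' @param n_subcats Subcategories per class; subcategory `k` uses
#'   orientation `orientations[k]`, blob density `blob_densities[k]` and
#'   contrast `contrasts[k]`.
#' @param frequencies Grating frequencies (cycles/pixel, in (0, 0.5)), one
#'   per class.
#' @param orientations Grating orientations in radians, one per
#'   subcategory.
#' @param blob_densities Expected blobs per 1000 px^2, one per subcategory.
#' @param contrasts Grating contrast in `[0, 1]`, one per subcategory.
#' @param noise_sd Additive Gaussian intensity noise (gray levels).
#' @param image_size Side length in pixels.
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return A `texture_spec` list.
#' @export
texture_spec <- function(n_classes = 3L, n_subcats = 2L,
                         frequencies = c(0.06, 0.13, 0.27),
                         orientations = c(0, pi / 2),
                         blob_densities = c(0.5, 2),
                         contrasts = c(0.8, 0.8),
                         noise_sd = 8, image_size = 64L, seed = 1L) {
  stopifnot(
    n_classes >= 1L, n_subcats >= 1L,
    length(frequencies) == n_classes, all(frequencies > 0 & frequencies < 0.5),
    length(orientations) == n_subcats,
    length(blob_densities) == n_subcats, all(blob_densities >= 0),
    length(contrasts) == n_subcats, all(contrasts >= 0 & contrasts <= 1),
    noise_sd >= 0, image_size >= 32L
  )
  structure(
    list(
      n_classes = as.integer(n_classes), n_subcats = as.integer(n_subcats),
      frequencies = frequencies, orientations = orientations,
      blob_densities = blob_densities,
      contrasts = contrasts, noise_sd = noise_sd,
      image_size = as.integer(image_size), seed = as.integer(seed)
    ),
    class = "texture_spec"
  )
}

#' @rdname texture_spec
#' @param spec A `texture_spec`.
#' @param n_per_class Images per class (split evenly over subcategories,
#'   remainders to the earlier subcategories).
#' @return `generate_texture_dataset()` returns a list with `images`
#'   (list of matrices), `labels` (integer classes), `subcategories`
#'   (integer true subcategory ids within class) and the `spec`.
#' @export
generate_texture_dataset <- function(spec, n_per_class) {
  stopifnot(inherits(spec, "texture_spec"))
  if (n_per_class < 1L) abort("n_per_class must be at least 1")
  sz <- spec$image_size
  coords_r <- matrix(seq_len(sz), sz, sz)
  coords_c <- matrix(seq_len(sz), sz, sz, byrow = TRUE)

  images <- list(); labels <- integer(0); subcats <- integer(0)
  withr::with_seed(spec$seed, {
    for (l in seq_len(spec$n_classes)) {
      freq <- spec$frequencies[l]
      ks <- rep_len(seq_len(spec$n_subcats), n_per_class)
      for (k in ks) {
        theta <- spec$orientations[k]
        phase <- runif(1, 0, 2 * pi)
        grating <- sin(2 * pi * freq *
                         (coords_c * cos(theta) + coords_r * sin(theta)) + phase)
        img <- 127.5 + spec$contrasts[k] * 127.5 * grating
        n_blobs <- rpois(1, spec$blob_densities[k] * sz * sz / 1000)
        if (n_blobs > 0) {
          for (b in seq_len(n_blobs)) {
            cr <- runif(1, 1, sz); cc <- runif(1, 1, sz)
            amp <- sample(c(-1, 1), 1) * runif(1, 30, 60)
            sigma <- runif(1, 1.5, 3)
            img <- img + amp * exp(-((coords_r - cr)^2 + (coords_c - cc)^2) /
                                     (2 * sigma^2))
          }
        }
        if (spec$noise_sd > 0) {
          img <- img + matrix(rnorm(sz * sz, sd = spec$noise_sd), sz, sz)
        }
        img <- pmin(pmax(img, 0), 255)
        images[[length(images) + 1L]] <- img
        labels <- c(labels, l)
        subcats <- c(subcats, k)
      }
    }
  })
  list(images = images, labels = labels, subcategories = subcats, spec = spec)
}

#' Synthetic block-structured descriptors with planted structure
#'
#' Generates `TrainingSet`-style block descriptors with known subcategory
#' structure: informative blocks carry a class mean plus a shared
#' subcategory-mode mean (both smoothed with a length-`D_true` boxcar so
#' the signal has that correlation length, and lifted to distinct positive
#' element-means so the block-mean statistic used by the transform is
#' discriminative), uninformative blocks are pure noise.  The subcategory
#' mode amplitude exceeds the class amplitude, mimicking data whose
#' within-class variation dominates the between-class difference.
#'
#' @param n_classes,n_subcats Classes and subcategory modes (modes are
#'   shared across classes: subcategory `(l, k)` combines class mean `l`
#'   with mode mean `k`).
#' @param n_informative,n_noise Number of informative / pure-noise blocks.
#' @param block_dim Block dimension `C`.
#' @param D_true Correlation length of the planted signal (odd,
#'   `< block_dim`).
#' @param noise_sd Within-subcategory (and noise-block) standard deviation.
#' @param separation Ratio of the mode amplitude to `noise_sd`.
#' @param class_separation Ratio of the class amplitude to `noise_sd`.
#' @param seed Integer seed.
#' @return A `planted_block_spec`.
#' @export
planted_block_spec <- function(n_classes = 3L, n_subcats = 3L,
                               n_informative = 4L, n_noise = 4L,
                               block_dim = 16L, D_true = 5L,
                               noise_sd = 1, separation = 5,
                               class_separation = 2.5, seed = 1L) {
  stopifnot(
    n_classes >= 2L, n_subcats >= 1L, n_informative >= 1L, n_noise >= 0L,
    D_true %% 2L == 1L, D_true < block_dim, noise_sd >= 0, separation > 0
  )
  structure(
    list(
      n_classes = as.integer(n_classes), n_subcats = as.integer(n_subcats),
      n_informative = as.integer(n_informative), n_noise = as.integer(n_noise),
      block_dim = as.integer(block_dim), D_true = as.integer(D_true),
      noise_sd = noise_sd, separation = separation,
      class_separation = class_separation, seed = as.integer(seed)
    ),
    class = "planted_block_spec"
  )
}

# length-D boxcar smoothing with edge renormalisation
smooth_boxcar <- function(v, D) {
  r <- (D - 1L) %/% 2L
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- max(1L, i - r):min(n, i + r)
    out[i] <- mean(v[w])
  }
  out
}

#' @rdname planted_block_spec
#' @param spec A `planted_block_spec`.
#' @param n_per_subcat Members per (class, mode) subcategory.
#' @return `generate_planted_blocks()` returns a list with `x`
#'   (`descriptor_set`; informative blocks under modality `"SIG"`, noise
#'   blocks under `"NOISE"`), `labels`, `subcategories` (true mode ids)
#'   and the `spec`.
#' @export
generate_planted_blocks <- function(spec, n_per_subcat) {
  stopifnot(inherits(spec, "planted_block_spec"), n_per_subcat >= 1L)
  C <- spec$block_dim
  B <- spec$n_informative + spec$n_noise
  N <- spec$n_classes * spec$n_subcats * n_per_subcat
  H <- B * C

  # amplitudes scale with the noise level; with noise_sd = 0 (noise-free
  # members) `separation` is read in absolute units
  noise_ref <- if (spec$noise_sd > 0) spec$noise_sd else 1
  withr::with_seed(spec$seed, {
    # per-block smoothed unit-scale patterns with distinct mean levels so
    # both direction and element-mean separate the groups
    make_means <- function(n_groups, amplitude) {
      lapply(seq_len(n_groups), function(g) {
        lapply(seq_len(spec$n_informative), function(b) {
          raw <- rnorm(C)
          sm <- smooth_boxcar(raw, spec$D_true)
          sm <- sm / max(sd(sm), 1e-9)
          (sm + g) * amplitude
        })
      })
    }
    class_means <- make_means(spec$n_classes,
                              spec$class_separation * noise_ref)
    mode_means <- make_means(spec$n_subcats, spec$separation * noise_ref)

    x <- matrix(0, N, H)
    labels <- integer(N); modes <- integer(N)
    row <- 0L
    for (l in seq_len(spec$n_classes)) {
      for (k in seq_len(spec$n_subcats)) {
        for (m in seq_len(n_per_subcat)) {
          row <- row + 1L
          labels[row] <- l; modes[row] <- k
          for (b in seq_len(spec$n_informative)) {
            cols <- ((b - 1L) * C + 1L):(b * C)
            x[row, cols] <- class_means[[l]][[b]] + mode_means[[k]][[b]] +
              rnorm(C, sd = spec$noise_sd)
          }
          if (spec$n_noise > 0L) {
            cols <- (spec$n_informative * C + 1L):H
            x[row, cols] <- rnorm(spec$n_noise * C, sd = spec$noise_sd)
          }
        }
      }
    }
  })
  layout <- dplyr::bind_rows(
    tibble(modality = "SIG", n_blocks = spec$n_informative, dim = C),
    if (spec$n_noise > 0L) tibble(modality = "NOISE", n_blocks = spec$n_noise, dim = C)
  )
  list(
    x = structure(list(x = x, layout = layout), class = "descriptor_set"),
    labels = labels, subcategories = modes, spec = spec
  )
}
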