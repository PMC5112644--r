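#' Block-structured descriptors
#'
#' Every extractor returns a `descriptor_part`: the blocks of one modality
#' as a matrix with one row per block.  `assemble_descriptor()` joins parts
#' into the block-structured descriptor `x = {x_b : b = 1..B}`: each
#' modality's concatenated vector is L2-normalised as a whole (all-zero
#' vectors are left at zero) and modalities are concatenated in the fixed
#' order IFV, LBP, HOG, CENTRIST, GIST (unknown modality names follow, in
#' the order requested).  The full five-modality layout (ILHCG, 64-component
#' IFV codebook) has `B = 128 + 16 * 3 + 4 = 180` blocks.
#'
#' @param modality Modality name.
#' @param values Matrix with one row per block.
#' @return `assemble_descriptor()` returns a `block_descriptor`: a list with
#'   the concatenated numeric vector `x` and a `layout` tibble
#'   (modality, n_blocks, dim).
#' @export
descriptor_part <- function(modality, values) {
  stopifnot(is.matrix(values), is.numeric(values))
  structure(list(modality = modality, values = values),
            class = "descriptor_part")
}

#' @rdname descriptor_part
#' @param parts Named list of `descriptor_part` objects (names ignored; the
#'   parts carry their modality).
#' @param modalities Modalities to assemble; defaults to all parts present.
#' @export
assemble_descriptor <- function(parts, modalities = NULL) {
  if (inherits(parts, "descriptor_part")) parts <- list(parts)
  names(parts) <- vapply(parts, function(p) p$modality, character(1))
  if (is.null(modalities)) modalities <- names(parts)
  missing <- setdiff(modalities, names(parts))
  if (length(missing)) {
    abort(paste0("missing modality: ", paste(missing, collapse = ", ")))
  }
  modalities <- order_modalities(modalities)
  vecs <- list(); lay <- list()
  for (m in modalities) {
    v <- as.vector(t(parts[[m]]$values))
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    vecs[[m]] <- v
    lay[[m]] <- tibble(
      modality = m,
      n_blocks = nrow(parts[[m]]$values),
      dim = ncol(parts[[m]]$values)
    )
  }
  structure(
    list(x = unlist(vecs, use.names = FALSE), layout = dplyr::bind_rows(lay)),
    class = "block_descriptor"
  )
}

order_modalities <- function(modalities) {
  known <- MODALITY_ORDER[MODALITY_ORDER %in% modalities]
  c(known, setdiff(modalities, known))
}

#' Per-block bookkeeping of a layout
#'
#' @param layout A layout tibble (`modality`, `n_blocks`, `dim`).
#' @return A tibble with one row per block: `block`, `modality`, `dim`,
#'   `start`, `end` (column range in the concatenated descriptor).
#' @export
block_table <- function(layout) {
  tb <- tidyr::uncount(layout, .data$n_blocks, .remove = FALSE)
  tb$block <- seq_len(nrow(tb))
  tb$end <- cumsum(tb$dim)
  tb$start <- tb$end - tb$dim + 1L
  dplyr::select(tb, "block", "modality", "dim", "start", "end")
}

layout_total_dim <- function(layout) sum(layout$n_blocks * layout$dim)

layouts_equal <- function(a, b) {
  isTRUE(all.equal(as.data.frame(a), as.data.frame(b), check.attributes = FALSE))
}

#' Collect per-image descriptors into a descriptor set
#'
#' @param descriptors List of `block_descriptor` objects sharing one layout.
#' @return A `descriptor_set`: list with `x` (N x H matrix) and `layout`.
#' @export
descriptor_set <- function(descriptors) {
  stopifnot(length(descriptors) >= 1L)
  layout <- descriptors[[1]]$layout
  for (d in descriptors) {
    if (!layouts_equal(d$layout, layout)) {
      abort("descriptors do not share a single block layout")
    }
  }
  structure(
    list(
      x = do.call(rbind, lapply(descriptors, function(d) d$x)),
      layout = layout
    ),
    class = "descriptor_set"
  )
}

#' @export
print.block_descriptor <- function(x, ...) {
  cat(sprintf(
    "<block_descriptor> H = %d, B = %d blocks (%s)\n",
    length(x$x), sum(x$layout$n_blocks),
    paste(x$layout$modality, collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf(
    "<descriptor_set> %d descriptors, H = %d, B = %d blocks (%s)\n",
    nrow(x$x), ncol(x$x), sum(x$layout$n_blocks),
    paste(x$layout$modality, collapse = ", ")
  ))
  invisible(x)
}

#' Persist / restore a descriptor set as CSV + JSON layout manifest
#'
#' Writes `<prefix>.csv` (one row per descriptor, no row names) and
#' `<prefix>_layout.json` (modality order, block counts, per-block dims).
#'
#' @param set A `descriptor_set`.
#' @param prefix Path prefix for the two files.
#' @return `read_descriptors()` returns the restored `descriptor_set`.
#' @export
write_descriptors <- function(set, prefix) {
  stopifnot(inherits(set, "descriptor_set"))
  utils::write.csv(as.data.frame(set$x), paste0(prefix, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    as.data.frame(set$layout), paste0(prefix, "_layout.json"),
    digits = NA
  )
  invisible(prefix)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(prefix) {
  x <- as.matrix(utils::read.csv(paste0(prefix, ".csv")))
  dimnames(x) <- NULL
  layout <- as_tibble(jsonlite::read_json(
    paste0(prefix, "_layout.json"), simplifyVector = TRUE
  ))
  layout$n_blocks <- as.integer(layout$n_blocks)
  layout$dim <- as.integer(layout$dim)
  structure(list(x = x, layout = layout), class = "descriptor_set")
}

#' Extract the full multi-modal descriptor of one image
#'
#' Runs the per-modality extractors and assembles the block-structured
#' descriptor.  `extract_descriptor_set()` does the same for a list of
#' images and returns a `descriptor_set`; precomputed SIFT sets can be
#' supplied to avoid re-extraction.
#'
#' @param image Numeric intensity matrix.
#' @param codebook Fitted `ifv_codebook` (required when `"IFV"` is among
#'   the modalities).
#' @param modalities Modalities to include.
#' @param sift_bin_widths,sift_step Dense-SIFT geometry.
#' @param sifts Optional precomputed `dense_sift` for the image.
#' @return A `block_descriptor`.
#' @export
extract_descriptor <- function(image, codebook = NULL,
                               modalities = c("IFV", "LBP", "HOG", "CENTRIST", "GIST"),
                               sift_bin_widths = c(2L, 4L, 6L, 8L, 10L),
                               sift_step = 2L, sifts = NULL) {
  parts <- list()
  if ("IFV" %in% modalities) {
    if (is.null(codebook)) abort("IFV requested but no codebook supplied")
    if (is.null(sifts)) {
      sifts <- extract_dense_sift(image, sift_bin_widths, sift_step)
    }
    parts$IFV <- encode_ifv(sifts, codebook)
  }
  if ("LBP" %in% modalities) parts$LBP <- extract_lbp_grid(image)
  if ("HOG" %in% modalities) parts$HOG <- extract_hog_grid(image)
  if ("CENTRIST" %in% modalities) parts$CENTRIST <- extract_centrist(image)
  if ("GIST" %in% modalities) parts$GIST <- extract_gist_grid(image)
  assemble_descriptor(parts, modalities)
}

#' @rdname extract_descriptor
#' @param images List of intensity matrices.
#' @param sift_sets Optional list of precomputed `dense_sift` objects.
#' @export
extract_descriptor_set <- function(images, codebook = NULL,
                                   modalities = c("IFV", "LBP", "HOG", "CENTRIST", "GIST"),
                                   sift_bin_widths = c(2L, 4L, 6L, 8L, 10L),
                                   sift_step = 2L, sift_sets = NULL) {
  descs <- lapply(seq_along(images), function(i) {
    extract_descriptor(
      images[[i]], codebook, modalities, sift_bin_widths, sift_step,
      sifts = if (is.null(sift_sets)) NULL else sift_sets[[i]]
    )
  })
  descriptor_set(descs)
}
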