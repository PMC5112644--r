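#' Load a class-per-directory image dataset
#'
#' Reads every image under `root_path/<class>/`, converting RGB to
#' grayscale with the standard luma weights and linearly rescaling
#' intensities to `[0, 255]` when the native range requires it (16-bit
#' TIFFs and similar).  Class labels are assigned from the subdirectory
#' names sorted lexicographically (`1..L`).  PNG and TIFF are read
#' natively; JPEG requires the EBImage package; BMP is not supported.
#'
#' @param root_path Directory with one subdirectory per class.
#' @return List with `images` (list of intensity matrices), `labels`
#'   (integer), `classes` (character, label `l` = `classes[l]`) and
#'   `files`.
#' @export
load_dataset <- function(root_path) {
  if (!dir.exists(root_path)) abort(sprintf("no such directory: %s", root_path))
  class_dirs <- sort(list.dirs(root_path, recursive = FALSE))
  if (!length(class_dirs)) abort(sprintf("no class subdirectories under %s", root_path))
  images <- list(); labels <- integer(0); files <- character(0)
  for (l in seq_along(class_dirs)) {
    fs <- sort(list.files(class_dirs[l], full.names = TRUE))
    fs <- fs[!dir.exists(fs)]
    if (!length(fs)) {
      abort(sprintf("class directory is empty: %s", class_dirs[l]))
    }
    for (f in fs) {
      img <- tryCatch(read_image(f), error = function(e) {
        abort(sprintf("unreadable image %s: %s", f, conditionMessage(e)))
      })
      images[[length(images) + 1L]] <- img
      labels <- c(labels, l)
      files <- c(files, f)
    }
  }
  list(images = images, labels = labels, classes = basename(class_dirs),
       files = files)
}

#' @rdname load_dataset
#' @param path Path of a single image file.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(
    ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        abort("reading JPEG requires the EBImage package")
      }
      im <- EBImage::readImage(path)
      a <- EBImage::imageData(im)
      # EBImage stores x (columns) in the first dimension
      if (length(dim(a)) == 2L) t(a) * 255 else aperm(a, c(2L, 1L, 3L)) * 255
    },
    bmp = abort("BMP images are not supported; convert to PNG or TIFF"),
    abort(sprintf("unsupported image format: .%s", ext))
  )
  gray <- rgb_to_gray(raw)
  rescale_intensity(gray)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_pipeline_config()` returns the validated
#'   `pipeline_config` (unknown fields are rejected).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipeline_config, obj)
}

#' Write / read an evaluation report (JSON aggregate + CSV folds)
#'
#' `write_eval_report()` writes `<prefix>.json` (mean accuracy, standard
#' error, confusion matrix, split accuracies, configuration echo) and
#' `<prefix>_folds.csv` (one row per split/fold).  The JSON round-trips
#' losslessly through `read_eval_report()`.
#'
#' @param report An `sdt_eval` report.
#' @param prefix Path prefix.
#' @return `read_eval_report()` returns a list with the aggregate fields
#'   and the folds tibble.
#' @export
write_eval_report <- function(report, prefix) {
  stopifnot(inherits(report, "sdt_eval"))
  agg <- list(
    mean_accuracy = report$mean_accuracy,
    std_error = report$std_error,
    split_accuracy = report$splits$accuracy,
    confusion = unname(apply(report$confusion, 1, as.integer, simplify = FALSE)),
    classes = rownames(report$confusion),
    modalities = report$config$modalities,
    transform = report$config$transform,
    n_folds = report$protocol$n_folds,
    n_splits = report$protocol$n_splits,
    seed = report$protocol$seed
  )
  jsonlite::write_json(agg, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE)
  utils::write.csv(as.data.frame(report$folds), paste0(prefix, "_folds.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(prefix) {
  agg <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  # rows were written as a list of integer vectors
  if (!is.matrix(agg$confusion)) {
    agg$confusion <- do.call(rbind, agg$confusion)
  }
  dimnames(agg$confusion) <- list(true = agg$classes, predicted = agg$classes)
  agg$folds <- as_tibble(utils::read.csv(paste0(prefix, "_folds.csv")))
  agg
}
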