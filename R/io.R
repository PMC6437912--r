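# Readers and writers: RGB images as PNG/TIFF, label rasters as 16-bit
# TIFF (8-bit PNG accepted for <= 255 labels), models as versioned RDS
# files, configs as YAML, manifests and metrics as JSON.

ext_of <- function(path) tolower(tools::file_ext(path))

#' Read an RGB image (PNG or TIFF)
#'
#' @param path file path; `.png`, `.tif`/`.tiff`.
#' @return H x W x 3 array in `[0, 1]` (alpha dropped, grayscale replicated).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  x <- switch(ext_of(path),
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", path, call. = FALSE))
  if (is.matrix(x)) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  x
}

#' Write an RGB image
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path output path (`.png` or `.tif`/`.tiff`).
#' @export
write_image <- function(image, path) {
  assert_rgb(image)
  image <- clamp(image, 0, 1)
  switch(ext_of(path),
         png = png::writePNG(image, path),
         tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 8),
         stop("unsupported image format: ", path, call. = FALSE))
  invisible(path)
}

#' Read an integer label raster
#'
#' @param path `.tif`/`.tiff` (16-bit) or `.png` (8-bit) file.
#' @return integer matrix; 0 is boundary/background.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  x <- switch(ext_of(path),
              png = round(png::readPNG(path) * 255),
              tif = , tiff = round(tiff::readTIFF(path) * 65535),
              stop("unsupported label format: ", path, call. = FALSE))
  if (!is.matrix(x)) x <- x[, , 1]
  storage.mode(x) <- "integer"
  x
}

#' Write an integer label raster
#'
#' Labels are stored losslessly: 16 bits per sample for TIFF (up to 65535
#' cells), 8 for PNG (up to 255).
#'
#' @param labels integer matrix, 0 reserved for boundary/background.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(is.matrix(labels))
  mx <- max(labels)
  switch(ext_of(path),
         png = {
           if (mx > 255) stop("more than 255 labels: use a 16-bit TIFF",
                              call. = FALSE)
           png::writePNG(labels / 255, path)
         },
         tif = , tiff = {
           if (mx > 65535) stop("more than 65535 labels cannot be stored in ",
                                "16 bits per sample", call. = FALSE)
           tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
         },
         stop("unsupported label format: ", path, call. = FALSE))
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a model file
#'
#' Models (contour forest, region scorer, or the combined pipeline bundle)
#' are written as a single versioned file; loading refuses mismatched
#' format versions.
#'
#' @param model object of class `forest_model`, `region_scorer` or
#'   `muscleseg_models`.
#' @param path file path.
#' @return `load_model` returns the model object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("forest_model", "region_scorer",
                              "muscleseg_models")))
  saveRDS(list(format_version = MODEL_FORMAT_VERSION,
               class = class(model)[1], model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  x <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt model file: ", path, call. = FALSE))
  if (!is.list(x) || is.null(x$format_version) ||
      x$format_version != MODEL_FORMAT_VERSION)
    stop("model file ", path, " has an unsupported format version",
         call. = FALSE)
  x$model
}

#' Write / read a pipeline configuration file
#'
#' Round-trips a [pipeline_config()] through YAML losslessly.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Write / read a synthetic-image specification file
#'
#' Round-trips a [synthetic_spec()] through YAML losslessly.
#'
#' @param spec a `synthetic_spec`.
#' @param path YAML file path.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  do.call(synthetic_spec, yaml::read_yaml(path))
}

#' Run manifest
#'
#' JSON summary embedding the resolved configuration, model file hashes and
#' per-cell results of a segmentation run.
#'
#' @param result output of [segment_cells()] or [run_parallel()].
#' @param config the resolved `pipeline_config`.
#' @param path output JSON path.
#' @param model_paths optional named character vector of model files to
#'   fingerprint (md5).
#' @export
write_manifest <- function(result, config, path, model_paths = NULL) {
  hashes <- if (!is.null(model_paths))
    as.list(vapply(model_paths, function(p) unname(tools::md5sum(p)), ""))
  m <- list(n_cells = nrow(result$cells),
            cells = result$cells,
            config = unclass(config),
            model_md5 = hashes)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
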