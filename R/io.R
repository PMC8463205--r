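#' Write a grayscale image to disk
#'
#' Supported formats: PNG and TIFF (8- or 16-bit grayscale, chosen by
#' `bits`) and a plain-text array format (`.txt`, whitespace-separated
#' rows) with a JSON sidecar (`<file>.json`) recording provenance such
#' as the generating [phantom_spec()].  Intensities are assumed to lie
#' in `[0, 1]`; PNG/TIFF writing quantizes accordingly.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param path Output path; format inferred from the extension
#'   (`.png`, `.tif`/`.tiff`, anything else is written as plain text).
#' @param bits Bit depth for PNG/TIFF quantization (8 or 16).
#' @param meta Optional list serialized to a JSON sidecar next to the
#'   image (always written for the text format, on request otherwise).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L, meta = NULL) {
  stopifnot(is.matrix(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(img, 0), 1), target = path,
                  dpi = NULL, asp = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pmin(pmax(img, 0), 1), where = path,
                    bits.per.sample = as.integer(bits))
  } else {
    utils::write.table(format(img, digits = 17), file = path,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    if (is.null(meta)) meta <- list()
    meta$dim <- dim(img)
  }
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grayscale image written by [write_image()]
#'
#' PNG/TIFF images are returned as numeric matrices in `[0, 1]`
#' (multi-channel files are averaged to grayscale); plain-text arrays
#' are read back exactly.
#'
#' @param path Image path.
#' @return A numeric matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
  } else {
    return(as.matrix(utils::read.table(path, header = FALSE)))
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  unname(img)
}

#' Save a model checkpoint
#'
#' Serializes an [srcnn_model()] (layer weights, biases, activation
#' flags) together with arbitrary metadata to a single JSON file.
#' JSON keeps the checkpoint plain-text and portable; array dimensions
#' are stored alongside the flattened values.
#'
#' @param model An `srcnn_model`.
#' @param path Output path (`.json`).
#' @param meta Optional named list of metadata (seed, training config).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, meta = NULL) {
  stopifnot(inherits(model, "srcnn_model"))
  payload <- list(
    meta = meta,
    layers = lapply(model$layers, function(l) list(
      dim = dim(l$weights),
      weights = as.numeric(l$weights),
      bias = as.numeric(l$bias),
      apply_relu = l$apply_relu)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return An `srcnn_model`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(nrow_or_len(payload$layers)), function(i) {
    l <- if (is.data.frame(payload$layers)) lapply(payload$layers, `[[`, i)
         else payload$layers[[i]]
    conv_layer(array(as.numeric(unlist(l$weights)),
                     dim = as.integer(unlist(l$dim))),
               bias = as.numeric(unlist(l$bias)),
               apply_relu = isTRUE(as.logical(l$apply_relu)))
  })
  srcnn_model(layers)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
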