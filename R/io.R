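#' Write an image to PNG (8-bit) or TIFF (32-bit float)
#'
#' Integer 3-channel arrays in 0..255 are written as 8-bit PNG; numeric
#' matrices are written as 32-bit float TIFF. Float TIFF storage holds
#' values in `[0, 1]`, so maps with a wider dynamic range (e.g. reduced
#' scattering in mm^-1) are normalized by `range` before writing; the range
#' and any extra metadata are recorded in a JSON sidecar (`<path>.json`) and
#' restored by [read_image()].
#'
#' @param x Matrix (grayscale) or H x W x 3 array (RGB label).
#' @param path Destination file; extension selects the format (`.png` /
#'   `.tif`/`.tiff`).
#' @param range Optional `c(lo, hi)` normalization range for float TIFF.
#' @param metadata Optional named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, range = NULL, metadata = list()) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (length(dim(x)) == 3) x <- x / 255
    png::writePNG(x, path)
  } else if (ext %in% c("tif", "tiff")) {
    meta <- metadata
    if (!is.null(range)) {
      x <- (x - range[1]) / (range[2] - range[1])
      meta$range <- range
    }
    if (any(x < 0 | x > 1, na.rm = TRUE)) {
      stop("float TIFF values must lie in [0, 1]; pass a `range`")
    }
    x[is.na(x)] <- 0
    tiff::writeTIFF(x, path, bits.per.sample = 32)
    if (length(meta)) {
      jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                           digits = NA)
    }
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' @rdname write_image
#' @param as_label For PNG, return integer 0..255 values (the label
#'   convention) instead of [0, 1] doubles.
#' @return `read_image()`: the image with any sidecar range applied and
#'   remaining sidecar fields attached as the `metadata` attribute.
#' @export
read_image <- function(path, as_label = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
    if (as_label) x <- array(as.integer(round(x * 255)), dim(x))
    return(x)
  }
  if (!ext %in% c("tif", "tiff")) stop("unsupported image format: .", ext)
  x <- tiff::readTIFF(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$range)) {
      r <- as.numeric(meta$range)
      x <- x * (r[2] - r[1]) + r[1]
      meta$range <- NULL
    }
    if (length(meta)) attr(x, "metadata") <- meta
  }
  x
}

#' Read a dataset manifest written by [build_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return The manifest list.
#' @export
read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"),
                      simplifyVector = FALSE)
}
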