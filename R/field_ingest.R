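#' Construct a standardized field image
#'
#' A field image is a 680x680 grid of 8-bit intensities with a physical
#' scale. Fields nominally cover 500x500 um of tissue; at the fixed working
#' resolution of 0.735 um/px the 680-px grid spans 499.8 um, which is
#' treated as exact.
#'
#' @param pixels numeric matrix of intensities in \[0, 255\] (rows = y,
#'   columns = x, origin top-left)
#' @param scale_um_per_px physical pixel size in micrometres (default 0.735)
#' @param source_id provenance string (file name, sampling coordinates, ...)
#' @return an object of class `field_image` with elements `pixels`,
#'   `scale_um_per_px` and `source_id`
#' @export
field_image <- function(pixels, scale_um_per_px = 0.735, source_id = "field") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop_lungmorph("field pixels must be finite numerics", "lungmorph_ingest_error")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_lungmorph("field intensities must lie in [0, 255]", "lungmorph_ingest_error")
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1L ||
      scale_um_per_px <= 0)
    stop_lungmorph("scale_um_per_px must be a positive number", "lungmorph_ingest_error")
  structure(list(pixels = pixels, scale_um_per_px = scale_um_per_px,
                 source_id = as.character(source_id)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %dx%d px @ %.3f um/px  [%s]\n",
              nrow(x$pixels), ncol(x$pixels), x$scale_um_per_px, x$source_id))
  cat(sprintf("  intensity range: %d-%d\n",
              as.integer(min(x$pixels)), as.integer(max(x$pixels))))
  invisible(x)
}

#' Field standardization size (pixels)
#' @keywords internal
FIELD_PX <- 680L

#' Default physical scale (um per pixel)
#' @keywords internal
DEFAULT_SCALE <- 0.735

#' Load a raster field and standardize it
#'
#' Reads a PNG field (grayscale or RGB), converts RGB to 8-bit gray by the
#' unweighted channel mean, and resizes to 680x680 px by bilinear
#' interpolation, after which the scale is the fixed working resolution.
#' Thresholding is always applied after this standardization.
#'
#' @param path path to a PNG raster
#' @param scale physical scale assigned to the standardized field
#'   (um/px, default 0.735)
#' @return a [field_image()]
#' @export
load_field <- function(path, scale = DEFAULT_SCALE) {
  if (!file.exists(path))
    stop_lungmorph(sprintf("cannot read field image '%s'", path),
                   "lungmorph_ingest_error")
  px <- tryCatch(png::readPNG(path), error = function(e)
    stop_lungmorph(sprintf("cannot read field image '%s': %s", path,
                           conditionMessage(e)), "lungmorph_ingest_error"))
  standardize_field(px, scale = scale, source_id = basename(path))
}

# px: array from png::readPNG (values in [0,1]) or a 0-255 matrix
standardize_field <- function(px, scale = DEFAULT_SCALE, source_id = "field") {
  if (is.matrix(px)) {
    gray <- px
  } else if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    # drop alpha; unweighted mean over colour channels
    ch <- min(nch, 3L)
    gray <- apply(px[, , seq_len(ch), drop = FALSE], c(1, 2), mean)
  } else {
    stop_lungmorph("unsupported raster layout", "lungmorph_ingest_error")
  }
  if (length(gray) == 0L)
    stop_lungmorph("zero-sized image", "lungmorph_ingest_error")
  if (max(gray) <= 1 + 1e-9) gray <- gray * 255
  if (nrow(gray) != FIELD_PX || ncol(gray) != FIELD_PX) {
    rz <- EBImage::resize(EBImage::Image(gray / 255),
                          w = FIELD_PX, h = FIELD_PX, filter = "bilinear")
    gray <- pmin(pmax(EBImage::imageData(rz), 0), 1) * 255
  }
  field_image(round(gray), scale_um_per_px = scale, source_id = source_id)
}

#' Suggest a tissue/air threshold by Otsu's method
#'
#' The batch contract is one threshold per batch, set on the first image;
#' this provides a non-interactive starting value which the user may
#' override in the batch configuration.
#'
#' @param img a [field_image()]
#' @return integer threshold in \[0, 255\]; a constant image returns 0 with
#'   a warning
#' @export
suggest_threshold <- function(img) {
  stopifnot(inherits(img, "field_image"))
  px <- img$pixels
  if (diff(range(px)) == 0) {
    warning("constant image: no tissue/air separation, returning 0")
    return(0L)
  }
  t01 <- EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1), levels = 256)
  as.integer(round(t01 * 255))
}

#' Apply an intensity threshold to a field
#'
#' Tissue is darker than air on H&E sections, so tissue = intensity <= t.
#'
#' @param img a [field_image()]
#' @param t intensity threshold in \[0, 255\]
#' @return a raw-stage [binary_mask()]
#' @export
apply_threshold <- function(img, t) {
  stopifnot(inherits(img, "field_image"))
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 255)
    stop_lungmorph("threshold must lie in [0, 255]", "lungmorph_ingest_error")
  binary_mask(img$pixels <= t, stage = "raw")
}

#' Construct a binary tissue mask
#'
#' Masks move through the fixed stages raw -> exudate_filtered -> clean;
#' each segmentation step checks and advances the stage.
#'
#' @param tissue logical matrix, TRUE = septal tissue
#' @param stage one of "raw", "exudate_filtered", "clean"
#' @return an object of class `binary_mask`
#' @export
binary_mask <- function(tissue, stage = c("raw", "exudate_filtered", "clean")) {
  stage <- match.arg(stage)
  tissue <- as.matrix(tissue)
  storage.mode(tissue) <- "logical"
  if (any(is.na(tissue)))
    stop_lungmorph("mask contains NA", "lungmorph_ingest_error")
  structure(list(tissue = tissue, stage = stage), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %dx%d, stage '%s', tissue fraction %.3f\n",
              nrow(x$tissue), ncol(x$tissue), x$stage, mean(x$tissue)))
  invisible(x)
}
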