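#' B-scan image with physical scaling
#'
#' Container for a single greyscale OCT B-scan. Pixel intensities are stored
#' normalised to \[0, 1\] on a common scale (divided by the container dtype
#' maximum, 255 or 65535), so intensity statistics are comparable across
#' scans. Physical scaling is carried per image because scan geometry varies
#' slightly between acquisitions.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\]; rows are the
#'   vertical (Y) axis, columns the horizontal (X) axis.
#' @param image_id Identifier string.
#' @param scale_x_um,scale_y_um Microns per pixel along X (columns) and Y
#'   (rows); both must be positive.
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, image_id, scale_x_um = 10.5, scale_y_um = 3.8) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("pixels must be a numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stopf("pixel intensities must lie in [0, 1] with no NA")
  if (scale_x_um <= 0 || scale_y_um <= 0)
    stopf("pixel scaling must be positive")
  structure(
    list(image_id = as.character(image_id), pixels = pixels,
         scale_x_um = scale_x_um, scale_y_um = scale_y_um),
    class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan '%s'> %d x %d px, %.3g x %.3g um/px, intensity [%.3f, %.3f]\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels),
              x$scale_x_um, x$scale_y_um, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary annotation mask tagged with its provenance
#'
#' @param mask Logical matrix; `TRUE` marks annotated (foreground) pixels.
#' @param image_id Identifier of the B-scan the mask belongs to.
#' @param rater_id Non-empty rater identifier.
#' @param round_id Annotation round, 1 or 2.
#' @return An object of class `annotation_mask`.
#' @export
annotation_mask <- function(mask, image_id, rater_id, round_id = 1L) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  if (!is.logical(mask)) {
    if (!is.numeric(mask)) stopf("mask must be logical or numeric")
    mask <- mask != 0
  }
  if (!nzchar(rater_id)) stopf("rater_id must be non-empty")
  round_id <- as.integer(round_id)
  if (!round_id %in% c(1L, 2L)) stopf("round_id must be 1 or 2")
  structure(
    list(image_id = as.character(image_id), rater_id = as.character(rater_id),
         round_id = round_id, mask = mask),
    class = "annotation_mask")
}

#' @export
print.annotation_mask <- function(x, ...) {
  cat(sprintf("<annotation_mask '%s' / '%s' / round %d> %d x %d px, %d foreground\n",
              x$image_id, x$rater_id, x$round_id,
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# Decode a PNG/TIFF raster to a greyscale matrix in [0,1].
# Multi-channel images are accepted only when all colour channels are equal
# (an alpha channel, if present, is ignored).
read_grey_raster <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stopf("unsupported raster format '%s' (expected png/tif/tiff): %s", ext, path))
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    ch <- if (nch >= 3) 3L else nch  # drop alpha (channel 4)
    for (k in seq_len(ch - 1L)) {
      if (max(abs(arr[, , k] - arr[, , k + 1L])) > 0)
        stopf("multi-channel raster with unequal channels is not greyscale: %s", path)
    }
    arr <- arr[, , 1L]
  }
  if (length(dim(arr)) != 2) stopf("raster is not 2-D: %s", path)
  arr
}

#' Read a greyscale B-scan from PNG or TIFF
#'
#' Intensities are rescaled linearly from the container's dtype range to
#' \[0, 1\] (8-bit value 255 and 16-bit value 65535 both map to 1), giving a
#' common intensity scale across images.
#'
#' @param path Path to an 8- or 16-bit greyscale PNG/TIFF.
#' @param scale_x_um,scale_y_um Physical scaling in microns per pixel.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A [bscan].
#' @export
read_image <- function(path, scale_x_um = 10.5, scale_y_um = 3.8,
                       image_id = tools::file_path_sans_ext(basename(path))) {
  bscan(read_grey_raster(path), image_id = image_id,
        scale_x_um = scale_x_um, scale_y_um = scale_y_um)
}

#' Read a binary annotation mask aligned to an image
#'
#' Tolerant read: any nonzero pixel is foreground. The raster must have
#' exactly the shape of the reference image; a mismatch signals mis-paired
#' files and is an error.
#'
#' @param path Path to a single-channel PNG/TIFF mask.
#' @param image The [bscan] the mask annotates.
#' @param rater_id,round_id Provenance tags for the mask.
#' @return An [annotation_mask].
#' @export
read_mask <- function(path, image, rater_id, round_id = 1L) {
  arr <- read_grey_raster(path)
  if (!identical(dim(arr), dim(image$pixels)))
    stopf("mask %s (%d x %d) is not aligned to image '%s' (%d x %d)",
          path, nrow(arr), ncol(arr), image$image_id,
          nrow(image$pixels), ncol(image$pixels))
  annotation_mask(arr != 0, image_id = image$image_id,
                  rater_id = rater_id, round_id = round_id)
}

#' Write a B-scan or mask to PNG
#'
#' Masks are written strictly as 0 (background) / 255 (foreground) 8-bit
#' PNG; images as 16-bit greyscale PNG.
#'
#' @param x A [bscan] or [annotation_mask].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_png <- function(x, path) {
  if (inherits(x, "annotation_mask")) {
    png::writePNG(x$mask * 1.0, target = path)  # 8-bit 0/255
  } else if (inherits(x, "bscan")) {
    png::writePNG(x$pixels, target = path, dpi = NULL)
  } else stopf("x must be a bscan or annotation_mask")
  invisible(path)
}

#' Write a results table as CSV with deterministic formatting
#'
#' Numeric columns are rendered with 6 significant digits so that repeated
#' runs on identical inputs produce byte-identical files.
#'
#' @param rows A data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.6g", out[[j]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
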