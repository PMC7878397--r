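#' Grayscale gel/blot image
#'
#' Container for a single-channel densitometry image. Pixel values are kept
#' on the native integer scale of the scanner (0 to `2^bit_depth - 1`);
#' `orientation` records whether lanes run down the rows (`"vertical"`, the
#' usual ChemiDoc layout: migration axis = rows, lane width = columns) or
#' across the columns (`"horizontal"`).
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param bit_depth 8 or 16; pixel values must not exceed `2^bit_depth - 1`.
#' @param orientation `"vertical"` (default) or `"horizontal"`.
#' @return An object of class `gel_image`.
#' @seealso [read_gel_image()], [extract_profile()], [make_synthetic_gel()]
#' @export
gel_image <- function(pixels, bit_depth = 16, orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    af_validation_error("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    af_validation_error("image must have at least one row and one column")
  if (!bit_depth %in% c(8, 16))
    af_validation_error("'bit_depth' must be 8 or 16, got %s", format(bit_depth))
  if (anyNA(pixels) || any(pixels < 0))
    af_validation_error("pixel intensities must be non-negative and non-missing")
  if (any(pixels > 2^bit_depth - 1))
    af_validation_error("pixel intensities exceed the %d-bit dynamic range", bit_depth)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 orientation = orientation),
            class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image> %d x %d px, %d-bit, lanes %s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$orientation))
  cat(sprintf("  intensity range: [%s, %s]\n",
              fmt_num(min(x$pixels)), fmt_num(max(x$pixels))))
  invisible(x)
}

#' Read a grayscale gel image from TIFF or PNG
#'
#' Multi-channel images are averaged to a single gray channel. Readers that
#' return intensities on a 0--1 scale are rescaled to the integer range
#' implied by `bit_depth`.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param bit_depth dynamic range of the scan (default 16).
#' @inheritParams gel_image
#' @return A [gel_image()].
#' @export
read_gel_image <- function(path, bit_depth = 16,
                           orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) af_validation_error("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    af_validation_error("unsupported image format '.%s' (use TIFF or PNG)", ext))
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)  # collapse channels
  if (max(px) <= 1) px <- px * (2^bit_depth - 1)
  gel_image(px, bit_depth = bit_depth, orientation = orientation)
}

#' Rectangular lane region of interest
#'
#' Coordinates are 1-based inclusive row/column ranges, matrix-style.
#'
#' @param lane_id lane identifier (character or coercible).
#' @param rows,cols length-2 integer vectors `c(first, last)`.
#' @return An object of class `lane_roi`.
#' @export
lane_roi <- function(lane_id, rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 2L || length(cols) != 2L || anyNA(rows) || anyNA(cols))
    af_validation_error("'rows' and 'cols' must be length-2 integer ranges")
  if (rows[1] > rows[2] || cols[1] > cols[2])
    af_validation_error("ROI ranges must satisfy first <= last")
  structure(list(lane_id = as.character(lane_id), rows = rows, cols = cols),
            class = "lane_roi")
}
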