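#' Generate a synthetic blot image with known band areas
#'
#' Builds a grayscale gel image from a band layout, for validating the
#' densitometry round trip against exact ground truth. Each band is a
#' Gaussian intensity profile along the migration axis, spread uniformly
#' across its lane's width, scaled so that the band's total added pixel
#' intensity equals `intensity` exactly. A smooth background and i.i.d.
#' Gaussian pixel noise can be layered on top; the returned ground truth
#' records the noiseless per-band totals.
#'
#' Bands within a lane must be separated by at least three times the sum
#' of their standard deviations (6 sigma for equal widths); closer layouts
#' are refused because their ground-truth areas would be ambiguous.
#'
#' @param bands data frame with columns `lane_id`, `band_label`, `center`
#'   (row position of the band peak), `sigma` (band half-width, px) and
#'   `intensity` (total band intensity, au).
#' @param dims image size `c(rows, cols)`.
#' @param lanes optional data frame `lane_id`, `col_start`, `col_end`;
#'   by default lanes are laid out as equal-width column blocks in the
#'   order they first appear in `bands`.
#' @param background `"none"`, `"ramp"` (linear 0 to `background_height`
#'   along the migration axis) or `"smooth"` (low-frequency sinusoid of
#'   amplitude `background_height`), added to every pixel.
#' @param background_height peak background level per pixel (au).
#' @param noise_sd standard deviation of additive Gaussian pixel noise;
#'   noisy pixels are clamped to the dynamic range.
#' @param bit_depth image bit depth (default 16).
#' @param seed optional integer; fixed seed gives a bit-identical image.
#' @return An object of class `synthetic_gel`: list with `image` (a
#'   [gel_image()]), `truth` (data frame `lane_id`, `band_label`, `area`),
#'   `lanes` (the lane layout) and `bands` (the input layout).
#' @export
make_synthetic_gel <- function(bands, dims = c(120, 80), lanes = NULL,
                               background = c("none", "ramp", "smooth"),
                               background_height = 0, noise_sd = 0,
                               bit_depth = 16, seed = NULL) {
  background <- match.arg(background)
  req <- c("lane_id", "band_label", "center", "sigma", "intensity")
  if (!is.data.frame(bands) || !all(req %in% names(bands)))
    af_validation_error("'bands' needs columns %s", paste(req, collapse = ", "))
  if (noise_sd < 0) af_validation_error("'noise_sd' must be >= 0")
  if (any(bands$sigma <= 0) || any(bands$intensity < 0))
    af_validation_error("band 'sigma' must be > 0 and 'intensity' >= 0")
  n_row <- as.integer(dims[1]); n_col <- as.integer(dims[2])
  if (any(bands$center < 1 | bands$center > n_row))
    af_validation_error("band centers must lie inside the image rows [1, %d]", n_row)

  lane_ids <- unique(as.character(bands$lane_id))
  if (is.null(lanes)) {
    w <- n_col %/% length(lane_ids)
    if (w < 1L) af_validation_error("image too narrow for %d lanes", length(lane_ids))
    lanes <- data.frame(lane_id = lane_ids,
                        col_start = (seq_along(lane_ids) - 1L) * w + 1L,
                        col_end = seq_along(lane_ids) * w,
                        stringsAsFactors = FALSE)
  }
  if (!all(lane_ids %in% lanes$lane_id))
    af_validation_error("lane layout missing lanes: %s",
                        paste(setdiff(lane_ids, lanes$lane_id), collapse = ", "))

  # refuse ambiguous layouts: per-lane centers closer than 3*(sigma_i+sigma_j)
  for (id in lane_ids) {
    b <- bands[bands$lane_id == id, , drop = FALSE]
    b <- b[order(b$center), , drop = FALSE]
    if (nrow(b) > 1L) {
      gap <- diff(b$center)
      lim <- 3 * (b$sigma[-nrow(b)] + b$sigma[-1])
      if (any(gap < lim))
        af_config_error("bands in lane '%s' overlap (need center separation >= 3*(sigma_i+sigma_j))", id)
    }
  }

  px <- matrix(0, n_row, n_col)
  rows <- seq_len(n_row)
  for (i in seq_len(nrow(bands))) {
    lane <- lanes[lanes$lane_id == as.character(bands$lane_id[i]), ]
    cols <- lane$col_start:lane$col_end
    g <- stats::dnorm(rows, mean = bands$center[i], sd = bands$sigma[i])
    g <- g / sum(g) * bands$intensity[i] / length(cols)  # exact total per band
    px[, cols] <- px[, cols] + g
  }
  bg <- switch(background,
    none = 0,
    ramp = background_height * (rows - 1) / max(1L, n_row - 1L),
    smooth = background_height * 0.5 * (1 + sin(2 * pi * rows / n_row)))
  px <- px + bg
  if (noise_sd > 0)
    px <- px + with_seed(seed, matrix(stats::rnorm(n_row * n_col, 0, noise_sd),
                                      n_row, n_col))
  px <- pmin(pmax(px, 0), 2^bit_depth - 1)

  truth <- data.frame(lane_id = as.character(bands$lane_id),
                      band_label = as.character(bands$band_label),
                      center = bands$center, sigma = bands$sigma,
                      area = bands$intensity, stringsAsFactors = FALSE)
  structure(list(image = gel_image(px, bit_depth = bit_depth),
                 truth = truth, lanes = lanes, bands = bands),
            class = "synthetic_gel")
}

#' @export
print.synthetic_gel <- function(x, ...) {
  cat(sprintf("<synthetic_gel> %d x %d px, %d lane(s), %d band(s), total intensity %s au\n",
              nrow(x$image$pixels), ncol(x$image$pixels),
              nrow(x$lanes), nrow(x$truth), fmt_num(sum(x$truth$area))))
  invisible(x)
}
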