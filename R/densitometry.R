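# Lane-profile densitometry: profile extraction, baseline estimation and
# band (peak) integration, mirroring the lane-profile workflow of
# interactive gel analyzers but with reproducible, scripted inputs.

#' Extract a lane intensity profile
#'
#' Sums pixel intensities across the lane width at every position along the
#' migration axis within a rectangular ROI. The returned profile carries the
#' per-position maximum pixel value so downstream integration can flag
#' saturated bands.
#'
#' @param image a [gel_image()].
#' @param roi a [lane_roi()], fully inside the image. For `"vertical"`
#'   orientation the migration axis is the ROI's row range and the lane
#'   width its column range (and vice versa for `"horizontal"`).
#' @return An object of class `lane_profile` with fields `lane_id`,
#'   `positions` (image coordinates along the migration axis), `intensity`
#'   (summed across the lane width), `baseline` (zeros until
#'   [subtract_baseline()] is applied), `peak_max`, and `bit_depth`.
#' @export
extract_profile <- function(image, roi) {
  stopifnot(inherits(image, "gel_image"), inherits(roi, "lane_roi"))
  px <- image$pixels
  if (roi$rows[1] < 1L || roi$rows[2] > nrow(px) ||
      roi$cols[1] < 1L || roi$cols[2] > ncol(px))
    af_bounds_error("ROI '%s' [rows %d..%d, cols %d..%d] lies outside the %d x %d image",
                    roi$lane_id, roi$rows[1], roi$rows[2], roi$cols[1], roi$cols[2],
                    nrow(px), ncol(px))
  sub <- px[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2], drop = FALSE]
  if (length(sub) == 0L)
    af_degenerate_error("ROI '%s' is empty", roi$lane_id)
  if (image$orientation == "horizontal") sub <- t(sub)
  positions <- if (image$orientation == "vertical")
    roi$rows[1]:roi$rows[2] else roi$cols[1]:roi$cols[2]
  structure(list(lane_id = roi$lane_id,
                 positions = positions,
                 intensity = rowSums(sub),
                 baseline  = numeric(nrow(sub)),
                 peak_max  = apply(sub, 1L, max),
                 bit_depth = image$bit_depth),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile> lane '%s', %d positions [%d..%d], total intensity %s\n",
              x$lane_id, length(x$positions), min(x$positions), max(x$positions),
              fmt_num(sum(x$intensity))))
  invisible(x)
}

#' Estimate and attach a profile baseline
#'
#' Two automatic baseline rules replace the manual baseline of interactive
#' gel analyzers. `"rolling-ball"` is a grayscale morphological opening of
#' the profile with a flat structuring element of radius `window` pixels
#' (erosion then dilation); it tracks slowly varying background while
#' passing under peaks narrower than about twice the radius. The radius
#' should be at least ~4 standard deviations of the widest band.
#' `"straight-line"` linearly interpolates through the profile's local
#' minima (plus the two endpoints), i.e. it connects the valleys flanking
#' each peak.
#'
#' The intensity vector is left untouched; only `baseline` is filled in.
#' Negative net signal is not clamped here but at integration time.
#'
#' @param profile a `lane_profile` from [extract_profile()].
#' @param method `"rolling-ball"` (default) or `"straight-line"`.
#' @param window rolling-ball radius in pixels (default 50); must be
#'   between 1 and the profile length.
#' @return The profile with its `baseline` field populated.
#' @export
subtract_baseline <- function(profile, method = c("rolling-ball", "straight-line"),
                              window = 50) {
  stopifnot(inherits(profile, "lane_profile"))
  if (length(method) == 1L && !method %in% c("rolling-ball", "straight-line"))
    af_config_error("unknown baseline method '%s' (use 'rolling-ball' or 'straight-line')",
                    method)
  method <- match.arg(method)
  x <- profile$intensity
  n <- length(x)
  if (method == "rolling-ball") {
    window <- as.integer(window)
    if (is.na(window) || window < 1L || window > n)
      af_config_error("'window' must be a positive integer <= profile length (%d)", n)
    profile$baseline <- run_max(run_min(x, window), window)
  } else {
    # local minima (<= both neighbours) plus endpoints as interpolation knots
    left  <- c(Inf, x[-n])
    right <- c(x[-1], Inf)
    knots <- sort(unique(c(1L, which(x <= left & x <= right), n)))
    profile$baseline <- if (length(knots) == 1L) rep(x[knots], n)
      else stats::approx(knots, x[knots], xout = seq_len(n), rule = 2)$y
  }
  profile
}

#' Integrate band areas from a baselined profile
#'
#' For each requested band interval, sums the baseline-subtracted signal,
#' clamping negative net values to zero position-wise (band areas are
#' physical quantities). Intervals are 1-based inclusive `[start, end]`
#' ranges on the same coordinate axis as `profile$positions`. A band is
#' flagged saturated when any pixel inside its interval reaches 98% of the
#' image's dynamic range, where chemiluminescent detection is no longer
#' linear.
#'
#' @param profile a `lane_profile` whose baseline has been estimated (a
#'   zero baseline from [extract_profile()] is accepted and means "no
#'   background correction").
#' @param intervals data frame with columns `band_label`, `start`, `end`.
#'   At most one interval per label; same-label overlaps are rejected.
#' @return Data frame with columns `lane_id`, `band_label`, `start`, `end`,
#'   `area` (au) and `saturated`.
#' @export
integrate_bands <- function(profile, intervals) {
  stopifnot(inherits(profile, "lane_profile"))
  req <- c("band_label", "start", "end")
  if (!is.data.frame(intervals) || !all(req %in% names(intervals)))
    af_validation_error("'intervals' needs columns band_label, start, end")
  if (nrow(intervals) == 0L)
    af_validation_error("no band intervals supplied for lane '%s'", profile$lane_id)
  if (anyDuplicated(intervals$band_label))
    af_validation_error("duplicate band label(s) for lane '%s': %s", profile$lane_id,
                        paste(unique(intervals$band_label[duplicated(intervals$band_label)]),
                              collapse = ", "))
  pos <- profile$positions
  net <- pmax(profile$intensity - profile$baseline, 0)
  sat_level <- 0.98 * (2^profile$bit_depth - 1)
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (is.na(s) || is.na(e) || s > e)
      af_validation_error("band '%s' in lane '%s': interval start must be <= end",
                          intervals$band_label[i], profile$lane_id)
    if (s < min(pos) || e > max(pos))
      af_bounds_error("band '%s' interval [%s, %s] outside lane '%s' profile [%d, %d]",
                      intervals$band_label[i], format(s), format(e), profile$lane_id,
                      min(pos), max(pos))
    sel <- pos >= s & pos <= e
    data.frame(lane_id = profile$lane_id,
               band_label = as.character(intervals$band_label[i]),
               start = s, end = e,
               area = sum(net[sel]),
               saturated = any(profile$peak_max[sel] >= sat_level),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Quantify a whole blot image
#'
#' Convenience wrapper running [extract_profile()], [subtract_baseline()]
#' and [integrate_bands()] for every lane, producing the band table
#' consumed by the flux model (after [assemble_lanes()]).
#'
#' @param image a [gel_image()].
#' @param rois data frame with columns `lane_id`, `row_start`, `row_end`,
#'   `col_start`, `col_end` (1-based inclusive), or a list of [lane_roi()].
#' @param bands data frame with columns `lane_id`, `band_label`, `start`,
#'   `end` giving the integration interval of each band along the
#'   migration axis.
#' @inheritParams subtract_baseline
#' @return Data frame of band calls, one row per (lane, band).
#' @export
quantify_gel <- function(image, rois, bands,
                         method = c("rolling-ball", "straight-line"), window = 50) {
  if (is.data.frame(rois)) {
    req <- c("lane_id", "row_start", "row_end", "col_start", "col_end")
    if (!all(req %in% names(rois)))
      af_validation_error("'rois' needs columns %s", paste(req, collapse = ", "))
    rois <- lapply(seq_len(nrow(rois)), function(i)
      lane_roi(rois$lane_id[i], c(rois$row_start[i], rois$row_end[i]),
               c(rois$col_start[i], rois$col_end[i])))
  }
  req <- c("lane_id", "band_label", "start", "end")
  if (!is.data.frame(bands) || !all(req %in% names(bands)))
    af_validation_error("'bands' needs columns %s", paste(req, collapse = ", "))
  res <- lapply(rois, function(roi) {
    prof <- subtract_baseline(extract_profile(image, roi), method = method,
                              window = window)
    iv <- bands[bands$lane_id == roi$lane_id, c("band_label", "start", "end"),
                drop = FALSE]
    if (nrow(iv) == 0L)
      af_validation_error("no band intervals supplied for lane '%s'", roi$lane_id)
    integrate_bands(prof, iv)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
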