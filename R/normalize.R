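# Lane validation and normalization into a replicate-matched flux design.

# canonical internal lane columns; *_au aliases from the CSV schema are
# mapped here so quantified, simulated and hand-typed tables all flow in
.lane_aliases <- c(lc3ii = "lc3ii_au", lc3i = "lc3i_au",
                   loading_control = "loading_au")

# validate and canonicalize a LaneQuant table
validate_lanes <- function(lanes) {
  if (!is.data.frame(lanes)) af_validation_error("'lanes' must be a data frame")
  lanes <- as.data.frame(lanes, stringsAsFactors = FALSE)
  for (nm in names(.lane_aliases))
    if (!nm %in% names(lanes) && .lane_aliases[[nm]] %in% names(lanes))
      names(lanes)[names(lanes) == .lane_aliases[[nm]]] <- nm
  req <- c("replicate_id", "condition", "inhibitor", "lc3ii", "loading_control")
  miss <- setdiff(req, names(lanes))
  if (length(miss))
    af_validation_error("lane table is missing column(s): %s", paste(miss, collapse = ", "))
  lanes$replicate_id <- as.character(lanes$replicate_id)
  lanes$condition <- as.character(lanes$condition)
  inh <- lanes$inhibitor
  if (is.character(inh)) inh <- toupper(trimws(inh))
  lanes$inhibitor <- if (is.logical(inh)) inh
    else if (is.numeric(inh)) inh != 0
    else inh %in% c("1", "TRUE", "T", "YES", "BAF+", "+")
  for (col in c("lc3ii", "loading_control"))
    if (!is.numeric(lanes[[col]]) || anyNA(lanes[[col]]))
      af_validation_error("column '%s' must be numeric and complete", col)
  if (any(lanes$lc3ii < 0)) af_validation_error("'lc3ii' intensities must be >= 0")
  if (any(lanes$loading_control <= 0))
    af_validation_error("'loading_control' must be > 0 in every lane (row %s)",
                        paste(which(lanes$loading_control <= 0), collapse = ", "))
  key <- paste(lanes$replicate_id, lanes$condition, lanes$inhibitor)
  if (anyDuplicated(key))
    af_validation_error("duplicate (replicate, condition, inhibitor) key at row %s",
                        paste(which(duplicated(key)), collapse = ", "))
  lanes
}

#' Normalize LC3-II lane intensities into a flux design
#'
#' Applies a loading-control normalization scheme to a table of per-lane
#' band intensities and arranges the result as the replicate-matched
#' k-condition x 2-inhibitor design that the two-step model consumes.
#'
#' Schemes: `"lc3ii_over_control"` divides LC3-II by the loading-control
#' (e.g. beta-actin) intensity; `"percent_over_control"` additionally
#' rescales each replicate so its reference cell (control condition
#' without inhibitor, by default) is 100, the "% over control" convention
#' of published blots; `"lc3ii_over_lc3i"` divides by the lane's LC3-I
#' intensity instead. Because the model's ratios are quotients of
#' differences, `lc3ii_over_control` and `percent_over_control` give
#' identical formation/degradation/net ratios.
#'
#' @param lanes data frame of lane quantifications, columns
#'   `replicate_id`, `condition`, `inhibitor` (logical or 0/1),
#'   `lc3ii`, `loading_control` (aliases `lc3ii_au`, `loading_au`
#'   accepted) and optionally `lc3i`/`lc3i_au`.
#' @param scheme normalization scheme (see Details).
#' @param reference list with elements `condition` and `inhibitor` naming
#'   the reference cell; defaults to condition `"EXP-"` (or the first
#'   condition seen) without inhibitor.
#' @return A `flux_design`: data frame with columns `replicate_id`,
#'   `condition` (factor, reference level first), `inhibitor`, `value`,
#'   carrying the scheme and reference as attributes.
#' @export
normalize_lanes <- function(lanes,
                            scheme = c("lc3ii_over_control", "percent_over_control",
                                       "lc3ii_over_lc3i"),
                            reference = NULL) {
  if (length(scheme) == 1L &&
      !scheme %in% c("lc3ii_over_control", "percent_over_control", "lc3ii_over_lc3i"))
    af_config_error("unknown normalization scheme '%s'", scheme)
  scheme <- match.arg(scheme)
  lanes <- validate_lanes(lanes)

  conds <- unique(lanes$condition)
  if (is.null(reference))
    reference <- list(condition = if ("EXP-" %in% conds) "EXP-" else conds[1],
                      inhibitor = FALSE)
  if (is.character(reference)) reference <- list(condition = reference, inhibitor = FALSE)
  if (is.null(reference$condition) || !reference$condition %in% conds)
    af_config_error("reference condition '%s' not present in the data",
                    format(reference$condition))
  reference$inhibitor <- isTRUE(reference$inhibitor)

  if (scheme == "lc3ii_over_lc3i") {
    if (!"lc3i" %in% names(lanes) || anyNA(lanes$lc3i))
      af_config_error("scheme 'lc3ii_over_lc3i' requires a complete 'lc3i' column")
    if (any(lanes$lc3i <= 0))
      af_validation_error("'lc3i' must be > 0 under scheme 'lc3ii_over_lc3i'")
    q <- lanes$lc3ii / lanes$lc3i
  } else {
    q <- lanes$lc3ii / lanes$loading_control
  }

  if (scheme == "percent_over_control") {
    is_ref <- lanes$condition == reference$condition &
      lanes$inhibitor == reference$inhibitor
    if (!any(is_ref))
      af_design_error("reference cell (%s, BAF%s) is empty", reference$condition,
                      if (reference$inhibitor) "+" else "-")
    ref_q <- tapply(q[is_ref], lanes$replicate_id[is_ref], mean)
    idx <- match(lanes$replicate_id, names(ref_q))
    if (anyNA(idx))
      af_design_error("replicate(s) %s lack a reference-cell lane",
                      paste(unique(lanes$replicate_id[is.na(idx)]), collapse = ", "))
    if (any(ref_q <= 0))
      af_validation_error("reference-cell normalized value must be > 0")
    q <- q / ref_q[idx] * 100
  }

  lev <- c(reference$condition, setdiff(conds, reference$condition))
  out <- data.frame(replicate_id = lanes$replicate_id,
                    condition = factor(lanes$condition, levels = lev),
                    inhibitor = lanes$inhibitor,
                    value = as.numeric(q),
                    stringsAsFactors = FALSE)
  structure(out, scheme = scheme, reference = reference,
            class = c("flux_design", "data.frame"))
}

# coerce raw lanes or an existing design to flux_design
as_flux_design <- function(x, scheme = "lc3ii_over_control", reference = NULL) {
  if (inherits(x, "flux_design")) return(x)
  if (is.data.frame(x) && all(c("replicate_id", "condition", "inhibitor", "value")
                              %in% names(x))) {
    conds <- unique(as.character(x$condition))
    if (is.null(reference))
      reference <- list(condition = if ("EXP-" %in% conds) "EXP-" else conds[1],
                        inhibitor = FALSE)
    if (is.character(reference)) reference <- list(condition = reference, inhibitor = FALSE)
    lev <- c(reference$condition, setdiff(conds, reference$condition))
    out <- data.frame(replicate_id = as.character(x$replicate_id),
                      condition = factor(as.character(x$condition), levels = lev),
                      inhibitor = as.logical(x$inhibitor),
                      value = as.numeric(x$value), stringsAsFactors = FALSE)
    return(structure(out, scheme = "precomputed", reference = reference,
                     class = c("flux_design", "data.frame")))
  }
  normalize_lanes(x, scheme = scheme, reference = reference)
}

# named per-replicate values of one (condition, inhibitor) cell
cell_values <- function(design, condition, inhibitor) {
  sel <- design$condition == condition & design$inhibitor == inhibitor
  if (!any(sel))
    af_design_error("design cell (%s, BAF%s) is missing", condition,
                    if (inhibitor) "+" else "-")
  stats::setNames(design$value[sel], design$replicate_id[sel])
}

# replicate-matched difference between two cells
cell_diff <- function(design, cond_a, inh_a, cond_b, inh_b) {
  a <- cell_values(design, cond_a, inh_a)
  b <- cell_values(design, cond_b, inh_b)
  common <- intersect(names(a), names(b))
  if (!length(common))
    af_design_error("no replicate is present in both (%s, BAF%s) and (%s, BAF%s)",
                    cond_a, if (inh_a) "+" else "-", cond_b, if (inh_b) "+" else "-")
  a[common] - b[common]
}
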