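# Readers/writers for the band-table CSV schema shared by the
# quantification, simulation and model stages.

.band_schema <- c("replicate_id", "condition", "inhibitor", "lc3ii_au",
                  "loading_au")

#' Read a per-lane band table
#'
#' Reads a CSV or TSV of per-lane LC3 quantifications (delimiter sniffed
#' from the header unless given) and returns a validated lane table ready
#' for [normalize_lanes()] / [flux_fit()]. Required columns:
#' `replicate_id`, `condition`, `inhibitor` (0/1 or logical), `lc3ii_au`,
#' `loading_au`; optional: `lc3i_au`, `treatment_label`, `duration_h`.
#' Internal column names (`lc3ii`, `loading_control`, `lc3i`) are also
#' accepted. Validation failures report the offending row number.
#'
#' @param path file path.
#' @param delimiter `","`, `"\t"`, or `NULL` to sniff.
#' @return Validated lane data frame with canonical column names.
#' @export
read_band_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) af_validation_error("band table not found: %s", path)
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("lc3ii_au", "loading_au", "lc3i_au", "lc3ii", "loading_control", "lc3i"))
    if (col %in% names(raw) && !is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))
      af_validation_error("non-numeric value in column '%s' at row %s", col,
                          paste(bad, collapse = ", "))
    }
  tryCatch(validate_lanes(raw), autoflux_validation_error = function(e) {
    stop(e)  # row numbers already embedded by validate_lanes
  })
}

#' Write a lane table in the band-table CSV schema
#'
#' @param lanes validated lane data frame (internal or `_au` names).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_band_table <- function(lanes, path) {
  lanes <- validate_lanes(lanes)
  out <- data.frame(replicate_id = lanes$replicate_id,
                    condition = lanes$condition,
                    inhibitor = as.integer(lanes$inhibitor),
                    lc3ii_au = lanes$lc3ii,
                    loading_au = lanes$loading_control,
                    stringsAsFactors = FALSE)
  if ("lc3i" %in% names(lanes)) out$lc3i_au <- lanes$lc3i
  if ("treatment_label" %in% names(lanes)) out$treatment_label <- lanes$treatment_label
  if ("duration_h" %in% names(lanes)) out$duration_h <- lanes$duration_h
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a lane table from quantified band calls
#'
#' Pivots the long band-call table produced by [quantify_gel()] (one row
#' per lane x band) into the wide per-lane schema of the flux model,
#' using a lane annotation table to attach the experimental factors.
#' Band labels `LC3-II` and `loading_control` are required per lane;
#' `LC3-I` is optional.
#'
#' @param band_calls data frame with columns `lane_id`, `band_label`,
#'   `area` (or `area_au`), optionally `saturated`.
#' @param annotations data frame with columns `lane_id`, `replicate_id`,
#'   `condition`, `inhibitor`, optionally `treatment_label`, `duration_h`.
#' @return Validated lane data frame; saturated LC3-II or loading bands
#'   raise a warning naming the lanes.
#' @export
assemble_lanes <- function(band_calls, annotations) {
  if ("area_au" %in% names(band_calls) && !"area" %in% names(band_calls))
    names(band_calls)[names(band_calls) == "area_au"] <- "area"
  req <- c("lane_id", "band_label", "area")
  if (!is.data.frame(band_calls) || !all(req %in% names(band_calls)))
    af_validation_error("'band_calls' needs columns %s", paste(req, collapse = ", "))
  if (!all(c("lane_id", "replicate_id", "condition", "inhibitor") %in% names(annotations)))
    af_validation_error("'annotations' needs lane_id, replicate_id, condition, inhibitor")
  pick <- function(lane, label) {
    sel <- band_calls$lane_id == lane & band_calls$band_label == label
    if (!any(sel)) return(NA_real_)
    band_calls$area[sel][1]
  }
  lanes <- unique(as.character(annotations$lane_id))
  miss <- setdiff(unique(as.character(band_calls$lane_id)), lanes)
  if (length(miss))
    warning(sprintf("band calls for unannotated lane(s) dropped: %s",
                    paste(miss, collapse = ", ")), call. = FALSE)
  out <- do.call(rbind, lapply(lanes, function(ln) {
    an <- annotations[annotations$lane_id == ln, ][1, ]
    lc3ii <- pick(ln, "LC3-II"); load <- pick(ln, "loading_control")
    if (is.na(lc3ii) || is.na(load))
      af_validation_error("lane '%s' is missing an LC3-II or loading_control band call", ln)
    row <- data.frame(replicate_id = as.character(an$replicate_id),
                      condition = as.character(an$condition),
                      inhibitor = an$inhibitor, lc3ii = lc3ii,
                      loading_control = load, stringsAsFactors = FALSE)
    lc3i <- pick(ln, "LC3-I")
    if (!is.na(lc3i)) row$lc3i <- lc3i
    if ("treatment_label" %in% names(an)) row$treatment_label <- an$treatment_label
    if ("duration_h" %in% names(an)) row$duration_h <- an$duration_h
    row
  }))
  if ("saturated" %in% names(band_calls)) {
    sat <- band_calls$lane_id[band_calls$saturated &
                                band_calls$band_label %in% c("LC3-II", "loading_control")]
    if (length(sat))
      warning(sprintf("saturated band(s) in lane(s): %s (nonlinear detection)",
                      paste(unique(sat), collapse = ", ")), call. = FALSE)
  }
  validate_lanes(out)
}
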