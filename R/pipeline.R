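# End-to-end run: config -> (quantify | simulate | read) -> fit -> stats
# -> outputs. One structured config drives the whole analysis so a run is
# reproducible from a single file plus its inputs.

#' Run the full analysis pipeline from a config
#'
#' Executes the stages the assay's workflow prescribes — quantify a blot
#' image (or read/simulate a band table), normalize into the
#' four-condition design, fit the two-step model, run the statistical
#' decision pipeline — and collects everything in a self-contained run
#' report. Identical config + inputs + seed give identical numeric
#' results.
#'
#' Config is a named list or a YAML file with sections:
#' \describe{
#'   \item{input}{exactly one of `bands` (CSV path), `simulate` (a list of
#'     [scenario_spec()]/[flux_preset()] arguments; `preset` selects a
#'     preset), or `image` (list with `path`, `rois`, `bands` CSV paths and
#'     optional `baseline`, `window`) plus `annotations` (CSV path mapping
#'     lane_id to factors).}
#'   \item{scheme}{normalization scheme, default `"lc3ii_over_control"`.}
#'   \item{reference}{list `condition`, `inhibitor`; mandatory.}
#'   \item{stats}{list with `direction` (mandatory for tests; set
#'     `stats: ~` to skip testing), `alpha`, `tendency`, `paired`,
#'     `posthoc`.}
#'   \item{seed}{top-level seed; all stage randomness derives from it.}
#'   \item{out_dir}{if set, estimates/ratios CSVs, a JSON summary and the
#'     figure panels are written there.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return An object of class `flux_report`: list with `config`, `seed`,
#'   `lanes`, `fit`, `stats` (or `NULL`), `warnings` (character vector of
#'   every stage warning, deduplicated), `version`, `timestamp`.
#' @export
flux_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) af_config_error("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) af_config_error("'config' must be a list or YAML path")
  # fail fast before any computation
  if (is.null(config$input))
    af_config_error("config is missing the 'input' section")
  if (sum(!vapply(config$input[c("bands", "simulate", "image")], is.null,
                  logical(1))) != 1L)
    af_config_error("config 'input' must name exactly one of: bands, simulate, image")
  if (is.null(config$reference) || is.null(config$reference$condition))
    af_config_error("config is missing the reference cell ('reference: condition: ...')")
  scheme <- config$scheme %||% "lc3ii_over_control"
  seed <- config$seed

  warn_log <- character()
  capture <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  lanes <- capture(
    if (!is.null(config$input$bands)) {
      read_band_table(config$input$bands)
    } else if (!is.null(config$input$simulate)) {
      sim_cfg <- config$input$simulate
      sim_cfg$seed <- sim_cfg$seed %||% derive_seed(seed, 1L)
      spec <- if (!is.null(sim_cfg$preset)) {
        args <- sim_cfg[setdiff(names(sim_cfg), "preset")]
        do.call(flux_preset, c(list(name = sim_cfg$preset), args))
      } else do.call(scenario_spec, sim_cfg)
      simulate_flux(spec)$lanes
    } else {
      img_cfg <- config$input$image
      if (is.null(img_cfg$path) || is.null(img_cfg$rois) || is.null(img_cfg$bands))
        af_config_error("image input needs 'path', 'rois' and 'bands'")
      if (is.null(config$input$annotations))
        af_config_error("image input needs an 'annotations' table")
      img <- read_gel_image(img_cfg$path, bit_depth = img_cfg$bit_depth %||% 16,
                            orientation = img_cfg$orientation %||% "vertical")
      rois <- utils::read.csv(img_cfg$rois, stringsAsFactors = FALSE)
      bands <- utils::read.csv(img_cfg$bands, stringsAsFactors = FALSE)
      calls <- quantify_gel(img, rois, bands,
                            method = img_cfg$baseline %||% "rolling-ball",
                            window = img_cfg$window %||% 50)
      ann <- utils::read.csv(config$input$annotations, stringsAsFactors = FALSE)
      assemble_lanes(calls, ann)
    })

  fit <- capture(flux_fit(lanes, scheme = scheme, reference = config$reference))

  stats_res <- NULL
  if (!is.null(config$stats)) {
    s <- config$stats
    if (is.null(s$direction))
      af_config_error("config 'stats' section must state the one-tailed 'direction'")
    stats_res <- capture(flux_stats(fit, direction = s$direction,
                                    alpha = s$alpha %||% 0.05,
                                    tendency = s$tendency %||% 0.1,
                                    paired = isTRUE(s$paired),
                                    posthoc = s$posthoc %||% "vs_control"))
  }

  report <- structure(
    list(config = config, seed = seed, lanes = lanes, fit = fit,
         stats = stats_res, warnings = unique(warn_log),
         version = as.character(utils::packageVersion("autoflux")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    class = "flux_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.flux_report <- function(x, ...) {
  cat(sprintf("Autophagic flux run report (autoflux %s, seed %s)\n",
              x$version, if (is.null(x$seed)) "none" else format(x$seed)))
  print(x$fit)
  if (!is.null(x$stats)) print(x$stats)
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  - ", w, "\n", sep = "")
  }
  invisible(x)
}

# write estimates/ratios CSVs + JSON summary + figures under out_dir
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$fit$estimates, file.path(out_dir, "estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(turnover_ratios(report$fit), file.path(out_dir, "ratios.csv"),
                   row.names = FALSE)
  sm <- summary(report$fit)$table
  js <- list(version = report$version, seed = report$seed,
             scheme = report$fit$scheme,
             reference = report$fit$reference,
             summary = sm, warnings = report$warnings)
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  render_figures(report, out_dir)
  invisible(out_dir)
}

#' Render the standard figure panels
#'
#' Writes the four bar-chart panels of [plot.flux_fit()] (raw LC3-II,
#' flux, formation/degradation rates, turnover ratios with the reference
#' line at 1) as deterministically named image files.
#'
#' @param x a `flux_report` or [flux_fit()] object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"autoflux"`).
#' @param format `"png"` or `"svg"`.
#' @param width,height device size in pixels (png) or inches (svg).
#' @return Character vector of files written, invisibly. An empty
#'   estimates table produces a warning and no files.
#' @export
render_figures <- function(x, dir, prefix = "autoflux", format = c("png", "svg"),
                           width = 700, height = 500) {
  format <- match.arg(format)
  fit <- if (inherits(x, "flux_report")) x$fit else x
  stopifnot(inherits(fit, "flux_fit"))
  if (nrow(fit$estimates) == 0L) {
    warning("no estimates to plot; skipping figures", call. = FALSE)
    return(invisible(character()))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panels <- c("raw_lc3ii", "flux", "rates", "ratios")
  files <- file.path(dir, sprintf("%s_%s.%s", prefix, panels, format))
  for (i in seq_along(panels)) {
    if (format == "png") grDevices::png(files[i], width = width, height = height)
    else grDevices::svg(files[i], width = width / 100, height = height / 100)
    plot(fit, which = i)
    grDevices::dev.off()
  }
  invisible(files)
}
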