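# S3 methods for flux_fit objects.

#' @export
print.flux_fit <- function(x, ...) {
  cat("Two-step autophagic flux model fit\n")
  cat(sprintf("  scheme: %s; reference: %s (BAF%s); %d replicate(s)\n",
              x$scheme, x$reference$condition,
              if (x$reference$inhibitor) "+" else "-", x$n_replicates))
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  co <- coef(x)
  cat("  condition-mean estimates:\n")
  print(round(co, 4))
  if (x$warnings$negative_rates > 0)
    cat(sprintf("  ! %d negative rate(s) flagged\n", x$warnings$negative_rates))
  if (x$warnings$undefined_ratios > 0)
    cat(sprintf("  ! %d undefined ratio(s) (NA)\n", x$warnings$undefined_ratios))
  invisible(x)
}

#' @export
coef.flux_fit <- function(object, ...) {
  e <- object$estimates
  agg <- function(col) tapply(e[[col]], e$condition, mean, na.rm = TRUE)
  out <- cbind(flux = agg("flux"), formation = agg("formation"),
               degradation = agg("degradation"),
               formation_ratio = agg("formation_ratio"),
               degradation_ratio = agg("degradation_ratio"),
               net_ratio = agg("net_ratio"))
  out[object$conditions, , drop = FALSE]
}

#' @export
residuals.flux_fit <- function(object, ...) {
  pb <- pool_balance(object)
  stats::setNames(pb$residual, paste(pb$replicate_id, pb$condition, sep = ":"))
}

#' Summarize a two-step flux fit
#'
#' Condition-level means and standard errors of the per-replicate rates
#' and ratios (the "mean +/- SEM" presentation of replicate blots).
#'
#' @param object a [flux_fit()] object.
#' @param ... unused.
#' @return A `summary.flux_fit` object: data frame of condition x measure
#'   means, SEMs and replicate counts.
#' @export
summary.flux_fit <- function(object, ...) {
  e <- object$estimates
  measures <- c("flux", "formation", "degradation",
                "formation_ratio", "degradation_ratio", "net_ratio")
  rows <- lapply(measures, function(m) {
    mu <- tapply(e[[m]], e$condition, mean, na.rm = TRUE)
    se <- tapply(e[[m]], e$condition, sem)
    n  <- tapply(!is.na(e[[m]]), e$condition, sum)
    data.frame(measure = m, condition = names(mu), mean = as.numeric(mu),
               sem = as.numeric(se), n = as.integer(n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(list(table = out, scheme = object$scheme,
                 reference = object$reference,
                 warnings = object$warnings,
                 n_replicates = object$n_replicates),
            class = "summary.flux_fit")
}

#' @export
print.summary.flux_fit <- function(x, ...) {
  cat(sprintf("Two-step flux model summary (%s, reference %s, n = %d)\n",
              x$scheme, x$reference$condition, x$n_replicates))
  tab <- x$table
  tab$mean <- round(tab$mean, 4); tab$sem <- round(tab$sem, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot a two-step flux fit
#'
#' Four base-graphics bar panels in the layout of published blot
#' quantifications: raw normalized LC3-II by design cell, conventional
#' flux per condition, formation and degradation rates, and the three
#' turnover ratios with a dotted red reference line at 1 (the basal
#' equilibrium value). Error bars are mean +/- SEM across replicates.
#'
#' @param x a [flux_fit()] object.
#' @param which subset of panels 1:4 to draw.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.flux_fit <- function(x, which = 1:4, ...) {
  e <- x$estimates
  d <- x$design
  op <- graphics::par(mfrow = c(length(which) > 2 && 2 || 1,
                                ceiling(length(which) / (length(which) > 2 && 2 || 1))),
                      mar = c(6, 4, 3, 1))
  on.exit(graphics::par(op))
  bars <- function(means, sems, main, ylab, ref_line = NULL, ...) {
    ok <- !is.na(means)
    ylim <- range(0, means[ok] + ifelse(is.na(sems[ok]), 0, sems[ok]),
                  means[ok] - ifelse(is.na(sems[ok]), 0, sems[ok]), ref_line)
    bp <- graphics::barplot(means, main = main, ylab = ylab, las = 2,
                            ylim = ylim * 1.1, ...)
    up <- means + sems; lo <- means - sems
    ok2 <- ok & !is.na(sems) & sems > 0
    if (any(ok2))
      graphics::arrows(bp[ok2], lo[ok2], bp[ok2], up[ok2], angle = 90, code = 3,
                       length = 0.04)
    if (!is.null(ref_line))
      graphics::abline(h = ref_line, col = "red", lty = 3)
    if (any(!ok))
      graphics::mtext("NA", side = 1, at = bp[!ok], line = -2, col = "grey40")
  }
  ylab <- if (x$scheme == "percent_over_control") "LC3-II (% of control)" else "LC3-II (au)"
  if (1 %in% which) {
    cellkey <- interaction(d$condition, ifelse(d$inhibitor, "BAF+", "BAF-"),
                           sep = " ", lex.order = TRUE)
    bars(tapply(d$value, cellkey, mean), tapply(d$value, cellkey, sem),
         "Raw LC3-II", ylab, ...)
  }
  agg <- function(col) list(m = tapply(e[[col]], e$condition, mean, na.rm = TRUE),
                            s = tapply(e[[col]], e$condition, sem))
  if (2 %in% which) { a <- agg("flux"); bars(a$m, a$s, "Autophagic flux", "au", ...) }
  if (3 %in% which) {
    fo <- agg("formation"); de <- agg("degradation")
    m <- rbind(formation = fo$m, degradation = de$m)
    bp <- graphics::barplot(m, beside = TRUE, main = "Formation / degradation",
                            ylab = "au", las = 2,
                            legend.text = rownames(m),
                            args.legend = list(x = "topleft", bty = "n", cex = 0.8), ...)
    s <- rbind(fo$s, de$s)
    ok <- !is.na(m) & !is.na(s) & s > 0
    if (any(ok))
      graphics::arrows(bp[ok], (m - s)[ok], bp[ok], (m + s)[ok], angle = 90,
                       code = 3, length = 0.04)
  }
  if (4 %in% which) {
    fr <- agg("formation_ratio"); dr <- agg("degradation_ratio"); nr <- agg("net_ratio")
    m <- rbind(formation = fr$m, degradation = dr$m, net = nr$m)
    bp <- graphics::barplot(m, beside = TRUE, main = "Turnover ratios",
                            ylab = "ratio vs basal", las = 2,
                            legend.text = rownames(m),
                            args.legend = list(x = "topleft", bty = "n", cex = 0.8), ...)
    s <- rbind(fr$s, dr$s, nr$s)
    ok <- !is.na(m) & !is.na(s) & s > 0
    if (any(ok))
      graphics::arrows(bp[ok], (m - s)[ok], bp[ok], (m + s)[ok], angle = 90,
                       code = 3, length = 0.04)
    graphics::abline(h = 1, col = "red", lty = 3)
  }
  invisible(x)
}

#' Simulate new datasets from a fitted model
#'
#' Builds a forward scenario from the fitted condition means (steady-state
#' pool, basal flux, and the first treatment's formation/degradation
#' multipliers) and draws `nsim` new four-condition lane tables with
#' multiplicative lognormal noise — a parametric bootstrap of the assay.
#'
#' @param object a [flux_fit()] object with at least one treatment
#'   condition and a positive basal flux.
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param noise_cv lane-noise coefficient of variation (default 0.1).
#' @param n_replicates replicates per dataset (default: as fitted).
#' @param ... unused.
#' @return A list of `nsim` lane tables (see [simulate_flux()]).
#' @export
simulate.flux_fit <- function(object, nsim = 1, seed = NULL, noise_cv = 0.1,
                              n_replicates = NULL, ...) {
  co <- coef(object)
  trt <- object$treatments[1]
  if (is.na(trt) || is.null(trt))
    af_design_error("fit has no treatment condition to simulate from")
  b <- mean(object$estimates$formation[object$estimates$condition ==
                                         object$reference$condition])
  pool <- mean(object$estimates$pool_ss)
  if (!is.finite(b) || b <= 0)
    af_degenerate_error("fitted basal flux must be > 0 to simulate")
  spec <- scenario_spec(pool_ss = pool, basal_flux = b,
                        f_mult = co[trt, "formation_ratio"],
                        d_mult = co[trt, "degradation_ratio"],
                        noise_cv = noise_cv,
                        n_replicates = n_replicates %||% object$n_replicates,
                        seed = seed, label = paste0("refit:", trt))
  lapply(seq_len(nsim), function(i)
    simulate_flux(within_spec_seed(spec, seed, i))$lanes)
}

# per-draw seed derivation for simulate.flux_fit
within_spec_seed <- function(spec, seed, i) {
  spec$seed <- if (is.null(seed)) NULL else derive_seed(seed, i)
  spec
}
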