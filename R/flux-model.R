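# The two-step pool model. The autophagosome pool is a black box with an
# input (formation) and an output (degradation); over the treatment window
#
#   pool_t = pool_ss + formation - degradation
#
# and in the basal condition formation = degradation (equilibrium), so the
# basal inhibitor increment measures both at once. All estimators are
# replicate-matched differences of the four design cells:
#
#   basal flux  = value(ref, BAF+) - value(ref, BAF-)
#   degradation = value(cond, BAF+) - value(cond, BAF-)   (conventional flux)
#   formation   = value(cond, BAF+) - value(ref,  BAF-)

ref_condition <- function(design) {
  ref <- attr(design, "reference")
  if (is.null(ref)) ref <- list(condition = levels(design$condition)[1],
                                inhibitor = FALSE)
  ref
}

#' Basal autophagic flux
#'
#' Per-replicate difference in normalized LC3-II between inhibitor-present
#' and inhibitor-absent lanes of the reference (basal) condition. Under the
#' basal-equilibrium assumption this single number is both the basal
#' formation and the basal degradation rate over the treatment window.
#'
#' @param design a `flux_design` from [normalize_lanes()] (or a lane table,
#'   which is normalized with defaults).
#' @return Named numeric vector of per-replicate basal fluxes (au). A
#'   warning is emitted when any replicate's flux is negative, which
#'   indicates inhibitor failure or densitometry noise.
#' @export
basal_flux <- function(design) {
  design <- as_flux_design(design)
  ref <- ref_condition(design)
  out <- cell_diff(design, ref$condition, TRUE, ref$condition, FALSE)
  if (any(out < 0))
    warning(sprintf("negative basal flux in replicate(s): %s",
                    paste(names(out)[out < 0], collapse = ", ")), call. = FALSE)
  out
}

#' Degradation rate of a condition
#'
#' The conventional autophagic flux of `condition`: the inhibitor-induced
#' LC3-II increment within that condition, i.e. the autophagosomes degraded
#' during the treatment window.
#'
#' @inheritParams basal_flux
#' @param condition condition label; defaults to the first non-reference
#'   condition.
#' @return Named numeric vector of per-replicate degradation amounts (au).
#' @export
degradation_rate <- function(design, condition = NULL) {
  design <- as_flux_design(design)
  condition <- condition %||% setdiff(levels(design$condition),
                                      ref_condition(design)$condition)[1]
  out <- cell_diff(design, condition, TRUE, condition, FALSE)
  if (any(out < 0))
    warning(sprintf("negative degradation rate (%s) in replicate(s): %s", condition,
                    paste(names(out)[out < 0], collapse = ", ")), call. = FALSE)
  out
}

#' Formation rate of a condition
#'
#' New autophagosomes made during the treatment window: LC3-II accumulated
#' under the inhibitor in `condition` minus the steady-state pool (the
#' reference condition without inhibitor), replicate-matched.
#'
#' @inheritParams degradation_rate
#' @return Named numeric vector of per-replicate formation amounts (au).
#' @export
formation_rate <- function(design, condition = NULL) {
  design <- as_flux_design(design)
  ref <- ref_condition(design)
  condition <- condition %||% setdiff(levels(design$condition), ref$condition)[1]
  out <- cell_diff(design, condition, TRUE, ref$condition, FALSE)
  if (any(out < 0))
    warning(sprintf("negative formation rate (%s) in replicate(s): %s", condition,
                    paste(names(out)[out < 0], collapse = ", ")), call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the two-step autophagic flux model
#'
#' The central fitting function: takes a lane table (or an already
#' normalized `flux_design`), applies the chosen normalization, and
#' computes per-replicate basal flux, formation, degradation, pool sizes
#' and the three turnover ratios for every treatment condition against the
#' reference. Rates are computed per replicate first and summarized
#' afterwards, preserving the blot pairing needed for paired tests.
#'
#' Negative rates are reported as-is and flagged, never clamped; ratios
#' with a non-positive denominator are set to `NA` and counted in
#' `$warnings` rather than silently dropped. The basal condition's ratios
#' are exactly 1 by the equilibrium assumption.
#'
#' @param data lane table (see [normalize_lanes()]) or `flux_design`.
#' @inheritParams normalize_lanes
#' @return An object of class `flux_fit`: list with `design`, `estimates`
#'   (per replicate x condition data frame with columns `pool_ss`,
#'   `pool_t`, `flux`, `formation`, `degradation`, `formation_ratio`,
#'   `degradation_ratio`, `net_ratio`, `negative_rate`), `reference`,
#'   `scheme`, `conditions`, `n_replicates`, `warnings`, and `call`.
#' @examples
#' sim <- simulate_flux(flux_preset("balanced_up", noise_cv = 0, seed = 1))
#' fit <- flux_fit(sim$lanes)
#' summary(fit)
#' @seealso [turnover_ratios()], [pool_balance()], [flux_stats()]
#' @export
flux_fit <- function(data, scheme = "lc3ii_over_control", reference = NULL) {
  design <- as_flux_design(data, scheme = scheme, reference = reference)
  ref <- ref_condition(design)
  conds <- levels(design$condition)
  treatments <- setdiff(conds, ref$condition)

  bf <- suppressWarnings(basal_flux(design))
  pool_ss <- cell_values(design, ref$condition, FALSE)

  one_condition <- function(cond) {
    if (cond == ref$condition) {
      reps <- names(bf)
      data.frame(replicate_id = reps, condition = cond,
                 pool_ss = as.numeric(pool_ss[reps]),
                 pool_t = as.numeric(pool_ss[reps]),
                 flux = as.numeric(bf), formation = as.numeric(bf),
                 degradation = as.numeric(bf),
                 formation_ratio = 1, degradation_ratio = 1, net_ratio = 1,
                 negative_rate = bf < 0, stringsAsFactors = FALSE)
    } else {
      fo <- suppressWarnings(formation_rate(design, cond))
      de <- suppressWarnings(degradation_rate(design, cond))
      pt <- cell_values(design, cond, FALSE)
      reps <- Reduce(intersect, list(names(fo), names(de), names(pt), names(bf)))
      fo <- fo[reps]; de <- de[reps]; b <- bf[reps]
      data.frame(replicate_id = reps, condition = cond,
                 pool_ss = as.numeric(pool_ss[reps]), pool_t = as.numeric(pt[reps]),
                 flux = as.numeric(de), formation = as.numeric(fo),
                 degradation = as.numeric(de),
                 formation_ratio = ifelse(b > 0, fo / b, NA_real_),
                 degradation_ratio = ifelse(b > 0, de / b, NA_real_),
                 net_ratio = ifelse(fo > 0, de / fo, NA_real_),
                 negative_rate = fo < 0 | de < 0, stringsAsFactors = FALSE)
    }
  }
  est <- do.call(rbind, lapply(conds, one_condition))
  est$condition <- factor(est$condition, levels = conds)
  rownames(est) <- NULL

  n_neg <- sum(est$negative_rate)
  n_undef <- sum(is.na(est[c("formation_ratio", "degradation_ratio", "net_ratio")]))
  if (n_neg > 0)
    warning(sprintf("%d replicate rate(s) are negative (flagged in estimates)", n_neg),
            call. = FALSE)
  if (n_undef > 0)
    warning(sprintf("%d ratio(s) undefined (non-positive denominator); set to NA", n_undef),
            call. = FALSE)

  structure(list(design = design, estimates = est, reference = ref,
                 scheme = attr(design, "scheme"), conditions = conds,
                 treatments = treatments,
                 n_replicates = length(unique(design$replicate_id)),
                 warnings = list(negative_rates = n_neg, undefined_ratios = n_undef),
                 call = match.call()),
            class = "flux_fit")
}

#' Turnover ratios of a fitted model
#'
#' Per-replicate formation ratio (condition formation over basal flux),
#' degradation ratio (condition degradation over basal flux) and net
#' turnover ratio (degradation over formation within the condition). The
#' net ratio is 1 at basal equilibrium; values below 1 mean formation
#' outpaces degradation (pool growth), above 1 the reverse.
#'
#' @param fit a [flux_fit()] object.
#' @return Data frame with columns `replicate_id`, `condition`,
#'   `formation_ratio`, `degradation_ratio`, `net_ratio`.
#' @export
turnover_ratios <- function(fit) {
  stopifnot(inherits(fit, "flux_fit"))
  fit$estimates[c("replicate_id", "condition", "formation_ratio",
                  "degradation_ratio", "net_ratio")]
}

#' Pool-balance residuals
#'
#' Checks the model's central self-consistency identity
#' `pool_t = pool_ss + formation - degradation` for every replicate and
#' condition. Because the three estimators are differences of the same
#' four cells, the residual is zero up to floating-point error for any
#' input; a non-zero residual indicates corrupted estimates.
#'
#' @param fit a [flux_fit()] object.
#' @return Data frame with columns `replicate_id`, `condition`, `residual`.
#' @export
pool_balance <- function(fit) {
  stopifnot(inherits(fit, "flux_fit"))
  e <- fit$estimates
  data.frame(replicate_id = e$replicate_id, condition = e$condition,
             residual = e$pool_t - (e$pool_ss + e$formation - e$degradation),
             stringsAsFactors = FALSE)
}
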