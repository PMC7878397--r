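# Statistical decision pipeline: two-way ANOVA interaction screen on the
# raw design, one-way ANOVA with Holm-Sidak step-down posthoc for >= 3
# conditions, one-tailed Student t-tests for two conditions, and
# one-tailed one-sample t-tests of the turnover ratios against 1. Every p
# is tier-labeled: significant (p < 0.05) or tendency (p < 0.1).

new_stat_result <- function(test_name, statistic, df, p_value, tail,
                            alpha = 0.05, tendency = 0.1, estimate = NA_real_) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value), tail = tail,
                 tier = p_tier(p_value, alpha, tendency), estimate = unname(estimate)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, %s-tailed p = %s [%s]\n",
              x$test_name, fmt_num(x$statistic), paste(fmt_num(x$df), collapse = ", "),
              x$tail, fmt_num(x$p_value), x$tier))
  invisible(x)
}

#' One-tailed one-sample t-test against 1
#'
#' Tests whether the mean of a set of ratios differs from the basal
#' reference value of 1 in a pre-specified direction. The direction must
#' always be supplied explicitly; inferring it from the data would double
#' the type-I error.
#'
#' @param values numeric vector, `n >= 2`, non-zero variance.
#' @param direction `"greater"` or `"less"` (alternative for the mean
#'   relative to `mu`).
#' @param mu null value (default 1, the basal net-turnover reference).
#' @param alpha,tendency significance and tendency thresholds for the
#'   tier label.
#' @return A `stat_result` with `t`, `df = n - 1`, the one-tailed p and
#'   its tier.
#' @export
t_test_vs_one <- function(values, direction = c("greater", "less"), mu = 1,
                          alpha = 0.05, tendency = 0.1) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    af_degenerate_error("need at least 2 non-missing values (got %d)", length(values))
  if (stats::sd(values) == 0)
    af_degenerate_error("zero variance: all values equal %s", fmt_num(values[1]))
  tt <- tryCatch(stats::t.test(values, mu = mu, alternative = direction),
                 error = function(e) af_degenerate_error(
                   "t-test failed: %s", conditionMessage(e)))
  new_stat_result(sprintf("one-sample t vs %s (%s)", fmt_num(mu), direction),
                  tt$statistic, tt$parameter, tt$p.value, "one",
                  alpha, tendency, estimate = mean(values))
}

#' One-tailed two-sample Student t-test
#'
#' Classic pooled-variance Student t by default (`welch = TRUE` switches
#' to the Welch correction); `paired = TRUE` tests the replicate-matched
#' difference scores. `direction` states the alternative for
#' `mean(a) - mean(b)`.
#'
#' @param a,b numeric vectors (equal length when `paired`).
#' @param direction `"greater"`, `"less"`, or `"two.sided"`.
#' @param paired replicate-matched test on `a - b`.
#' @param welch use the Welch unequal-variance t instead of pooled.
#' @inheritParams t_test_vs_one
#' @return A `stat_result`.
#' @export
t_test_groups <- function(a, b, direction = c("greater", "less", "two.sided"),
                          paired = FALSE, welch = FALSE,
                          alpha = 0.05, tendency = 0.1) {
  direction <- match.arg(direction)
  if (paired && length(a) != length(b))
    af_validation_error("paired test needs equal lengths (got %d and %d)",
                        length(a), length(b))
  if (length(a) < 2L || length(b) < 2L)
    af_degenerate_error("each group needs n >= 2")
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0 && !paired)
    af_degenerate_error("zero variance in both groups")
  if (paired && stats::sd(a - b) == 0)
    af_degenerate_error("zero variance of paired differences")
  tt <- tryCatch(stats::t.test(a, b, alternative = direction, paired = paired,
                               var.equal = !welch),
                 error = function(e) af_degenerate_error(
                   "t-test failed: %s", conditionMessage(e)))
  new_stat_result(sprintf("%s%s t-test (%s)", if (paired) "paired " else "",
                          if (welch) "Welch" else "Student", direction),
                  tt$statistic, tt$parameter, tt$p.value,
                  if (direction == "two.sided") "two" else "one",
                  alpha, tendency, estimate = mean(a) - mean(b))
}

#' One-way ANOVA
#'
#' Standard between/within decomposition via [stats::lm()]. Zero
#' within-group variance is rejected as degenerate input (real
#' densitometry never has zero variance; such data indicates a pipeline
#' bug upstream).
#'
#' @param values numeric response, or a list of per-group numeric vectors
#'   (in which case `group` is ignored).
#' @param group grouping factor matching `values`.
#' @return An `anova_table` data frame (term, df, sumsq, meansq,
#'   statistic, p_value) with the F test on the group term.
#' @export
oneway_anova <- function(values, group = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    if (any(lengths(values) == 0L)) af_validation_error("empty group supplied")
    group <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  group <- factor(group)
  if (nlevels(group) < 2L) af_validation_error("need at least 2 groups")
  if (any(tabulate(group) == 0L)) af_validation_error("empty group supplied")
  if (length(values) < nlevels(group) + 1L)
    af_validation_error("need total n >= k + 1 observations")
  fit <- stats::lm(values ~ group)
  tab <- suppressWarnings(stats::anova(fit))
  if (tab["Residuals", "Sum Sq"] <= 1e-12 * sum(tab[["Sum Sq"]]))
    af_degenerate_error("zero within-group variance; F is undefined")
  out <- data.frame(term = c("group", "residual"), df = tab$Df,
                    sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
                    statistic = tab$`F value`, p_value = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Two-way factorial ANOVA
#'
#' Main effects, interaction and residual for a treatment x inhibitor
#' factorial via [stats::lm()] with type-I sums of squares (identical to
#' all SS types on the balanced designs this assay produces). Every cell
#' must be occupied; an interaction F requires replicate observations
#' (residual df > 0), and an essentially exact fit (residual SS ~ 0 with
#' residual df > 0) is rejected as degenerate.
#'
#' @param values numeric response.
#' @param a,b the two factors (e.g. condition and inhibitor).
#' @param names_ab labels for the two factors in the output table.
#' @return An `anova_table` data frame with rows for `a`, `b`, `a:b` and
#'   the residual.
#' @export
twoway_anova <- function(values, a, b, names_ab = c("A", "B")) {
  a <- factor(a); b <- factor(b)
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    af_validation_error("both factors need >= 2 levels")
  counts <- table(a, b)
  if (any(counts == 0L)) {
    idx <- which(counts == 0L, arr.ind = TRUE)[1, ]
    af_validation_error("design cell (%s = %s, %s = %s) is empty",
                        names_ab[1], rownames(counts)[idx[1]],
                        names_ab[2], colnames(counts)[idx[2]])
  }
  fit <- stats::lm(values ~ a * b)
  tab <- suppressWarnings(stats::anova(fit))
  if (tab["Residuals", "Df"] == 0L)
    af_degenerate_error("no replicate observations per cell; interaction untestable")
  if (tab["Residuals", "Sum Sq"] <= 1e-12 * sum(tab[["Sum Sq"]]))
    af_degenerate_error("residual variance is zero (exact fit); F is undefined")
  out <- data.frame(term = c(names_ab[1], names_ab[2],
                             paste(names_ab, collapse = ":"), "residual"),
                    df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
                    statistic = tab$`F value`, p_value = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Holm-Sidak step-down multiplicity adjustment
#'
#' Sorts the m raw p-values ascending and adjusts the i-th smallest as
#' `1 - (1 - p)^(m - i + 1)`, enforcing monotonicity with a running
#' maximum (step-down). Hypotheses are rejected while the adjusted p
#' stays below `alpha`.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param alpha family-wise error rate (default 0.05).
#' @return Data frame in the input order with columns `p`, `p_adj`,
#'   `reject`.
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1))
    af_validation_error("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj_sorted <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj_sorted <- cummax(adj_sorted)
  adj <- numeric(m); adj[ord] <- adj_sorted
  # step-down rejection: stop at the first non-rejected sorted hypothesis
  rej_sorted <- adj_sorted < alpha
  if (any(!rej_sorted)) rej_sorted[seq(match(FALSE, rej_sorted), m)] <- FALSE
  reject <- logical(m); reject[ord] <- rej_sorted
  data.frame(p = p, p_adj = adj, reject = reject)
}

#' Normality and homoscedasticity screen
#'
#' Advisory pre-analysis checks: Shapiro-Wilk per group (groups with
#' `n >= 3`) and a Brown-Forsythe/Levene test (one-way ANOVA of absolute
#' deviations from group medians). No automatic nonparametric fallback is
#' taken; results are reported for the analyst.
#'
#' @param values numeric response.
#' @param group grouping factor.
#' @return List with `shapiro` (data frame per group) and `levene`
#'   (`stat_result`-like list), or `NULL` entries where sample sizes do
#'   not permit the check.
#' @export
assumption_screen <- function(values, group) {
  group <- factor(group)
  sh <- do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g]
    if (length(v) >= 3L && stats::sd(v) > 0) {
      s <- stats::shapiro.test(v)
      data.frame(group = g, n = length(v), W = unname(s$statistic),
                 p_value = s$p.value, stringsAsFactors = FALSE)
    } else data.frame(group = g, n = length(v), W = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
  }))
  lev <- NULL
  if (all(tabulate(group) >= 2L)) {
    med <- tapply(values, group, stats::median)
    z <- abs(values - med[group])
    lev <- tryCatch({
      tab <- oneway_anova(z, group)
      list(statistic = tab$statistic[1], df = tab$df,
           p_value = tab$p_value[1])
    }, autoflux_degenerate_error = function(e) NULL)
  }
  list(shapiro = sh, levene = lev)
}

# directions: single string recycled, or named list/vector per measure
resolve_direction <- function(direction, measure) {
  if (is.null(direction))
    af_config_error("one-tailed 'direction' must be supplied explicitly (never inferred from the data)")
  if (length(direction) == 1L && is.null(names(direction))) return(direction)
  d <- direction[[measure]]
  if (is.null(d))
    af_config_error("no direction configured for measure '%s'", measure)
  d
}

#' Statistical decision pipeline for a flux fit
#'
#' Reproduces the assay's analysis sequence. (1) The raw normalized
#' design is screened by two-way ANOVA (condition x inhibitor); if the
#' interaction is significant at `alpha`, the treatment effect is
#' re-examined by one-way ANOVA within each inhibitor level. (2) Flux,
#' formation and degradation are compared between each treatment and the
#' basal condition: by a one-tailed Student t-test when there is a single
#' treatment, or by one-way ANOVA across conditions followed by
#' Holm-Sidak-adjusted comparisons of each treatment against the control
#' (two-tailed, pooled ANOVA error) when there are two or more.
#' (3) Formation, degradation and net turnover ratios are tested against
#' the basal reference value of 1 with one-tailed one-sample t-tests,
#' Holm-Sidak-adjusted across treatments when there are several. Every
#' reported p carries a significance tier.
#'
#' Ratios that are undefined (`NA`) are excluded from the vs-1 tests with
#' their count recorded in the report.
#'
#' @param fit a [flux_fit()] object.
#' @param direction one-tailed alternative(s), mandatory: a single string
#'   (`"greater"`/`"less"`) applied to every comparison, or a named list
#'   with entries `flux`, `formation`, `degradation`, `formation_ratio`,
#'   `degradation_ratio`, `net_ratio`.
#' @param alpha significance threshold (default 0.05).
#' @param tendency tendency threshold (default 0.1).
#' @param paired use paired t-tests for the rate comparisons (replicates
#'   are blot-matched); default unpaired.
#' @param posthoc `"vs_control"` (default) or `"all_pairwise"` comparison
#'   family for the Holm-Sidak step.
#' @return An object of class `flux_stats`: list with `two_way`,
#'   `interaction`, `one_way_by_inhibitor`, `rate_tests`, `ratio_tests`,
#'   `posthoc`, `assumptions`, `excluded_ratios`, `alpha`, `tendency`.
#' @export
flux_stats <- function(fit, direction, alpha = 0.05, tendency = 0.1,
                       paired = FALSE, posthoc = c("vs_control", "all_pairwise")) {
  stopifnot(inherits(fit, "flux_fit"))
  posthoc <- match.arg(posthoc)
  if (missing(direction)) resolve_direction(NULL, "")
  d <- fit$design
  e <- fit$estimates
  refc <- fit$reference$condition
  treatments <- fit$treatments
  if (!length(treatments)) af_design_error("fit has no treatment condition to test")

  # stage 1: two-way screen on raw normalized values
  two_way <- twoway_anova(d$value, d$condition, ifelse(d$inhibitor, "BAF+", "BAF-"),
                          names_ab = c("condition", "inhibitor"))
  inter_p <- two_way$p_value[two_way$term == "condition:inhibitor"]
  one_way_by_inh <- NULL
  if (!is.na(inter_p) && inter_p < alpha && nlevels(d$condition) >= 2L) {
    one_way_by_inh <- lapply(c(`BAF-` = FALSE, `BAF+` = TRUE), function(i) {
      sub <- d[d$inhibitor == i, ]
      tryCatch(oneway_anova(sub$value, sub$condition),
               autoflux_degenerate_error = function(err) NULL)
    })
  }

  basal <- e[e$condition == refc, ]
  measures <- c("flux", "formation", "degradation")
  ratio_measures <- c("formation_ratio", "degradation_ratio", "net_ratio")
  rate_tests <- list(); posthoc_tab <- NULL

  if (length(treatments) == 1L) {
    trt <- e[e$condition == treatments, ]
    for (m in measures) {
      dir_m <- resolve_direction(direction, m)
      rate_tests[[paste(m, treatments, sep = ":")]] <-
        t_test_groups(trt[[m]], basal[[m]], direction = dir_m, paired = paired,
                      alpha = alpha, tendency = tendency)
    }
  } else {
    # one-way ANOVA across conditions per measure, Holm-Sidak vs-control posthoc
    for (m in measures) {
      an <- oneway_anova(e[[m]], e$condition)
      mse <- an$meansq[an$term == "residual"]
      dfr <- an$df[an$term == "residual"]
      pairs <- if (posthoc == "vs_control")
        lapply(treatments, function(tc) c(tc, refc))
      else utils::combn(fit$conditions, 2, simplify = FALSE)
      praw <- vapply(pairs, function(pr) {
        v1 <- e[[m]][e$condition == pr[1]]; v2 <- e[[m]][e$condition == pr[2]]
        tstat <- (mean(v1) - mean(v2)) /
          sqrt(mse * (1 / length(v1) + 1 / length(v2)))
        2 * stats::pt(abs(tstat), dfr, lower.tail = FALSE)
      }, numeric(1))
      hs <- holm_sidak(praw, alpha = alpha)
      tab <- data.frame(measure = m,
                        comparison = vapply(pairs, paste, character(1),
                                            collapse = " vs "),
                        p = hs$p, p_adj = hs$p_adj, reject = hs$reject,
                        tier = p_tier(hs$p_adj, alpha, tendency),
                        stringsAsFactors = FALSE)
      posthoc_tab <- rbind(posthoc_tab, tab)
      rate_tests[[paste("anova", m, sep = ":")]] <-
        new_stat_result(sprintf("one-way ANOVA on %s", m), an$statistic[1],
                        an$df, an$p_value[1], "two", alpha, tendency)
    }
  }

  # stage 3: ratios vs the basal reference of 1, one-tailed
  ratio_tests <- list(); excluded <- 0L
  ratio_p <- list()
  for (m in ratio_measures) {
    for (tc in treatments) {
      v <- e[[m]][e$condition == tc]
      excluded <- excluded + sum(is.na(v))
      res <- tryCatch(
        t_test_vs_one(v, direction = resolve_direction(direction, m),
                      alpha = alpha, tendency = tendency),
        autoflux_degenerate_error = function(err)
          new_stat_result(sprintf("one-sample t vs 1 (%s)", m), NA_real_,
                          NA_real_, NA_real_, "one", alpha, tendency))
      ratio_tests[[paste(m, tc, sep = ":")]] <- res
      ratio_p[[m]] <- c(ratio_p[[m]], stats::setNames(res$p_value, tc))
    }
  }
  ratio_adj <- NULL
  if (length(treatments) >= 2L) {
    ratio_adj <- do.call(rbind, lapply(names(ratio_p), function(m) {
      pv <- ratio_p[[m]]
      ok <- !is.na(pv)
      out <- data.frame(measure = m, condition = names(pv), p = as.numeric(pv),
                        p_adj = NA_real_, reject = NA, stringsAsFactors = FALSE)
      if (any(ok)) {
        hs <- holm_sidak(pv[ok], alpha = alpha)
        out$p_adj[ok] <- hs$p_adj; out$reject[ok] <- hs$reject
      }
      out$tier <- p_tier(out$p_adj, alpha, tendency)
      out
    }))
  }

  assumptions <- assumption_screen(
    d$value, interaction(d$condition, ifelse(d$inhibitor, "BAF+", "BAF-")))

  structure(list(two_way = two_way,
                 interaction = list(p_value = inter_p,
                                    significant = !is.na(inter_p) && inter_p < alpha,
                                    tier = p_tier(inter_p, alpha, tendency)),
                 one_way_by_inhibitor = one_way_by_inh,
                 rate_tests = rate_tests, posthoc = posthoc_tab,
                 ratio_tests = ratio_tests, ratio_posthoc = ratio_adj,
                 assumptions = assumptions, excluded_ratios = excluded,
                 alpha = alpha, tendency = tendency, treatments = treatments),
            class = "flux_stats")
}

#' @export
print.flux_stats <- function(x, ...) {
  cat("Autophagic flux decision pipeline\n")
  cat(sprintf("  two-way ANOVA interaction p = %s [%s]%s\n",
              fmt_num(x$interaction$p_value), x$interaction$tier,
              if (x$interaction$significant)
                " -> treatment re-analyzed by one-way ANOVA per inhibitor level"
              else ""))
  if (!is.null(x$one_way_by_inhibitor)) {
    for (nm in names(x$one_way_by_inhibitor)) {
      ow <- x$one_way_by_inhibitor[[nm]]
      if (!is.null(ow))
        cat(sprintf("    %s: F(%d, %d) = %s, p = %s [%s]\n", nm, ow$df[1], ow$df[2],
                    fmt_num(ow$statistic[1]), fmt_num(ow$p_value[1]),
                    p_tier(ow$p_value[1], x$alpha, x$tendency)))
    }
  }
  cat("  rate comparisons:\n")
  for (nm in names(x$rate_tests)) {
    r <- x$rate_tests[[nm]]
    cat(sprintf("    %-24s p = %-8s [%s]\n", nm, fmt_num(r$p_value), r$tier))
  }
  if (!is.null(x$posthoc)) {
    cat("  Holm-Sidak posthoc (rates):\n")
    ph <- x$posthoc; ph$p <- round(ph$p, 4); ph$p_adj <- round(ph$p_adj, 4)
    print(ph, row.names = FALSE)
  }
  cat("  ratios vs 1:\n")
  for (nm in names(x$ratio_tests)) {
    r <- x$ratio_tests[[nm]]
    cat(sprintf("    %-28s p = %-8s [%s]\n", nm, fmt_num(r$p_value), r$tier))
  }
  if (!is.null(x$ratio_posthoc)) {
    cat("  Holm-Sidak posthoc (ratios vs 1):\n")
    rp <- x$ratio_posthoc; rp$p <- round(rp$p, 4); rp$p_adj <- round(rp$p_adj, 4)
    print(rp, row.names = FALSE)
  }
  if (x$excluded_ratios > 0)
    cat(sprintf("  ! %d undefined ratio value(s) excluded from vs-1 tests\n",
                x$excluded_ratios))
  invisible(x)
}
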