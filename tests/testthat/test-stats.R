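# t-tests, ANOVA, Holm-Sidak and the decision pipeline.

# closed-form one-tailed upper p for Student t with 2 df:
# P(T > t) = 1/2 - t / (2*sqrt(2)*sqrt(1 + t^2/2))
p_upper_df2 <- function(t) 0.5 - t / (2 * sqrt(2) * sqrt(1 + t^2 / 2))

test_that("one-sample t vs 1 matches the closed-form df-2 oracle", {
  res <- t_test_vs_one(c(1.2, 1.3, 1.1), direction = "greater")
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-6)   # = 3.4641
  expect_equal(res$df, 2)
  expect_equal(res$p_value, p_upper_df2(2 * sqrt(3)), tolerance = 1e-10)
  expect_equal(res$p_value, 0.0371, tolerance = 1e-3)
  expect_equal(res$tier, "significant")
})

test_that("degenerate one-sample inputs raise errors; mean at 1 gives p = 0.5", {
  expect_error(t_test_vs_one(c(1, 1, 1), "greater"),
               class = "autoflux_degenerate_error")
  expect_error(t_test_vs_one(1.2, "greater"),
               class = "autoflux_degenerate_error")
  res <- t_test_vs_one(c(0.9, 1.1), "greater")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.5)
  expect_equal(res$tier, "ns")
})

test_that("two-sample Student t behaves under symmetry, pairing and translation", {
  res <- t_test_groups(c(10, 11, 12), c(10, 11, 12), direction = "two.sided")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.5 * 2)

  # paired test equals the one-sample test on difference scores (df = n-1)
  a <- c(10, 11, 12); b <- c(13, 14.5, 15)
  pr <- t_test_groups(b, a, direction = "greater", paired = TRUE)
  dd <- b - a
  or <- t_test_vs_one(dd, direction = "greater", mu = 0)
  expect_equal(pr$statistic, or$statistic, tolerance = 1e-12)
  expect_equal(pr$df, 2)
  expect_equal(pr$p_value, or$p_value, tolerance = 1e-12)

  # pooled-variance hand oracle
  m <- mean(b) - mean(a)
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  t_hand <- m / sqrt(sp2 * (2 / 3))
  un <- t_test_groups(b, a, direction = "greater")
  expect_equal(un$statistic, t_hand, tolerance = 1e-12)
  expect_equal(un$df, 4)

  # translation invariance
  sh <- t_test_groups(b + 100, a + 100, direction = "greater")
  expect_equal(sh$statistic, un$statistic, tolerance = 1e-10)
  expect_equal(sh$p_value, un$p_value, tolerance = 1e-10)

  expect_error(t_test_groups(1:3, 1:4, paired = TRUE, direction = "greater"),
               class = "autoflux_validation_error")
})

test_that("one-way ANOVA: F equals t^2 for two groups; degenerate input errors", {
  set.seed(31)
  for (i in 1:20) {
    a <- stats::rnorm(4); b <- stats::rnorm(5, 0.5)
    tab <- oneway_anova(list(a, b))
    tt <- t_test_groups(a, b, direction = "two.sided")
    expect_equal(tab$statistic[1], tt$statistic^2, tolerance = 1e-8)
    expect_equal(tab$p_value[1], tt$p_value, tolerance = 1e-8)
  }
  expect_error(oneway_anova(list(c(1, 1), c(2, 2))),
               class = "autoflux_degenerate_error")
  expect_error(oneway_anova(list(numeric(0), 1:3)),
               class = "autoflux_validation_error")
})

test_that("one-way ANOVA p-values are uniform under the null (label shuffling)", {
  set.seed(77)
  g <- rep(1:3, each = 4)
  p <- vapply(1:2000, function(i)
    oneway_anova(stats::rnorm(12), sample(g))$p_value[1], numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Holm-Sidak reproduces the hand examples and its guarantees", {
  one <- holm_sidak(0.03)
  expect_equal(one$p_adj, 0.03)
  expect_true(one$reject)

  hs <- holm_sidak(c(0.01, 0.04))
  expect_equal(hs$p_adj, c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  expect_equal(hs$p_adj[1], 0.0199, tolerance = 1e-12)
  expect_true(all(hs$reject))

  expect_error(holm_sidak(c(0.2, 1.2)), class = "autoflux_validation_error")

  set.seed(5)
  for (i in 1:50) {
    p <- stats::runif(sample(2:8, 1))
    hs <- holm_sidak(p)
    expect_true(all(hs$p_adj >= hs$p - 1e-15))
    ord <- order(hs$p)
    expect_true(all(diff(hs$p_adj[ord]) >= -1e-15))  # monotone in sorted order
  }
})

test_that("two-way ANOVA: additivity kills the interaction; errors are classed", {
  # additive cell means + replicate noise centered within every cell, so the
  # cell means (hence the interaction) are untouched but the residual is not 0
  a <- rep(rep(c("c1", "c2"), each = 2), times = 3)
  b <- rep(c("i0", "i1"), times = 6)
  mu <- 10 + 2 * (a == "c2") + 5 * (b == "i1")
  jit <- rep(c(-1, 0, 1), each = 4)  # zero-sum across the 3 replicates per cell
  tab <- twoway_anova(mu + 0.1 * jit, a, b)
  expect_equal(tab$sumsq[tab$term == "A:B"], 0, tolerance = 1e-12)
  expect_gt(tab$sumsq[tab$term == "residual"], 0)

  # zero within-cell variance with interaction structure -> degenerate
  v <- c(0, 0, 0, 10)[match(paste(a, b), c("c1 i0", "c1 i1", "c2 i0", "c2 i1"))]
  expect_error(twoway_anova(v, a, b), class = "autoflux_degenerate_error")

  # empty cell named in the error
  err <- tryCatch(twoway_anova(stats::rnorm(6), rep(c("c1", "c2", "c2"), 2),
                               rep(c("i0", "i0", "i1"), 2),
                               names_ab = c("treat", "baf")),
                  error = function(e) e)
  expect_s3_class(err, "autoflux_validation_error")
  expect_match(conditionMessage(err), "treat")
})

test_that("two-way ANOVA matches an explicit projection-matrix computation", {
  set.seed(41)
  a <- factor(rep(c("c1", "c2"), each = 6))
  b <- factor(rep(c("i0", "i1"), times = 6))
  y <- stats::rnorm(12)
  tab <- twoway_anova(y, a, b)

  # oracle: sequential projections onto hand-built indicator bases
  proj <- function(X, y) X %*% solve(crossprod(X), crossprod(X, y))
  X1 <- cbind(rep(1, 12))
  XA <- cbind(X1, a == "c2")
  XB <- cbind(XA, b == "i1")
  XAB <- cbind(XB, (a == "c2") * (b == "i1"))
  ss <- function(Xbig, Xsmall) sum((proj(Xbig, y) - proj(Xsmall, y))^2)
  expect_equal(tab$sumsq[1], ss(XA, X1), tolerance = 1e-8)
  expect_equal(tab$sumsq[2], ss(XB, XA), tolerance = 1e-8)
  expect_equal(tab$sumsq[3], ss(XAB, XB), tolerance = 1e-8)
  expect_equal(tab$sumsq[4], sum((y - proj(XAB, y))^2), tolerance = 1e-8)
  # SS decomposition sums to total on this balanced design
  expect_equal(sum(tab$sumsq), sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("the vs-1 test holds its nominal type-I error under null draws", {
  set.seed(2024)
  n_rep <- 4000  # null: normal ratios centered at 1
  rej <- vapply(seq_len(n_rep), function(i)
    t_test_vs_one(stats::rnorm(3, 1, 0.1), "greater")$p_value < 0.05,
    logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("decision pipeline: two-condition branch emits tier-labeled tests", {
  sim <- simulate_flux(flux_preset("balanced_up", noise_cv = 0.05, seed = 12))
  fit <- flux_fit(sim$lanes)
  st <- flux_stats(fit, direction = "greater")
  expect_s3_class(st, "flux_stats")
  expect_named(st$rate_tests, c("flux:EXP+", "formation:EXP+", "degradation:EXP+"))
  tiers <- vapply(c(st$rate_tests, st$ratio_tests), `[[`, character(1), "tier")
  expect_true(all(tiers %in% c("significant", "tendency", "ns")))
  expect_length(st$ratio_tests, 3)
  expect_output(print(st), "decision pipeline")
  # direction is mandatory, never inferred
  expect_error(flux_stats(fit), class = "autoflux_config_error")
  # per-measure directions are honored
  st2 <- flux_stats(fit, direction = list(flux = "greater", formation = "greater",
                                          degradation = "greater",
                                          formation_ratio = "greater",
                                          degradation_ratio = "greater",
                                          net_ratio = "less"))
  expect_match(st2$ratio_tests$`net_ratio:EXP+`$test_name, "less")
})

test_that("decision pipeline: additive data skips the one-way branch", {
  # purely additive cell means with replicate noise centered within each
  # cell -> interaction SS is exactly 0 -> branch skipped
  set.seed(88)
  e <- matrix(stats::rnorm(12, 0, 2), 3, 4)
  e <- sweep(e, 2, colMeans(e))  # keep every cell mean exactly additive
  lanes <- do.call(rbind, lapply(1:3, function(r)
    make_lanes(c(100, 150, 120, 170) + e[r, ], replicate_id = sprintf("R%d", r))))
  fit <- suppressWarnings(flux_fit(lanes))
  st <- flux_stats(fit, direction = "greater")
  expect_false(st$interaction$significant)
  expect_null(st$one_way_by_inhibitor)
})

test_that("decision pipeline: >= 3 conditions takes the Holm-Sidak branch", {
  set.seed(55)
  lanes <- make_multidose_lanes(list(D1 = c(0.9, 0.9), D10 = c(0.5, 0.5)),
                                noise_cv = 0.08, n_replicates = 3)
  fit <- suppressWarnings(flux_fit(lanes))
  st <- flux_stats(fit, direction = "less")
  expect_false(is.null(st$posthoc))
  # vs-control family: one comparison per dose and measure
  expect_equal(nrow(st$posthoc), 2 * 3)
  expect_true(all(st$posthoc$p_adj >= st$posthoc$p - 1e-15))
  expect_false(is.null(st$ratio_posthoc))
  expect_true("anova:flux" %in% names(st$rate_tests))
})

test_that("assumption screen reports Shapiro-Wilk and Levene results", {
  set.seed(66)
  v <- stats::rnorm(24)
  g <- rep(letters[1:4], each = 6)
  sc <- assumption_screen(v, g)
  expect_equal(nrow(sc$shapiro), 4)
  expect_true(all(sc$shapiro$p_value > 0 & sc$shapiro$p_value <= 1))
  expect_false(is.null(sc$levene))
  expect_true(sc$levene$p_value > 0)
})
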