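# Shared fixture builders (all fixtures are generated in code).

# lane table for one replicate set from explicit cell values, default cell
# order EXP-/BAF-, EXP-/BAF+, EXP+/BAF-, EXP+/BAF+ (truncated to the number
# of values supplied)
make_lanes <- function(values,
                       conditions = rep(c("EXP-", "EXP-", "EXP+", "EXP+"),
                                        length.out = length(values)),
                       inhibitor = rep(c(FALSE, TRUE), length.out = length(values)),
                       replicate_id = "R1", loading = 100) {
  data.frame(replicate_id = replicate_id, condition = conditions,
             inhibitor = inhibitor, lc3ii = values * loading / 100 * 100,
             loading_control = loading, stringsAsFactors = FALSE)
}

# n-replicate lane table from per-replicate cell matrices (4 columns in the
# order EXP-/BAF-, EXP-/BAF+, EXP+/BAF-, EXP+/BAF+)
make_design_lanes <- function(cells) {
  cells <- rbind(cells)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(r)
    data.frame(replicate_id = sprintf("R%d", r),
               condition = c("EXP-", "EXP-", "EXP+", "EXP+"),
               inhibitor = c(FALSE, TRUE, FALSE, TRUE),
               lc3ii = as.numeric(cells[r, ]), loading_control = 1,
               stringsAsFactors = FALSE)))
}

# random feasible four-condition design (positive cells), for property tests
random_design_lanes <- function(n_replicates = 3) {
  cells <- t(vapply(seq_len(n_replicates), function(i) {
    pool <- stats::runif(1, 50, 500)
    b <- stats::runif(1, 5, pool)
    f <- stats::runif(1, 0, 3)
    d <- stats::runif(1, 0, (pool + f * b) / b)
    c(pool, pool + b, pool + f * b - d * b, pool + f * b) *
      stats::rlnorm(4, 0, 0.1)
  }, numeric(4)))
  make_design_lanes(cells)
}

# random feasible scenario spec
random_scenario <- function(noise_cv = 0, n_replicates = 3, seed = NULL) {
  pool <- stats::runif(1, 50, 500)
  b <- stats::runif(1, 5, pool)
  f <- stats::runif(1, 0.05, 3)
  d <- stats::runif(1, 0, (pool + f * b) / b * 0.99)
  scenario_spec(pool_ss = pool, basal_flux = b, f_mult = f, d_mult = d,
                noise_cv = noise_cv, n_replicates = n_replicates, seed = seed)
}

# multi-dose lane table: one shared control plus k treatment conditions with
# given formation/degradation multipliers and lognormal lane noise
make_multidose_lanes <- function(doses, pool = 100, b = 50, noise_cv = 0,
                                 n_replicates = 3) {
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  noisy <- function(mu) mu * if (sdlog > 0)
    stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog) else 1
  out <- list()
  for (r in seq_len(n_replicates)) {
    rows <- data.frame(condition = "EXP-", inhibitor = c(FALSE, TRUE),
                       mu = c(pool, pool + b), stringsAsFactors = FALSE)
    for (nm in names(doses)) {
      f <- doses[[nm]][1]; d <- doses[[nm]][2]
      rows <- rbind(rows, data.frame(condition = nm, inhibitor = c(FALSE, TRUE),
                                     mu = c(pool + f * b - d * b, pool + f * b)))
    }
    out[[r]] <- data.frame(replicate_id = sprintf("R%d", r),
                           condition = rows$condition, inhibitor = rows$inhibitor,
                           lc3ii = noisy(rows$mu), loading_control = 1,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# random synthetic gel layout for round-trip tests: bands >= 6 sigma apart,
# faint smooth/ramp background, noise bounded by a fraction of peak height
random_gel_case <- function(seed, noise_frac = 0.02) {
  set.seed(seed)
  n_lanes <- sample(2:4, 1)
  n_bands <- sample(2:3, 1)
  n_rows <- 160L
  sigma <- stats::runif(n_bands, 1.5, 3)
  centers <- numeric(n_bands)
  centers[1] <- stats::runif(1, 25, 45)
  for (i in seq_len(n_bands)[-1])
    centers[i] <- centers[i - 1] + 6 * max(sigma) + stats::runif(1, 5, 20)
  stopifnot(max(centers) < n_rows - 20)
  labels <- paste0("B", seq_len(n_bands))
  bands <- do.call(rbind, lapply(seq_len(n_lanes), function(l)
    data.frame(lane_id = paste0("L", l), band_label = labels,
               center = centers, sigma = sigma,
               intensity = stats::runif(n_bands, 2000, 10000),
               stringsAsFactors = FALSE)))
  lane_w <- 15L
  # faintest band's profile peak bounds the admissible noise and background
  peak_h <- min(bands$intensity * stats::dnorm(0, 0, bands$sigma))
  make_synthetic_gel(bands, dims = c(n_rows, n_lanes * lane_w),
                     background = sample(c("none", "ramp", "smooth"), 1),
                     background_height = stats::runif(1, 0, 0.01 * peak_h / lane_w),
                     noise_sd = stats::runif(1, 0, noise_frac * peak_h / lane_w),
                     seed = seed)
}

# quantify every lane of a synthetic gel with generous intervals
roundtrip_areas <- function(g, window = NULL) {
  n_rows <- nrow(g$image$pixels)
  if (is.null(window)) window <- ceiling(4 * max(g$truth$sigma))
  iv <- unique(g$truth[c("band_label", "center", "sigma")])
  rois <- data.frame(lane_id = g$lanes$lane_id, row_start = 1, row_end = n_rows,
                     col_start = g$lanes$col_start, col_end = g$lanes$col_end)
  bands <- do.call(rbind, lapply(g$lanes$lane_id, function(l)
    data.frame(lane_id = l, band_label = iv$band_label,
               start = pmax(1, floor(iv$center - 5 * iv$sigma)),
               end = pmin(n_rows, ceiling(iv$center + 5 * iv$sigma)),
               stringsAsFactors = FALSE)))
  calls <- quantify_gel(g$image, rois, bands, window = window)
  merge(calls, g$truth, by = c("lane_id", "band_label"),
        suffixes = c("_rec", "_true"))
}
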