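# Internal helpers shared across the package.

# classed conditions so callers can distinguish user errors from bugs
af_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "autoflux_error", "error")))
}
af_validation_error <- function(fmt, ...) af_stop("autoflux_validation_error", fmt, ...)
af_config_error     <- function(fmt, ...) af_stop("autoflux_config_error", fmt, ...)
af_design_error     <- function(fmt, ...) af_stop("autoflux_design_error", fmt, ...)
af_degenerate_error <- function(fmt, ...) af_stop("autoflux_degenerate_error", fmt, ...)
af_bounds_error     <- function(fmt, ...) af_stop("autoflux_bounds_error", fmt, ...)

# evaluate expr under a temporary RNG state; NULL seed leaves the stream alone
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a reproducible substream seed from a top-level seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

#' Standard error of the mean
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return `sd(x)/sqrt(n)`, or `NA` if fewer than two non-missing values.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# running min/max with a flat window of radius r (edge-truncated)
run_min <- function(x, r) {
  n <- length(x)
  vapply(seq_len(n), function(i) min(x[max(1L, i - r):min(n, i + r)]), numeric(1))
}
run_max <- function(x, r) {
  n <- length(x)
  vapply(seq_len(n), function(i) max(x[max(1L, i - r):min(n, i + r)]), numeric(1))
}

# significance tier labels used throughout the reporting layer
p_tier <- function(p, alpha = 0.05, tendency = 0.1) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < alpha, "significant",
                ifelse(p < tendency, "tendency", "ns")))
}

fmt_num <- function(x, digits = 4) trimws(formatC(x, digits = digits, format = "g"))
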