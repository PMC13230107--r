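#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set from `seed`, then
#' restores the previous stream, so seeded package functions never perturb
#' the caller's RNG state. A `NULL` seed evaluates the code in the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Quantiles by linear interpolation between order statistics (type 7),
# the convention used for every quartile and percentile in this package.
#' @noRd
q7 <- function(x, p) unname(quantile(x, p, type = 7, names = FALSE))

#' @noRd
check_lifestyle <- function(x, allow_na = TRUE) {
  bad <- !(x %in% LIFESTYLES)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    stop(sprintf(
      "unknown lifestyle label(s): %s (expected one of: %s)",
      paste(unique(x[bad]), collapse = ", "),
      paste(LIFESTYLES, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Descriptive block used for the per-lifestyle metric summaries:
# mean, SD, min, max, deciles/quartiles and IQR.
#' @noRd
describe_vector <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) {
    return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_, min = NA_real_,
                      max = NA_real_, p10 = NA_real_, p25 = NA_real_,
                      p50 = NA_real_, p75 = NA_real_, p90 = NA_real_,
                      iqr = NA_real_))
  }
  qs <- q7(x, c(0.10, 0.25, 0.50, 0.75, 0.90))
  data.frame(n = n, mean = mean(x), sd = if (n > 1L) sd(x) else NA_real_,
             min = min(x), max = max(x),
             p10 = qs[1], p25 = qs[2], p50 = qs[3], p75 = qs[4], p90 = qs[5],
             iqr = qs[4] - qs[2])
}
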