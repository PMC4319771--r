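#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm rbinom rpois runif qnorm pnorm sd var ar setNames
#' @importFrom utils head tail write.table read.table
NULL

# draw k class effects with exact sample mean 0 and exact variance sigma2
# (keeps the analytic liability variance honest even for few classes)
draw_calibrated_effects <- function(k, sigma2) {
  if (sigma2 <= 0 || k < 2) return(rep(0, k))
  x <- rnorm(k)
  x <- x - mean(x)
  x * sqrt(sigma2) / stats::sd(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) abort(sprintf("`%s` must be in %s%g, %g%s", name,
                         if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]"))
  as.numeric(x)
}
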