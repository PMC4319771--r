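#' Shortest (highest posterior density) interval of a sample
#'
#' The narrowest interval over the sorted samples that contains `prob` of
#' them. A constant chain gives a zero-width (point) interval.
#'
#' @param x Numeric sample.
#' @param prob Coverage probability, default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  assert_fraction(prob, "prob", 0, 1, open_lo = TRUE, open_hi = TRUE)
  xs <- sort(x)
  n <- length(xs)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = xs[1], upper = xs[n]))
  width <- xs[(m + 1):n] - xs[1:(n - m)]
  k <- which.min(width)
  c(lower = xs[k], upper = xs[k + m])
}

# spectral density at frequency zero via an AR fit (for ESS / Geweke)
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0 || length(x) < 10) return(v)
  fit <- tryCatch(stats::ar(x, aic = TRUE), error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Effective sample size of a chain
#'
#' @param x Numeric sample from a single chain.
#' @return Estimated number of independent draws.
#' @export
effective_size <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(length(x))
  min(length(x), length(x) * v / spectrum0_ar(x))
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` of the chain with the mean of the
#' last `frac2`, standardized by spectral variance estimates.
#'
#' @param x Numeric chain.
#' @param frac1,frac2 Fractions of the chain used for the two windows.
#' @return z statistic (approximately N(0,1) under convergence).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  x1 <- x[seq_len(max(2, floor(frac1 * n)))]
  x2 <- x[seq(n - max(2, floor(frac2 * n)) + 1, n)]
  se2 <- spectrum0_ar(x1) / length(x1) + spectrum0_ar(x2) / length(x2)
  if (se2 == 0) return(0)
  (mean(x1) - mean(x2)) / sqrt(se2)
}

#' Posterior summary table of a fitted chain
#'
#' Posterior mean, SD, 95% highest-density interval, Geweke z and effective
#' sample size for the variance components, the heritability and (optionally)
#' every location effect.
#'
#' @param fit A `threshold_fit`.
#' @param prob HPD coverage, default 0.95.
#' @param include_location Also summarize fixed, herd-year and sire effects.
#' @return Tibble `term`, `mean`, `sd`, `hpd_lower`, `hpd_upper`,
#'   `geweke_z`, `ess`.
#' @export
summarize_chain <- function(fit, prob = 0.95, include_location = FALSE) {
  stopifnot(inherits(fit, "threshold_fit"))
  if (nrow(fit$samples) < 100) {
    abort("at least 100 retained samples are required for posterior summaries")
  }
  cols <- list(sigma2_s = fit$samples$sigma2_s,
               sigma2_h = fit$samples$sigma2_h,
               sigma2_e = fit$samples$sigma2_e,
               h2 = fit$samples$h2)
  if (include_location) {
    for (j in colnames(fit$location)) cols[[j]] <- fit$location[, j]
  }
  purrr::map_dfr(names(cols), function(nm) {
    x <- cols[[nm]]
    hpd <- hpd_interval(x, prob)
    tibble::tibble(term = nm, mean = mean(x), sd = stats::sd(x),
                   hpd_lower = hpd[["lower"]], hpd_upper = hpd[["upper"]],
                   geweke_z = geweke_z(x), ess = effective_size(x))
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a threshold-model fit
#'
#' @param x A `threshold_fit`.
#' @param prob HPD interval coverage.
#' @param include_location Include location-effect terms.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` (HPD bounds).
#' @export
tidy.threshold_fit <- function(x, prob = 0.95, include_location = FALSE, ...) {
  s <- summarize_chain(x, prob = prob, include_location = include_location)
  tibble::tibble(term = s$term, estimate = s$mean, std.error = s$sd,
                 conf.low = s$hpd_lower, conf.high = s$hpd_upper)
}

#' One-row model overview of a threshold-model fit
#'
#' @param x A `threshold_fit`.
#' @param ... Unused.
#' @return One-row tibble: record/animal counts, chain settings and the
#'   posterior means of the variance components and heritability.
#' @export
glance.threshold_fit <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    n_animals = length(x$animal_ids),
    n_herd_years = length(x$hy_levels),
    n_iterations = x$config$n_iterations,
    burn_in = x$config$burn_in,
    thin = x$config$thin,
    n_retained = nrow(x$samples),
    sigma2_s = mean(x$samples$sigma2_s),
    sigma2_h = mean(x$samples$sigma2_h),
    sigma2_e = 1,
    h2 = mean(x$samples$h2)
  )
}

#' Trace plots for the variance components and heritability
#'
#' @param object A `threshold_fit`.
#' @param ... Unused.
#' @return A ggplot with one facet per parameter.
#' @export
autoplot.threshold_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$samples,
                            cols = c("sigma2_h", "sigma2_s", "h2"),
                            names_to = "parameter", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
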