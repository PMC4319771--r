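#' Gibbs sampler settings
#'
#' Defaults match routine practice for threshold-model variance component
#' estimation in national dairy evaluations: 120,000 iterations with 20,000
#' burn-in, keeping every 10th sample. Variance priors are scaled inverse
#' chi-square with `nu = -2`, `S = 0`, i.e. improper flat priors on the
#' variances.
#'
#' @param n_iterations Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before retention; must be < `n_iterations`.
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param seed Integer seed for the chain.
#' @param nu_h,S_h Prior degrees of freedom and scale for the herd-year
#'   variance.
#' @param nu_s,S_s Prior degrees of freedom and scale for the sire variance.
#' @param start_sigma2_h,start_sigma2_s Chain starting values.
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(n_iterations = 120000L, burn_in = 20000L, thin = 10L,
                         seed = 1L, nu_h = -2, S_h = 0, nu_s = -2, S_s = 0,
                         start_sigma2_h = 0.5, start_sigma2_s = 0.05) {
  n_iterations <- assert_count(n_iterations, "n_iterations")
  burn_in <- assert_count(burn_in, "burn_in", min = 0L)
  thin <- assert_count(thin, "thin")
  if (burn_in >= n_iterations) abort("`burn_in` must be smaller than `n_iterations`")
  if ((n_iterations - burn_in) < thin) abort("no samples would be retained")
  structure(list(n_iterations = n_iterations, burn_in = burn_in, thin = thin,
                 seed = assert_count(seed, "seed", min = 0L),
                 nu_h = nu_h, S_h = S_h, nu_s = nu_s, S_s = S_s,
                 start_sigma2_h = start_sigma2_h, start_sigma2_s = start_sigma2_s),
            class = "gibbs_config")
}

#' Fit the threshold-liability sire model by Gibbs sampling
#'
#' Data augmentation on the record liabilities (truncated-normal draws with
#' the sign fixed by the observed 0/1 outcome, threshold at 0, residual
#' variance fixed at 1), blocked Gaussian updates for the location effects
#' (fixed effects, herd-years, sires), and scaled-inverse-chi-square full
#' conditionals for the herd-year and sire variances, the sire one using
#' `s' H^-1 s`. Heritability on the liability scale,
#' `h2 = 4 sigma2_s / (sigma2_s + sigma2_h + sigma2_e)`, is computed per
#' retained sample.
#'
#' @param frame A [build_model_frame()] result.
#' @param Hinv Relationship matrix inverse over `frame$animal_ids` (from
#'   [build_H_inverse()] or [build_A_inverse()] for a pedigree-only run).
#' @param config A [gibbs_config()].
#' @param gaussian If `TRUE`, treat `lambda_obs` as observed Gaussian data
#'   (no truncation; residual variance still 1, variances still fixed at
#'   their starting values). Used to check the sampler against mixed-model
#'   equations; not part of the analysis path.
#' @param lambda_obs Observed liabilities for `gaussian = TRUE`.
#' @return A `threshold_fit` object: `$samples` tibble (`iteration`,
#'   `sigma2_h`, `sigma2_s`, `sigma2_e`, `h2`), `$location` matrix of
#'   retained location samples (columns named), plus the frame levels and
#'   config.
#' @export
gibbs_fit <- function(frame, Hinv, config = gibbs_config(),
                      gaussian = FALSE, lambda_obs = NULL) {
  stopifnot(inherits(frame, "model_frame"), inherits(config, "gibbs_config"))
  ids <- frame$animal_ids
  if (is.null(rownames(Hinv)) || !all(ids %in% rownames(Hinv))) {
    abort("Hinv must carry dimnames covering all pedigree animals of the frame")
  }
  Hd <- as.matrix(Hinv)[ids, ids, drop = FALSE]

  if (!gaussian) {
    if (all(frame$y == 0L) || all(frame$y == 1L)) {
      abort("all records share the same outcome; the threshold is unidentifiable")
    }
    lambda_obs <- numeric(frame$n_records)
  } else {
    stopifnot(length(lambda_obs) == frame$n_records)
  }

  set.seed(config$seed)
  out <- .gibbs_core(frame$X, frame$herd_index, frame$sire_index, Hd,
                     frame$y, as.numeric(lambda_obs), gaussian,
                     config$n_iterations, config$burn_in, config$thin,
                     config$nu_h, config$S_h, config$nu_s, config$S_s,
                     config$start_sigma2_h, config$start_sigma2_s)

  nkeep <- out$n_kept
  iter <- config$burn_in + config$thin * seq_len(nkeep)
  samples <- tibble::tibble(
    iteration = iter,
    sigma2_h = out$var_samples[, 1],
    sigma2_s = out$var_samples[, 2],
    sigma2_e = 1,
    h2 = out$var_samples[, 3]
  )
  loc <- out$loc_samples
  colnames(loc) <- c(colnames(frame$X),
                     paste0("herd_year:", frame$hy_levels),
                     paste0("sire:", ids))
  structure(list(samples = samples, location = loc,
                 animal_ids = ids, hy_levels = frame$hy_levels,
                 ys_levels = frame$ys_levels, n_records = frame$n_records,
                 config = config, gaussian = gaussian),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> %d records, %d pedigree animals, %d retained samples\n",
              x$n_records, length(x$animal_ids), nrow(x$samples)))
  cat(sprintf("  posterior means: sigma2_s = %.4f, sigma2_h = %.4f, h2 = %.4f (sigma2_e fixed at 1)\n",
              mean(x$samples$sigma2_s), mean(x$samples$sigma2_h), mean(x$samples$h2)))
  invisible(x)
}

#' Posterior means of the genetic (sire) solutions
#'
#' @param fit A `threshold_fit`.
#' @param ids Optional subset of animal IDs (e.g. the genotyped sires whose
#'   solutions are back-solved into marker effects).
#' @return Tibble `animal`, `estimate` (posterior mean), `sd` (posterior SD).
#' @export
sire_solutions <- function(fit, ids = NULL) {
  stopifnot(inherits(fit, "threshold_fit"))
  ids <- ids %||% fit$animal_ids
  if (!all(ids %in% fit$animal_ids)) abort("unknown animal IDs requested")
  cols <- paste0("sire:", ids)
  sub <- fit$location[, cols, drop = FALSE]
  tibble::tibble(animal = ids,
                 estimate = colMeans(sub),
                 sd = apply(sub, 2, stats::sd))
}

#' Liability-scale heritability from sire-model variance components
#'
#' `h2 = 4 sigma2_s / (sigma2_s + sigma2_h + sigma2_e)`: the sire variance is
#' one quarter of the additive genetic variance, so multiplying by 4 puts the
#' ratio on the usual narrow-sense scale. Vectorized over its arguments.
#'
#' @param sigma2_s Sire variance(s).
#' @param sigma2_h Herd-year variance(s).
#' @param sigma2_e Residual variance(s); 1 under the threshold model.
#' @return Numeric heritability value(s).
#' @examples
#' heritability_from_components(0.037, 0.496, 1)
#' @export
heritability_from_components <- function(sigma2_s, sigma2_h, sigma2_e = 1) {
  denom <- sigma2_s + sigma2_h + sigma2_e
  if (any(denom <= 0)) abort("total variance must be positive")
  4 * sigma2_s / denom
}
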