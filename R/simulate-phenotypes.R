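#' Simulate binary phenotypes from a liability sire model
#'
#' Inverts the analysis model: each daughter's liability is the sum of a
#' year-season effect, a herd-year effect, half her sire's breeding value
#' (the transmitting ability — the sire-model genetic effect, with variance
#' `sigma2_s = sigma2_a / 4`) and a residual `N(0, sigma2_e)`. Breeding
#' values are the sum of QTL effects carried by the simulated genotypes plus
#' a polygenic remainder dropped through the pedigree. The case/control
#' outcome is `y = 1` iff the liability exceeds a threshold set at the
#' `(1 - incidence)` quantile of the *analytic* marginal liability
#' distribution, so incidence stays a parameter rather than an artifact of
#' the realized sample. Year-season and herd-year class effects are drawn
#' normal and then standardized to exact mean 0 / exact variance, keeping the
#' analytic threshold honest even with few classes.
#'
#' @param ped Pedigree from [simulate_pedigree()].
#' @param panel Marker panel from [simulate_genotypes()] covering the QTL
#'   carriers (all pedigree animals).
#' @param config A [sim_config()].
#' @return A list with
#'   \describe{
#'     \item{phenotypes}{tibble `animal`, `sire`, `herd_year`, `year_season`,
#'       `y` (0/1), `liability` — one row per daughter;}
#'     \item{truth}{list with `qtl_markers`, `qtl_indices`, `qtl_effects`,
#'       `true_breeding_values` (named, all animals), `sire_effects`
#'       (half the breeding value), `liability_threshold`, and the variance
#'       components used — ground truth for parameter-recovery tests.}
#'   }
#' @export
simulate_phenotypes <- function(ped, panel, config) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "marker_panel"))
  validate_pedigree(ped)
  if (!all(ped$animal %in% rownames(panel$genotypes))) {
    abort("panel must contain genotypes for every pedigree animal")
  }
  set.seed(config$seed + 2L)

  m <- ncol(panel$genotypes)
  sigma2_a <- 4 * config$sigma2_s
  p_true <- panel$map$founder_freq %||% panel$freq

  # QTL component of the breeding values
  qtl_idx <- integer(0); alpha <- numeric(0)
  qtl_var <- config$qtl_variance_fraction * sigma2_a
  if (config$n_qtl > 0 && qtl_var > 0) {
    qtl_idx <- sort(sample.int(m, config$n_qtl))
    alpha <- rnorm(config$n_qtl)
    raw <- sum(2 * p_true[qtl_idx] * (1 - p_true[qtl_idx]) * alpha^2)
    alpha <- alpha * sqrt(qtl_var / raw)
  }
  g_ord <- panel$genotypes[ped$animal, , drop = FALSE]
  if (length(qtl_idx)) {
    gq <- g_ord[, qtl_idx, drop = FALSE]
    if (anyNA(gq)) {
      mu <- rep(2 * p_true[qtl_idx], each = nrow(gq))
      gq[is.na(gq)] <- mu[is.na(gq)]
    }
    storage.mode(gq) <- "double"
    bv_qtl <- drop(sweep(gq, 2, 2 * p_true[qtl_idx]) %*% alpha)
  } else {
    bv_qtl <- numeric(nrow(ped))
  }

  # polygenic remainder dropped through the pedigree
  sigma2_pg <- sigma2_a - qtl_var
  n <- nrow(ped)
  sire_idx <- match(ped$sire, ped$animal)
  dam_idx <- match(ped$dam, ped$animal)
  pg <- numeric(n)
  if (sigma2_pg > 0) {
    founder <- is.na(sire_idx) & is.na(dam_idx)
    pg[founder] <- rnorm(sum(founder), 0, sqrt(sigma2_pg))
    ms <- rnorm(n, 0, sqrt(0.5 * sigma2_pg))
    for (i in which(!founder)) {
      ps <- if (is.na(sire_idx[i])) 0 else pg[sire_idx[i]]
      pd <- if (is.na(dam_idx[i])) 0 else pg[dam_idx[i]]
      pg[i] <- 0.5 * (ps + pd) + ms[i]
    }
  }
  bv <- setNames(bv_qtl + pg, ped$animal)

  # records: one per daughter
  dau <- which((ped$role %||% "daughter") == "daughter" & !is.na(ped$sire))
  if (!length(dau)) abort("pedigree contains no daughters with a known sire")
  nrec <- length(dau)

  hy_eff <- draw_calibrated_effects(config$n_herds, config$sigma2_h)
  ys_eff <- draw_calibrated_effects(config$n_year_seasons, config$sigma2_ys)
  hy <- sample.int(config$n_herds, nrec, replace = TRUE)
  ys <- sample.int(config$n_year_seasons, nrec, replace = TRUE)

  sire_effect <- 0.5 * bv
  lambda <- ys_eff[ys] + hy_eff[hy] + sire_effect[ped$sire[dau]] +
    rnorm(nrec, 0, sqrt(config$sigma2_e))

  # threshold from the analytic marginal distribution: year-season effects
  # are fixed effects, so the marginal is an equal-weight mixture of normals
  # over the year-season classes; the remaining components are normal
  sd_rest <- sqrt(config$sigma2_h + config$sigma2_s + config$sigma2_e)
  marg_p <- function(t) mean(pnorm(t, mean = ys_eff, sd = sd_rest))
  lim <- 8 * sqrt(config$sigma2_ys + sd_rest^2)
  threshold <- stats::uniroot(function(t) marg_p(t) - (1 - config$incidence),
                              lower = -lim, upper = lim, tol = 1e-12)$root

  phen <- tibble::tibble(
    animal = ped$animal[dau],
    sire = ped$sire[dau],
    herd_year = sprintf("HY%04d", hy),
    year_season = sprintf("YS%02d", ys),
    y = as.integer(lambda > threshold),
    liability = lambda
  )
  truth <- list(
    qtl_markers = panel$map$marker[qtl_idx],
    qtl_indices = qtl_idx,
    qtl_effects = alpha,
    true_breeding_values = bv,
    sire_effects = sire_effect,
    liability_threshold = threshold,
    sigma2_s = config$sigma2_s,
    sigma2_h = config$sigma2_h,
    sigma2_ys = config$sigma2_ys,
    sigma2_e = config$sigma2_e,
    incidence = config$incidence
  )
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete study: pedigree, genotypes and phenotypes
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return A list `pedigree`, `panel`, `phenotypes`, `truth`.
#' @examples
#' study <- simulate_study(sim_config(n_founder_sires = 5, n_generations = 1,
#'                                    daughters_per_sire = 4,
#'                                    n_chromosomes = 2,
#'                                    markers_per_chromosome = 10))
#' mean(study$phenotypes$y)
#' @export
simulate_study <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  panel <- simulate_genotypes(ped, config)
  sim <- simulate_phenotypes(ped, panel, config)
  list(pedigree = ped, panel = panel,
       phenotypes = sim$phenotypes, truth = sim$truth)
}
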