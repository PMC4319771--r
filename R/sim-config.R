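#' Simulation settings for the synthetic daughter-design population
#'
#' Defines the pedigree layout, marker panel, trait architecture and
#' liability-scale variance components used by [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_phenotypes()]. The defaults emulate a
#' US dairy daughter design: genotyped AI sires, ~10 recorded daughters per
#' sire, a binary health trait with low sire variance (0.037), large herd-year
#' variance (0.496), residual variance fixed at 1 on the liability scale, and
#' a disease incidence of 10.91%.
#'
#' @param n_founder_sires Number of unrelated founder sires (generation 0).
#' @param n_generations Number of daughter generations. For generations after
#'   the first, each sire line is continued by a son out of a new founder dam.
#' @param daughters_per_sire Recorded daughters per sire and generation.
#' @param n_herds Number of herd-year classes phenotypes are scattered over.
#' @param n_year_seasons Number of year-season (fixed effect) classes.
#' @param n_chromosomes Autosome count of the simulated genome.
#' @param markers_per_chromosome SNPs per chromosome, placed at sorted uniform
#'   base-pair positions.
#' @param n_qtl Number of markers carrying true additive effects.
#' @param founder_maf_low,founder_maf_high Bounds of the uniform distribution
#'   the founder allele frequencies are drawn from; both in (0, 0.5].
#' @param morgans_per_chromosome Genetic length of each chromosome (Morgans);
#'   crossovers per meiosis are Poisson with this mean, positions uniform.
#' @param bp_per_chromosome Physical length of each chromosome in base pairs.
#' @param sigma2_s Sire variance on the liability scale (one quarter of the
#'   additive genetic variance).
#' @param sigma2_h Herd-year variance on the liability scale.
#' @param sigma2_ys Variance of the year-season class effects (treated as
#'   fixed effects by the analysis model, but drawn here).
#' @param sigma2_e Residual liability variance; fixed at 1 by the threshold
#'   model and kept at 1 here.
#' @param incidence Target marginal case fraction, in (0, 1).
#' @param qtl_variance_fraction Fraction of the additive variance explained by
#'   the QTL; the remainder is a polygenic term dropped through the pedigree.
#' @param genotype_dropout Probability that an individual genotype call is
#'   set missing (exercises the call-rate QC); 0 disables.
#' @param seed Integer seed; identical seeds give identical simulations.
#'
#' @return A `sim_config` list with validated fields.
#' @examples
#' cfg <- sim_config(n_founder_sires = 10, n_generations = 1,
#'                   daughters_per_sire = 5, seed = 42)
#' cfg$sigma2_s
#' @export
sim_config <- function(n_founder_sires = 100L,
                       n_generations = 3L,
                       daughters_per_sire = 10L,
                       n_herds = 100L,
                       n_year_seasons = 4L,
                       n_chromosomes = 29L,
                       markers_per_chromosome = 40L,
                       n_qtl = 30L,
                       founder_maf_low = 0.05,
                       founder_maf_high = 0.5,
                       morgans_per_chromosome = 1,
                       bp_per_chromosome = 1e8,
                       sigma2_s = 0.037,
                       sigma2_h = 0.496,
                       sigma2_ys = 0.05,
                       sigma2_e = 1,
                       incidence = 0.1091,
                       qtl_variance_fraction = 0.5,
                       genotype_dropout = 0,
                       seed = 1L) {
  cfg <- list(
    n_founder_sires = assert_count(n_founder_sires, "n_founder_sires"),
    n_generations = assert_count(n_generations, "n_generations"),
    daughters_per_sire = assert_count(daughters_per_sire, "daughters_per_sire"),
    n_herds = assert_count(n_herds, "n_herds"),
    n_year_seasons = assert_count(n_year_seasons, "n_year_seasons"),
    n_chromosomes = assert_count(n_chromosomes, "n_chromosomes"),
    markers_per_chromosome = assert_count(markers_per_chromosome, "markers_per_chromosome"),
    n_qtl = assert_count(n_qtl, "n_qtl", min = 0L),
    founder_maf_low = assert_fraction(founder_maf_low, "founder_maf_low", 0, 0.5, open_lo = TRUE),
    founder_maf_high = assert_fraction(founder_maf_high, "founder_maf_high", 0, 0.5, open_lo = TRUE),
    morgans_per_chromosome = assert_fraction(morgans_per_chromosome, "morgans_per_chromosome", 0, Inf),
    bp_per_chromosome = assert_count(bp_per_chromosome, "bp_per_chromosome"),
    sigma2_s = assert_fraction(sigma2_s, "sigma2_s", 0, Inf),
    sigma2_h = assert_fraction(sigma2_h, "sigma2_h", 0, Inf),
    sigma2_ys = assert_fraction(sigma2_ys, "sigma2_ys", 0, Inf),
    sigma2_e = assert_fraction(sigma2_e, "sigma2_e", 0, Inf, open_lo = TRUE),
    incidence = assert_fraction(incidence, "incidence", 0, 1, open_lo = TRUE, open_hi = TRUE),
    qtl_variance_fraction = assert_fraction(qtl_variance_fraction, "qtl_variance_fraction", 0, 1),
    genotype_dropout = assert_fraction(genotype_dropout, "genotype_dropout", 0, 1, open_hi = TRUE),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$founder_maf_low > cfg$founder_maf_high) {
    abort("`founder_maf_low` must not exceed `founder_maf_high`")
  }
  if (cfg$n_qtl > cfg$n_chromosomes * cfg$markers_per_chromosome) {
    abort("`n_qtl` exceeds the number of markers on the genome")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n_d <- x$n_founder_sires * x$n_generations * x$daughters_per_sire
  cat("<sim_config>\n")
  cat(sprintf("  pedigree: %d founder sires x %d generation(s) x %d daughters (= %d records)\n",
              x$n_founder_sires, x$n_generations, x$daughters_per_sire, n_d))
  cat(sprintf("  genome:   %d chromosomes x %d SNPs, %d QTL\n",
              x$n_chromosomes, x$markers_per_chromosome, x$n_qtl))
  cat(sprintf("  liability: sigma2_s = %.3f, sigma2_h = %.3f, sigma2_e = %.3f, incidence = %.2f%%\n",
              x$sigma2_s, x$sigma2_h, x$sigma2_e, 100 * x$incidence))
  invisible(x)
}
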