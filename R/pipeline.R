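#' Configuration for an end-to-end association run
#'
#' Either a simulation block (`sim`) or the three real-input paths
#' (`pedigree_file`, `genotype_prefix`, `phenotype_file`) must be supplied —
#' not both. The run `seed` re-seeds both the simulator and the Gibbs chain
#' so a full run is reproducible from one integer.
#'
#' @param sim A [sim_config()], or `NULL` when reading real files.
#' @param pedigree_file,phenotype_file CSV paths (see [read_pedigree()],
#'   [read_phenotypes()]).
#' @param genotype_prefix PLINK prefix for [read_plink()].
#' @param qc A [qc_thresholds()].
#' @param gibbs A [gibbs_config()].
#' @param n_rounds Re-weighting rounds (default 4).
#' @param window_size SNPs per window (default 10).
#' @param n_top Windows reported in the top table (default 10).
#' @param alpha Blending fraction for G (default 0.05).
#' @param ag_scale Multiplier applied to the sire solutions before
#'   back-solving (e.g. 2 to move from transmitting ability to EBV scale);
#'   window shares are invariant to it.
#' @param output_dir Directory for TSV/JSON/PNG outputs.
#' @param seed Master seed for the run.
#' @param verbose Print stage banners.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       pedigree_file = NULL, genotype_prefix = NULL,
                       phenotype_file = NULL,
                       qc = qc_thresholds(), gibbs = gibbs_config(),
                       n_rounds = 4L, window_size = 10L, n_top = 10L,
                       alpha = 0.05, ag_scale = 1,
                       output_dir = tempfile("liabilityscan-"),
                       seed = 1L, verbose = TRUE) {
  files <- c(pedigree_file, genotype_prefix, phenotype_file)
  if (!is.null(sim) && length(files) > 0) {
    abort("supply either a simulation block or real input paths, not both")
  }
  if (is.null(sim) &&
      (is.null(pedigree_file) || is.null(genotype_prefix) || is.null(phenotype_file))) {
    abort("real-input mode needs pedigree_file, genotype_prefix and phenotype_file")
  }
  seed <- assert_count(seed, "seed", min = 0L)
  if (!is.null(sim)) sim$seed <- seed
  gibbs$seed <- seed + 1L
  structure(list(sim = sim, pedigree_file = pedigree_file,
                 genotype_prefix = genotype_prefix, phenotype_file = phenotype_file,
                 qc = qc, gibbs = gibbs,
                 n_rounds = assert_count(n_rounds, "n_rounds"),
                 window_size = assert_count(window_size, "window_size"),
                 n_top = assert_count(n_top, "n_top"),
                 alpha = assert_fraction(alpha, "alpha", 0, 1, open_hi = TRUE),
                 ag_scale = ag_scale,
                 output_dir = output_dir, seed = seed, verbose = verbose),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), c("output_dir", "verbose"))], tmp,
          version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full association pipeline
#'
#' simulate (or read) -> QC -> relationship matrices -> threshold-model
#' Gibbs fit -> back-solved marker effects with iterative G re-weighting ->
#' window variance partition and ranking -> report files. All stages derive
#' their randomness from the run seed, so two runs with the same config give
#' identical outputs.
#'
#' Outputs written to `config$output_dir`: `posterior_summary.tsv`/`.json`,
#' `effects.tsv` (all rounds), `windows.tsv`, `top_windows.tsv`,
#' `manhattan.tsv` (+ `.png`), `qc_report.tsv` and `manifest.json`.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list: `fit`, `posterior`, `effects`,
#'   `windows`, `top_windows`, `qc_report`, `manifest`, `paths`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # ---- inputs ----
  inputs <- stage("input", {
    if (!is.null(config$sim)) {
      say("[simulate] seed %d: generating pedigree, genotypes, phenotypes", config$seed)
      simulate_study(config$sim)
    } else {
      say("[read] loading pedigree, genotypes, phenotypes")
      list(pedigree = read_pedigree(config$pedigree_file),
           panel = read_plink(config$genotype_prefix),
           phenotypes = read_phenotypes(config$phenotype_file),
           truth = NULL)
    }
  })
  ped <- inputs$pedigree; phen <- inputs$phenotypes
  say("[input] %d pedigree animals, %d phenotype records, %d markers",
      nrow(ped), nrow(phen), ncol(inputs$panel$genotypes))

  # ---- QC ----
  qc_out <- stage("qc", {
    cand <- intersect(unique(phen$sire), rownames(inputs$panel$genotypes))
    if (!length(cand)) abort("no phenotyped sire has genotypes")
    apply_qc(subset_panel(inputs$panel, individuals = cand), phen, config$qc)
  })
  panel <- qc_out$panel
  gids <- rownames(panel$genotypes)
  say("[qc] %d genotyped sires and %d markers survive editing",
      length(gids), ncol(panel$genotypes))

  # ---- relationship matrices ----
  rel <- stage("relmat", {
    ped_s <- prune_pedigree(ped, union(unique(phen$sire), gids))
    Ainv <- build_A_inverse(ped_s)
    if (length(gids)) {
      A22 <- pedigree_A_submatrix(ped_s, gids)
      G <- build_G(panel)
      G_star <- blend_G(G, A22, config$alpha)
      Hinv <- build_H_inverse(Ainv, G_star, A22)
    } else {
      A22 <- NULL; Hinv <- Ainv
      attr(Hinv, "genotyped") <- character(0)
    }
    list(ped_s = ped_s, Ainv = Ainv, A22 = A22, Hinv = Hinv)
  })
  say("[relmat] sire pedigree has %d animals (%d genotyped)",
      nrow(rel$ped_s), length(gids))

  # ---- threshold-model fit ----
  fit <- stage("fit", {
    frame <- build_model_frame(phen, rel$ped_s)
    gibbs_fit(frame, rel$Hinv, config$gibbs)
  })
  posterior <- summarize_chain(fit)
  say("[fit] posterior means: sigma2_s = %.4f, sigma2_h = %.4f, h2 = %.4f",
      posterior$mean[posterior$term == "sigma2_s"],
      posterior$mean[posterior$term == "sigma2_h"],
      posterior$mean[posterior$term == "h2"])

  # ---- marker effects and windows ----
  snp <- stage("snp_effects", {
    a_g <- setNames(sire_solutions(fit, gids)$estimate * config$ag_scale, gids)
    effects <- iterate_reweighting(panel, a_g, n_rounds = config$n_rounds,
                                   A22 = rel$A22, alpha = config$alpha)
    final <- effects[effects$iteration == config$n_rounds, ]
    windows <- window_variance(final, config$window_size)
    list(effects = effects, windows = windows,
         top = top_windows(windows, config$n_top))
  })
  say("[snp_effects] %d windows; top-%d windows absorb %.2f%% of the variance",
      nrow(snp$windows), nrow(snp$top), 100 * sum(snp$top$variance_share))

  # ---- report ----
  paths <- stage("report", {
    od <- config$output_dir
    wtsv <- function(df, name) {
      p <- file.path(od, name)
      utils::write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    }
    p1 <- wtsv(posterior, "posterior_summary.tsv")
    jsonlite::write_json(posterior, file.path(od, "posterior_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    p2 <- wtsv(snp$effects, "effects.tsv")
    p3 <- wtsv(snp$windows, "windows.tsv")
    p4 <- wtsv(snp$top, "top_windows.tsv")
    render_manhattan(snp$windows, file.path(od, "manhattan"))
    p6 <- wtsv(qc_out$report$counts, "qc_report.tsv")
    c(posterior_summary = p1, posterior_json = file.path(od, "posterior_summary.json"),
      effects = p2, windows = p3, top_windows = p4,
      manhattan = file.path(od, "manhattan.tsv"), qc_report = p6)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("liabilityscan")),
    seed = config$seed,
    config_hash = config_hash(config),
    counts = list(
      pedigree_animals = nrow(ped),
      phenotype_records = nrow(phen),
      markers_in = ncol(inputs$panel$genotypes),
      markers_analyzed = ncol(panel$genotypes),
      genotyped_sires = length(gids),
      sire_pedigree_animals = nrow(rel$ped_s),
      retained_samples = nrow(fit$samples),
      windows = nrow(snp$windows)
    ),
    outputs = as.list(tools::md5sum(unname(paths)))
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] outputs in %s", config$output_dir)

  structure(list(fit = fit, posterior = posterior, effects = snp$effects,
                 windows = snp$windows, top_windows = snp$top,
                 qc_report = qc_out$report, manifest = manifest,
                 paths = paths, truth = inputs$truth),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d records, %d analyzed markers, %d windows\n",
              x$manifest$counts$phenotype_records,
              x$manifest$counts$markers_analyzed, x$manifest$counts$windows))
  cat(sprintf("  h2 posterior mean: %.4f | top-%d window share: %.3f\n",
              x$posterior$mean[x$posterior$term == "h2"], nrow(x$top_windows),
              sum(x$top_windows$variance_share)))
  invisible(x)
}
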