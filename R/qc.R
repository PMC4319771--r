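#' Editing thresholds for markers, genotyped individuals and records
#'
#' Defaults follow the editing rules of chip-based dairy evaluations: markers
#' and genotyped individuals with call rate below 99% are removed, as are
#' monomorphic markers, markers with minor allele frequency below 0.05 and
#' non-autosomal markers; genotyped sires need at least 5 phenotyped
#' daughters to stay in the genotyped set. "Below" is strict: a marker with
#' MAF exactly 0.05, or a sire with exactly 5 daughters, is kept.
#'
#' @param min_call_rate Minimum fraction of non-missing calls (markers and
#'   individuals).
#' @param min_maf Minimum minor allele frequency.
#' @param autosomes Admissible chromosome labels (character).
#' @param min_phenotyped_daughters Minimum phenotyped daughters for a
#'   genotyped sire to remain genotyped (he stays in the pedigree regardless).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_call_rate = 0.99,
                          min_maf = 0.05,
                          autosomes = as.character(1:29),
                          min_phenotyped_daughters = 5L) {
  structure(list(
    min_call_rate = assert_fraction(min_call_rate, "min_call_rate", 0, 1, open_lo = TRUE),
    min_maf = assert_fraction(min_maf, "min_maf", 0, 0.5),
    autosomes = as.character(autosomes),
    min_phenotyped_daughters = assert_count(min_phenotyped_daughters,
                                            "min_phenotyped_daughters", min = 0L)
  ), class = "qc_thresholds")
}

new_qc_report <- function(counts, surviving_markers, surviving_individuals) {
  structure(list(counts = counts,
                 surviving_markers = surviving_markers,
                 surviving_individuals = surviving_individuals),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  print(x$counts)
  cat(sprintf("  surviving: %d markers, %d genotyped individuals\n",
              length(x$surviving_markers), length(x$surviving_individuals)))
  invisible(x)
}

#' Filter markers by call rate, polymorphism, MAF and chromosome
#'
#' Rules are applied in a documented order — marker call rate, then
#' monomorphic/MAF (frequencies computed on the panel as passed in, i.e.
#' after any individual edits), then autosome membership — and each count in
#' the report refers to markers removed by that rule among the survivors of
#' the previous ones. Order is preserved for surviving markers.
#'
#' @param panel A [marker_panel()].
#' @param thresholds A [qc_thresholds()].
#' @return A list `panel` (filtered) and `report` (a `qc_report`).
#' @export
filter_markers <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "marker_panel"), inherits(thresholds, "qc_thresholds"))
  markers <- panel$map$marker
  keep <- rep(TRUE, length(markers))

  cr <- call_rate(panel, "marker")
  fail_cr <- keep & cr < thresholds$min_call_rate
  keep <- keep & !fail_cr

  # frequencies from the currently analyzed set
  sub <- subset_panel(panel, markers = which(keep))
  maf <- minor_allele_freq(sub)
  fail_mono <- maf == 0
  fail_maf <- !fail_mono & maf < thresholds$min_maf
  rm_mono <- sum(fail_mono); rm_maf <- sum(fail_maf)
  idx <- which(keep)
  keep[idx[fail_mono | fail_maf]] <- FALSE

  fail_auto <- keep & !(panel$map$chromosome %in% thresholds$autosomes)
  keep <- keep & !fail_auto

  if (!any(keep)) abort("no markers survive QC")
  out <- subset_panel(panel, markers = which(keep))
  counts <- tibble::tibble(
    category = "marker",
    rule = c("call_rate", "monomorphic", "maf", "non_autosomal"),
    n_removed = c(sum(fail_cr), rm_mono, rm_maf, sum(fail_auto))
  )
  list(panel = out,
       report = new_qc_report(counts, out$map$marker, rownames(out$genotypes)))
}

#' Filter genotyped individuals by call rate and daughter count
#'
#' Genotyped individuals with call rate below `min_call_rate` are removed;
#' genotyped sires with fewer than `min_phenotyped_daughters` phenotyped
#' daughters are dropped from the genotyped set (they remain in the
#' pedigree). Individuals in the panel that never appear as sires in the
#' phenotype table are treated as having 0 phenotyped daughters.
#'
#' @param panel A [marker_panel()] restricted to the genotyped candidates.
#' @param phenotypes Tibble with at least `sire` per record.
#' @param thresholds A [qc_thresholds()].
#' @return A list `panel` and `report`. An empty surviving set is legal (the
#'   evaluation degrades to pedigree-only) and returns a 0-row panel.
#' @export
filter_individuals <- function(panel, phenotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "marker_panel"), is.data.frame(phenotypes),
            "sire" %in% names(phenotypes))
  ids <- rownames(panel$genotypes)

  cr <- call_rate(panel, "individual")
  fail_cr <- cr < thresholds$min_call_rate

  ndau <- table(phenotypes$sire)
  n_of <- function(id) if (id %in% names(ndau)) as.integer(ndau[[id]]) else 0L
  daughters <- vapply(ids, n_of, integer(1))
  fail_dau <- !fail_cr & daughters < thresholds$min_phenotyped_daughters

  keep <- !(fail_cr | fail_dau)
  out <- subset_panel(panel, individuals = which(keep))
  counts <- tibble::tibble(
    category = "individual",
    rule = c("call_rate", "few_phenotyped_daughters"),
    n_removed = c(sum(fail_cr), sum(fail_dau))
  )
  list(panel = out,
       report = new_qc_report(counts, out$map$marker, rownames(out$genotypes)))
}

#' Apply the full editing pipeline
#'
#' Order: individual call rate, then marker call rate, then monomorphic/MAF
#' (frequencies from the post-edit individual set), then autosomes, then the
#' phenotyped-daughter rule for genotyped sires. The combined report stacks
#' the per-rule counts in application order.
#'
#' @inheritParams filter_individuals
#' @return A list `panel`, `report`.
#' @export
apply_qc <- function(panel, phenotypes, thresholds = qc_thresholds()) {
  ids <- rownames(panel$genotypes)
  cr <- call_rate(panel, "individual")
  keep_ind <- cr >= thresholds$min_call_rate
  n_cr_ind <- sum(!keep_ind)
  panel1 <- subset_panel(panel, individuals = which(keep_ind))

  mk <- filter_markers(panel1, thresholds)
  ind <- filter_individuals(mk$panel, phenotypes, thresholds)

  counts <- dplyr::bind_rows(
    tibble::tibble(category = "individual", rule = "call_rate", n_removed = n_cr_ind),
    mk$report$counts,
    ind$report$counts[ind$report$counts$rule != "call_rate", ]
  )
  list(panel = ind$panel,
       report = new_qc_report(counts, ind$panel$map$marker,
                              rownames(ind$panel$genotypes)))
}
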