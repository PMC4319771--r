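#' Assemble design information for the threshold sire model
#'
#' Maps each phenotype record to its year-season (fixed), herd-year (random,
#' iid) and sire (random, correlated through H). The fixed-effect design is
#' full-rank: intercept plus treatment contrasts for year-season (first level
#' absorbed); a single year-season gives an intercept-only X. The genetic
#' effect is indexed over *all* animals of the supplied pedigree, so
#' ancestors without records are carried along and receive solutions.
#'
#' @param phenotypes Tibble with `sire`, `herd_year`, `year_season`, `y`.
#' @param ped Pedigree tibble defining the domain of the genetic effect
#'   (typically the pruned sire pedigree, see [prune_pedigree()]).
#' @return A `model_frame` list: `y`, `X`, `herd_index`, `sire_index`,
#'   `ys_levels`, `hy_levels`, `animal_ids`, `n_records`.
#' @export
build_model_frame <- function(phenotypes, ped) {
  stopifnot(is.data.frame(phenotypes),
            all(c("sire", "herd_year", "year_season", "y") %in% names(phenotypes)))
  validate_pedigree(ped)
  if (anyNA(phenotypes$sire)) {
    abort("records with unknown sire cannot enter a sire model")
  }
  if (!all(phenotypes$sire %in% ped$animal)) {
    missing <- setdiff(phenotypes$sire, ped$animal)
    abort(sprintf("sires absent from the pedigree: %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
  if (anyNA(phenotypes$herd_year) || anyNA(phenotypes$year_season)) {
    abort("every record needs a herd-year and a year-season class")
  }

  ys <- factor(phenotypes$year_season)
  hy <- factor(phenotypes$herd_year)
  X <- if (nlevels(ys) > 1) {
    stats::model.matrix(~ ys)
  } else {
    matrix(1, nrow(phenotypes), 1, dimnames = list(NULL, "(Intercept)"))
  }
  colnames(X) <- sub("^ys", "year_season", colnames(X))

  structure(list(
    y = as.integer(phenotypes$y),
    X = X,
    herd_index = as.integer(hy),
    sire_index = match(phenotypes$sire, ped$animal),
    ys_levels = levels(ys),
    hy_levels = levels(hy),
    animal_ids = ped$animal,
    n_records = nrow(phenotypes)
  ), class = "model_frame")
}

#' @export
print.model_frame <- function(x, ...) {
  cat(sprintf("<model_frame> %d records | %d fixed-effect column(s), %d herd-years, %d pedigree animals\n",
              x$n_records, ncol(x$X), length(x$hy_levels), length(x$animal_ids)))
  invisible(x)
}
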