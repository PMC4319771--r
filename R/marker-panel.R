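#' Construct a marker panel
#'
#' A marker panel couples a genotype matrix (individuals x markers, coded as
#' 0/1/2 copies of the counted allele, `NA` = missing call) with a marker map
#' and the allele frequencies used for centering. Frequencies default to the
#' observed frequencies of the counted allele in the panel itself, the base
#' population the analysis actually sees; pass `freq` to override (e.g. with
#' frequencies from an external reference).
#'
#' @param genotypes Integer matrix, rows = individuals (rownames required),
#'   columns = markers (colnames required), entries 0/1/2 or `NA`.
#' @param map Tibble with one row per marker: `marker`, `chromosome`
#'   (character), `bp` (integer position), sorted by (chromosome, bp) in the
#'   column order of `genotypes`.
#' @param freq Optional numeric vector of counted-allele frequencies per
#'   marker; computed from `genotypes` when `NULL`.
#' @return A `marker_panel` object (list with `genotypes`, `map`, `freq`).
#' @export
marker_panel <- function(genotypes, map, freq = NULL) {
  stopifnot(is.matrix(genotypes), !is.null(colnames(genotypes)), is.data.frame(map))
  if (is.null(rownames(genotypes))) {
    if (nrow(genotypes) > 0) abort("genotype rows must be named by individual ID")
    rownames(genotypes) <- character(0)
  }
  stopifnot(all(c("marker", "chromosome", "bp") %in% names(map)))
  if (nrow(map) != ncol(genotypes) || !identical(map$marker, colnames(genotypes))) {
    abort("`map` rows must match the genotype columns (same markers, same order)")
  }
  if (length(genotypes) && !all(is.na(genotypes))) {
    rng <- range(genotypes, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) abort("genotypes must be coded 0/1/2 (NA = missing)")
  }
  if (is.null(freq)) {
    freq <- colMeans(genotypes, na.rm = TRUE) / 2
  }
  stopifnot(length(freq) == ncol(genotypes))
  structure(list(genotypes = genotypes,
                 map = tibble::as_tibble(map),
                 freq = unname(freq)),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$map$chromosome))))
  mis <- mean(is.na(x$genotypes))
  if (mis > 0) cat(sprintf("  missing calls: %.2f%%\n", 100 * mis))
  invisible(x)
}

#' Subset a marker panel by individuals and/or markers
#'
#' Allele frequencies are recomputed from the retained individuals unless
#' `refreq = FALSE`.
#'
#' @param panel A [marker_panel()].
#' @param individuals Character IDs (or logical/integer index) of rows to keep.
#' @param markers Character IDs (or logical/integer index) of columns to keep.
#' @param refreq Recompute frequencies from the subset (default `TRUE`).
#' @return A `marker_panel`.
#' @export
subset_panel <- function(panel, individuals = NULL, markers = NULL, refreq = TRUE) {
  stopifnot(inherits(panel, "marker_panel"))
  g <- panel$genotypes
  map <- panel$map
  freq <- panel$freq
  if (!is.null(individuals)) {
    if (is.character(individuals) && !all(individuals %in% rownames(g))) {
      abort("unknown individual IDs in `individuals`")
    }
    g <- g[individuals, , drop = FALSE]
  }
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, colnames(g))
    g <- g[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
    freq <- freq[markers]
  }
  marker_panel(g, map, freq = if (refreq) NULL else freq)
}

#' Genotype call rates
#'
#' @param panel A [marker_panel()].
#' @param margin `"individual"` or `"marker"`.
#' @return Named numeric vector of call rates (fraction non-missing).
#' @export
call_rate <- function(panel, margin = c("individual", "marker")) {
  margin <- match.arg(margin)
  ok <- !is.na(panel$genotypes)
  if (margin == "individual") rowMeans(ok) else colMeans(ok)
}

#' Minor allele frequencies of a panel
#'
#' @param panel A [marker_panel()].
#' @return Numeric vector `pmin(p, 1 - p)` per marker.
#' @export
minor_allele_freq <- function(panel) {
  pmin(panel$freq, 1 - panel$freq)
}

# genotype matrix with missing calls imputed to the marker mean 2p,
# used for matrix building only (never written back to files)
impute_genotypes <- function(panel) {
  g <- panel$genotypes
  if (anyNA(g)) {
    mu <- rep(2 * panel$freq, each = nrow(g))
    g[is.na(g)] <- mu[is.na(g)]
  }
  storage.mode(g) <- "double"
  g
}
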