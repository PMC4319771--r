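#' Read and write pedigree CSV files
#'
#' Plain `animal,sire,dam` CSV (extra columns such as `sex`, `generation`,
#' `role` round-trip when present). Unknown parents are written as `0` and
#' read back as `NA`.
#'
#' @param ped Pedigree tibble.
#' @param path File path.
#' @return `write_pedigree()` returns `path` invisibly; `read_pedigree()`
#'   returns a validated pedigree tibble.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) abort("pedigree CSV needs animal, sire, dam columns")
  df$sire[df$sire == "0"] <- NA_character_
  df$dam[df$dam == "0"] <- NA_character_
  if ("generation" %in% names(df)) df$generation <- as.integer(df$generation)
  ped <- tibble::as_tibble(df)
  validate_pedigree(ped)
  ped
}

#' Read and write phenotype CSV files
#'
#' Columns `animal,sire,herd_year,year_season,y` (plus `liability` when
#' present).
#'
#' @param phenotypes Phenotype tibble.
#' @param path File path.
#' @return `write_phenotypes()` returns `path` invisibly; `read_phenotypes()`
#'   a tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(as.data.frame(phenotypes), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("animal", "sire", "herd_year", "year_season", "y")
  if (!all(need %in% names(df))) {
    abort("phenotype CSV needs animal, sire, herd_year, year_season, y columns")
  }
  df$y <- as.integer(df$y)
  if (!all(df$y %in% c(0L, 1L))) abort("phenotype y must be 0/1")
  if ("liability" %in% names(df)) df$liability <- as.numeric(df$liability)
  if (anyDuplicated(df$animal)) abort("duplicate animal IDs in phenotype file")
  tibble::as_tibble(df)
}

#' Write a marker panel as PLINK PED/MAP text files
#'
#' Biallelic coding with alleles `A` (uncounted) and `B` (counted):
#' genotype 0/1/2 is the number of `B` alleles, missing calls are `0 0`.
#' The MAP file holds chromosome, marker, genetic position (0) and bp.
#'
#' @param panel A [marker_panel()].
#' @param prefix Path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param sex Optional named vector (`"M"`/`"F"`) used for the PED sex
#'   column.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(panel, prefix, sex = NULL) {
  g <- panel$genotypes
  ids <- rownames(g)
  sx <- rep(0L, length(ids))
  if (!is.null(sex)) sx <- ifelse(sex[ids] == "M", 1L, ifelse(sex[ids] == "F", 2L, 0L))
  allele <- function(gi) {
    out <- character(2 * length(gi))
    a1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, "B", "A"))
    a2 <- ifelse(is.na(gi), "0", ifelse(gi == 2, "B", "A"))
    out[c(TRUE, FALSE)] <- a1
    out[c(FALSE, TRUE)] <- a2
    out
  }
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], ids[i], "0", "0", sx[i], "-9", allele(g[i, ])), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  map <- panel$map
  utils::write.table(data.frame(map$chromosome, map$marker, 0, map$bp),
                     paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK PED/MAP pair into a marker panel
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return A [marker_panel()]; the counted allele is `B`.
#' @export
read_plink <- function(prefix) {
  map_path <- paste0(prefix, ".map"); ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path)) {
    abort(sprintf("missing %s.ped / %s.map", prefix, prefix))
  }
  map <- utils::read.table(map_path, colClasses = c("character", "character",
                                                    "numeric", "integer"))
  names(map) <- c("chromosome", "marker", "cm", "bp")
  m <- nrow(map)
  lines <- readLines(ped_path)
  ids <- character(length(lines))
  geno <- matrix(NA_integer_, length(lines), m)
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 6 + 2 * m) {
      abort(sprintf("%s line %d: expected %d fields, found %d",
                    basename(ped_path), i, 6 + 2 * m, length(parts)))
    }
    ids[i] <- parts[2]
    a <- parts[-(1:6)]
    a1 <- a[c(TRUE, FALSE)]; a2 <- a[c(FALSE, TRUE)]
    miss <- a1 == "0" | a2 == "0"
    gi <- (a1 == "B") + (a2 == "B")
    gi[miss] <- NA_integer_
    geno[i, ] <- gi
  }
  if (anyDuplicated(ids)) abort("duplicate individual IDs in PED file")
  rownames(geno) <- ids
  colnames(geno) <- map$marker
  marker_panel(geno, tibble::tibble(marker = map$marker,
                                    chromosome = map$chromosome, bp = map$bp))
}

#' Write/read genotypes in the one-line-per-animal 0/1/2/5 dialect
#'
#' `ID<space><contiguous digits>`, one character per marker: 0/1/2 copies of
#' the counted allele, 5 = missing. The marker map travels separately
#' (reuse the PLINK `.map` of [write_plink()] or pass a map tibble).
#'
#' @param panel A [marker_panel()].
#' @param path Genotype file path.
#' @param id_width Left-padding width for the ID column.
#' @return `write_blupf90()` returns `path` invisibly.
#' @export
write_blupf90 <- function(panel, path, id_width = 12L) {
  g <- panel$genotypes
  ch <- g
  ch[is.na(ch)] <- 5L
  lines <- vapply(seq_len(nrow(g)), function(i) {
    sprintf("%-*s %s", id_width, rownames(g)[i], paste(ch[i, ], collapse = ""))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_blupf90
#' @param map Marker map tibble (`marker`, `chromosome`, `bp`) matching the
#'   genotype columns.
#' @export
read_blupf90 <- function(path, map) {
  stopifnot(is.data.frame(map))
  lines <- readLines(path)
  ids <- character(length(lines))
  geno <- matrix(NA_integer_, length(lines), nrow(map))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) abort(sprintf("%s line %d: expected 'ID GENOTYPES'", basename(path), i))
    ids[i] <- parts[1]
    digits <- strtoi(strsplit(parts[2], "")[[1]])
    if (length(digits) != nrow(map)) {
      abort(sprintf("%s line %d: %d genotype characters, map has %d markers",
                    basename(path), i, length(digits), nrow(map)))
    }
    if (any(!digits %in% c(0L, 1L, 2L, 5L))) {
      abort(sprintf("%s line %d: genotype characters must be 0/1/2/5", basename(path), i))
    }
    digits[digits == 5L] <- NA_integer_
    geno[i, ] <- digits
  }
  if (anyDuplicated(ids)) abort("duplicate individual IDs in genotype file")
  rownames(geno) <- ids
  colnames(geno) <- map$marker
  marker_panel(geno, tibble::as_tibble(map))
}

#' Write the simulation ground truth as JSON
#'
#' @param truth The `truth` element of [simulate_phenotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$true_breeding_values <- as.list(out$true_breeding_values)
  out$sire_effects <- as.list(out$sire_effects)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
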