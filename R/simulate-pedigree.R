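#' Simulate a multi-generation daughter-design pedigree
#'
#' Builds the pedigree of a progeny-testing scheme: founder sires each get a
#' fixed number of recorded daughters out of unique founder dams; for later
#' generations each sire line is continued by a son (out of a new founder dam)
#' who in turn gets daughters. Parents always precede their offspring in the
#' returned table.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `animal`, `sire`, `dam` (character IDs,
#'   `NA` = unknown parent), `sex` (`"M"`/`"F"`), `generation` (founders are
#'   0) and `role` (`"founder_sire"`, `"founder_dam"`, `"son"`, `"daughter"`).
#' @examples
#' ped <- simulate_pedigree(sim_config(n_founder_sires = 4, n_generations = 2,
#'                                     daughters_per_sire = 3))
#' table(ped$role)
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  ns <- config$n_founder_sires
  ng <- config$n_generations
  nd <- config$daughters_per_sire

  sire_counter <- ns
  dam_counter <- 0L
  dau_counter <- 0L

  founder_sires <- sprintf("B%05d", seq_len(ns))
  rows <- list(tibble::tibble(
    animal = founder_sires, sire = NA_character_, dam = NA_character_,
    sex = "M", generation = 0L, role = "founder_sire"
  ))

  serving <- founder_sires
  for (g in seq_len(ng)) {
    if (g > 1L) {
      # continue each sire line with a son out of a fresh founder dam
      son_dams <- sprintf("F%07d", dam_counter + seq_len(ns))
      dam_counter <- dam_counter + ns
      sons <- sprintf("B%05d", sire_counter + seq_len(ns))
      sire_counter <- sire_counter + ns
      rows <- c(rows, list(
        tibble::tibble(animal = son_dams, sire = NA_character_, dam = NA_character_,
                       sex = "F", generation = 0L, role = "founder_dam"),
        tibble::tibble(animal = sons, sire = serving, dam = son_dams,
                       sex = "M", generation = g - 1L, role = "son")
      ))
      serving <- sons
    }
    n_dau <- ns * nd
    dau_dams <- sprintf("F%07d", dam_counter + seq_len(n_dau))
    dam_counter <- dam_counter + n_dau
    daughters <- sprintf("D%07d", dau_counter + seq_len(n_dau))
    dau_counter <- dau_counter + n_dau
    rows <- c(rows, list(
      tibble::tibble(animal = dau_dams, sire = NA_character_, dam = NA_character_,
                     sex = "F", generation = 0L, role = "founder_dam"),
      tibble::tibble(animal = daughters, sire = rep(serving, each = nd),
                     dam = dau_dams, sex = "F", generation = g, role = "daughter")
    ))
  }

  ped <- dplyr::bind_rows(rows)
  validate_pedigree(ped)
  ped
}

#' Validate pedigree ordering and identity constraints
#'
#' Checks that animal IDs are unique, that every named parent appears as an
#' animal earlier in the table (so parents precede offspring and no animal can
#' be its own ancestor), and that no animal is its own parent.
#'
#' @param ped A pedigree tibble with `animal`, `sire`, `dam` columns.
#' @return `ped`, invisibly; errors on violation.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("animal", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$animal)) {
    abort(sprintf("duplicate animal IDs in pedigree: %s",
                  paste(unique(ped$animal[duplicated(ped$animal)])[1:3], collapse = ", ")))
  }
  pos <- setNames(seq_len(nrow(ped)), ped$animal)
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- !is.na(p)
    miss <- known & !(p %in% names(pos))
    if (any(miss)) abort(sprintf("%s IDs not present as animals: %s", col,
                                 paste(head(unique(p[miss]), 3), collapse = ", ")))
    bad <- known & pos[p] >= seq_len(nrow(ped))
    if (any(bad)) abort(sprintf("pedigree not topologically ordered: %s appears before its %s",
                                ped$animal[which(bad)[1]], col))
  }
  invisible(ped)
}

#' Restrict a pedigree to a set of animals and all their ancestors
#'
#' Used to carve the sire pedigree (the domain of the random genetic effect)
#' out of a full simulation pedigree: daughters carry records but only sires
#' and their ancestors enter the relationship matrix of a sire model.
#'
#' @param ped A pedigree tibble.
#' @param ids Animal IDs to keep (their ancestors are added automatically).
#' @return The pruned pedigree tibble, original order preserved.
#' @export
prune_pedigree <- function(ped, ids) {
  validate_pedigree(ped)
  keep <- ped$animal %in% ids
  sire_of <- setNames(match(ped$sire, ped$animal), ped$animal)
  dam_of <- setNames(match(ped$dam, ped$animal), ped$animal)
  # sweep backwards: an animal is kept if any kept animal descends from it
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      s <- sire_of[i]; d <- dam_of[i]
      if (!is.na(s)) keep[s] <- TRUE
      if (!is.na(d)) keep[d] <- TRUE
    }
  }
  ped[keep, , drop = FALSE]
}
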