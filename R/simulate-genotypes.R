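#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder haplotypes are drawn marker-wise from uniform allele frequencies in
#' `[founder_maf_low, founder_maf_high]`; descendant haplotypes are produced
#' by meiosis with recombination (crossover count per chromosome is Poisson
#' with mean `morgans_per_chromosome`, positions uniform on the genetic map,
#' no interference). Genotypes are coded 0/1/2 copies of the counted allele;
#' an optional uniform dropout masks calls as missing to exercise QC.
#'
#' @param ped A pedigree from [simulate_pedigree()] (or any topologically
#'   ordered pedigree tibble).
#' @param config A [sim_config()].
#' @param keep_haplotypes Attach the phased haplotype matrices as attribute
#'   `haplotypes` (a list `H1`, `H2`); doubles memory, used for testing
#'   transmission.
#' @return A [marker_panel()] covering every pedigree animal. The map carries
#'   the founder (true) allele frequency per marker in column `founder_freq`;
#'   the panel `freq` field holds the observed frequencies.
#' @export
simulate_genotypes <- function(ped, config, keep_haplotypes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  validate_pedigree(ped)
  set.seed(config$seed + 1L)

  n_chr <- config$n_chromosomes
  m_chr <- config$markers_per_chromosome
  m <- n_chr * m_chr

  map <- purrr::map_dfr(seq_len(n_chr), function(chr) {
    tibble::tibble(chromosome = as.character(chr),
                   bp = sort(sample.int(config$bp_per_chromosome, m_chr)))
  })
  map <- dplyr::mutate(map,
                       marker = sprintf("M%05d", dplyr::row_number()),
                       founder_freq = runif(m, config$founder_maf_low, config$founder_maf_high))
  map <- map[, c("marker", "chromosome", "bp", "founder_freq")]

  n <- nrow(ped)
  sire_idx <- match(ped$sire, ped$animal)
  dam_idx <- match(ped$dam, ped$animal)

  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)

  # process animals in waves: founders first, then each wave once both
  # parents are done (parents precede offspring, so waves are well defined)
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L
    if (!is.na(sire_idx[i])) d <- depth[sire_idx[i]] + 1L
    if (!is.na(dam_idx[i])) d <- max(d, depth[dam_idx[i]] + 1L)
    depth[i] <- d
  }

  founders <- which(depth == 0L)
  p <- map$founder_freq
  nf <- length(founders)
  H1[founders, ] <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  H2[founders, ] <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)

  # Poisson-process crossover masks: per child x marker, the transmitted
  # parental haplotype flips at each crossover along the genetic map
  gpos <- map$bp / config$bp_per_chromosome * config$morgans_per_chromosome
  chr_of <- map$chromosome
  new_chr <- c(TRUE, chr_of[-1] != chr_of[-m])
  dpos <- ifelse(new_chr, 0, c(0, diff(gpos)))
  dpos[dpos < 0] <- 0

  meiosis <- function(P1, P2) {
    k <- nrow(P1)
    cross <- matrix(0L, k, m)
    run <- integer(k)
    for (j in seq_len(m)) {
      if (new_chr[j]) {
        run <- rbinom(k, 1L, 0.5)
      } else if (dpos[j] > 0) {
        run <- run + rpois(k, dpos[j])
      }
      cross[, j] <- run
    }
    mask <- cross %% 2L
    P1 * (1L - mask) + P2 * mask
  }

  for (d in seq_len(max(depth))) {
    wave <- which(depth == d)
    if (!length(wave)) next
    s <- sire_idx[wave]; dm <- dam_idx[wave]
    if (anyNA(s) || anyNA(dm)) {
      abort("gene dropping requires both parents known for every non-founder")
    }
    H1[wave, ] <- meiosis(H1[s, , drop = FALSE], H2[s, , drop = FALSE])
    H2[wave, ] <- meiosis(H1[dm, , drop = FALSE], H2[dm, , drop = FALSE])
  }

  geno <- H1 + H2
  rownames(geno) <- ped$animal
  colnames(geno) <- map$marker
  if (config$genotype_dropout > 0) {
    drop <- runif(length(geno)) < config$genotype_dropout
    geno[drop] <- NA_integer_
  }
  panel <- marker_panel(geno, map)
  if (keep_haplotypes) {
    rownames(H1) <- rownames(H2) <- ped$animal
    attr(panel, "haplotypes") <- list(H1 = H1, H2 = H2)
  }
  panel
}
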