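# small shared fixtures, built once per test run

small_config <- function(seed = 42, ...) {
  sim_config(n_founder_sires = 12, n_generations = 2, daughters_per_sire = 6,
             n_chromosomes = 3, markers_per_chromosome = 15, n_qtl = 6,
             n_herds = 8, n_year_seasons = 3, seed = seed, ...)
}

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(small_config())
    cache
  }
})

# founder-only panel built directly from HWE sampling (no pedigree dropping)
hwe_panel <- function(n, p, n_chr = 1, seed = 1) {
  set.seed(seed)
  m <- length(p)
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  rownames(g) <- sprintf("I%05d", seq_len(n))
  colnames(g) <- sprintf("M%05d", seq_len(m))
  per_chr <- ceiling(m / n_chr)
  map <- tibble::tibble(
    marker = colnames(g),
    chromosome = as.character(rep(seq_len(n_chr), each = per_chr, length.out = m)),
    bp = as.integer(rep(seq(1e6, 9e7, length.out = per_chr), n_chr)[seq_len(m)])
  )
  marker_panel(g, map, freq = p)
}

# drop markers fixed (p = 0 or 1) in the current individual subset
drop_fixed <- function(panel) {
  subset_panel(panel, markers = which(panel$freq > 0 & panel$freq < 1))
}

# hand-written pedigree tibble
ped_tbl <- function(animal, sire, dam, role = "daughter") {
  tibble::tibble(animal = animal, sire = sire, dam = dam,
                 sex = "F", generation = 0L, role = role)
}
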