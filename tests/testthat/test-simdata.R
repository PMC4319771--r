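test_that("pedigree layout matches the configured design", {
  cfg <- sim_config(n_founder_sires = 10, n_generations = 1, daughters_per_sire = 5)
  ped <- simulate_pedigree(cfg)
  expect_equal(sum(ped$role == "founder_sire"), 10)
  expect_equal(sum(ped$role == "daughter"), 50)
  expect_gte(sum(ped$role == "founder_dam"), 50)
  founders <- ped[ped$generation == 0, ]
  expect_true(all(is.na(founders$sire) & is.na(founders$dam)))
  # every daughter has both parents
  dau <- ped[ped$role == "daughter", ]
  expect_false(anyNA(dau$sire) || anyNA(dau$dam))
  # later generations draw sires from the previous generation's sons
  cfg2 <- sim_config(n_founder_sires = 4, n_generations = 3, daughters_per_sire = 2)
  ped2 <- simulate_pedigree(cfg2)
  expect_equal(sum(ped2$role == "son"), 8)            # 4 per later generation
  expect_equal(sum(ped2$role == "daughter"), 24)
})

test_that("simulation is deterministic given the seed", {
  cfg <- small_config(seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$panel$genotypes, s2$panel$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  s3 <- simulate_study(small_config(seed = 8))
  expect_false(identical(s1$phenotypes$y, s3$phenotypes$y))
})

test_that("pedigrees are topologically ordered and validated", {
  ped <- simulate_pedigree(small_config())
  pos <- setNames(seq_len(nrow(ped)), ped$animal)
  ok <- is.na(ped$sire) | pos[ped$sire] < seq_len(nrow(ped))
  expect_true(all(ok))
  bad <- ped_tbl(c("X", "Y"), c("Y", NA), c(NA, NA))
  expect_error(validate_pedigree(bad), "topologically")
  dup <- ped_tbl(c("X", "X"), c(NA, NA), c(NA, NA))
  expect_error(validate_pedigree(dup), "duplicate")
})

test_that("gene dropping is Mendelian-consistent for every parent-offspring pair", {
  st <- small_study()
  ped <- st$pedigree; g <- st$panel$genotypes
  kids <- which(!is.na(ped$sire))
  for (i in kids) {
    gk <- g[ped$animal[i], ]
    gs <- g[ped$sire[i], ]
    gd <- g[ped$dam[i], ]
    # child allele count must be attainable from one sire + one dam allele
    smin <- pmax(0, gs - 1); smax <- pmin(1, gs)
    dmin <- pmax(0, gd - 1); dmax <- pmin(1, gd)
    expect_true(all(gk >= smin + dmin & gk <= smax + dmax))
  }
})

test_that("founder genotypes agree with Hardy-Weinberg at p = 0.3", {
  cfg <- sim_config(n_founder_sires = 10000, n_generations = 1, daughters_per_sire = 1,
                    n_chromosomes = 1, markers_per_chromosome = 3, n_qtl = 1,
                    founder_maf_low = 0.3, founder_maf_high = 0.3, seed = 5)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  founders <- ped$animal[ped$role == "founder_sire"]
  g <- panel$genotypes[founders, 1]
  n <- length(g)
  exp_freq <- c(`0` = 0.49, `1` = 0.42, `2` = 0.09)
  for (k in names(exp_freq)) {
    obs <- mean(g == as.integer(k))
    se <- sqrt(exp_freq[[k]] * (1 - exp_freq[[k]]) / n)
    expect_lt(abs(obs - exp_freq[[k]]), 3 * se)
  }
})

test_that("zero genetic length transmits parental haplotypes intact", {
  cfg <- sim_config(n_founder_sires = 1, n_generations = 1, daughters_per_sire = 30,
                    n_chromosomes = 1, markers_per_chromosome = 40, n_qtl = 2,
                    morgans_per_chromosome = 0, seed = 9)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg, keep_haplotypes = TRUE)
  # with no crossovers every transmitted gamete is an intact parental
  # haplotype: each child haplotype must equal one of its parent's two
  H <- attr(panel, "haplotypes")
  kids <- which(!is.na(ped$sire))
  for (i in kids) {
    for (pair in list(c("H1", "sire"), c("H2", "dam"))) {
      child <- H[[pair[1]]][ped$animal[i], ]
      par <- ped[[pair[2]]][i]
      match1 <- all(child == H$H1[par, ])
      match2 <- all(child == H$H2[par, ])
      expect_true(match1 || match2)
    }
  }
})

test_that("empirical incidence tracks the configured incidence", {
  cfg <- sim_config(n_founder_sires = 400, n_generations = 1, daughters_per_sire = 100,
                    n_chromosomes = 2, markers_per_chromosome = 5, n_qtl = 3,
                    n_herds = 800, incidence = 0.1091, seed = 31)
  st <- simulate_study(cfg)
  n <- nrow(st$phenotypes)
  se <- sqrt(0.1091 * (1 - 0.1091) / n)
  expect_lt(abs(mean(st$phenotypes$y) - 0.1091), 2 * se)
  # median threshold gives ~50% incidence
  cfg2 <- sim_config(n_founder_sires = 400, n_generations = 1, daughters_per_sire = 100,
                     n_chromosomes = 2, markers_per_chromosome = 5, n_qtl = 3,
                     n_herds = 800, incidence = 0.5, seed = 32)
  st2 <- simulate_study(cfg2)
  se2 <- sqrt(0.25 / n)
  expect_lt(abs(mean(st2$phenotypes$y) - 0.5), 2 * se2)
})

test_that("simulated sire-effect variance calibrates to sigma2_s at scale", {
  cfg <- sim_config(n_founder_sires = 5000, n_generations = 1, daughters_per_sire = 10,
                    n_chromosomes = 2, markers_per_chromosome = 4, n_qtl = 4,
                    n_herds = 1000, seed = 13)
  st <- simulate_study(cfg)
  sires <- unique(st$phenotypes$sire)
  expect_gte(nrow(st$phenotypes), 50000)
  v <- var(st$truth$sire_effects[sires])
  expect_lt(abs(v - cfg$sigma2_s) / cfg$sigma2_s, 0.05)
})

test_that("without genetic variance, sires do not differ in case probability", {
  cfg <- sim_config(n_founder_sires = 50, n_generations = 1, daughters_per_sire = 200,
                    n_chromosomes = 2, markers_per_chromosome = 4, n_qtl = 0,
                    sigma2_s = 0, n_herds = 500, seed = 17)
  st <- simulate_study(cfg)
  expect_true(all(st$truth$true_breeding_values == 0))
  tab <- table(st$phenotypes$sire, st$phenotypes$y)
  p <- suppressWarnings(stats::chisq.test(tab))$p.value
  expect_gt(p, 0.01)
})

test_that("breeding values equal genotype-times-effect sums exactly", {
  st <- small_study()
  tr <- st$truth
  g <- st$panel$genotypes[, tr$qtl_indices, drop = FALSE]
  p <- st$panel$map$founder_freq[tr$qtl_indices]
  bv_qtl <- drop(sweep(g, 2, 2 * p) %*% tr$qtl_effects)
  # polygenic part is the remainder; with qtl_variance_fraction given, the
  # QTL part must match the recorded breeding values minus a pedigree-smooth
  # polygenic term -- founders' dams have no records, so check the identity
  # on the QTL component only under a fully-QTL configuration
  cfg <- small_config(qtl_variance_fraction = 1)
  st2 <- simulate_study(cfg)
  g2 <- st2$panel$genotypes[, st2$truth$qtl_indices, drop = FALSE]
  p2 <- st2$panel$map$founder_freq[st2$truth$qtl_indices]
  bv2 <- drop(sweep(g2, 2, 2 * p2) %*% st2$truth$qtl_effects)
  expect_equal(unname(st2$truth$true_breeding_values), unname(bv2), tolerance = 1e-12)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_founder_sires = 0), "n_founder_sires")
  expect_error(sim_config(incidence = 0), "incidence")
  expect_error(sim_config(incidence = 1), "incidence")
  expect_error(sim_config(founder_maf_low = 0.4, founder_maf_high = 0.2), "maf")
})
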