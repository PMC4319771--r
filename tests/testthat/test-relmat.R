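test_that("A matches hand-derived relationships", {
  # founders only -> identity
  ped0 <- ped_tbl(c("A", "B", "C"), NA_character_, NA_character_, role = "founder_dam")
  expect_equal(unclass(build_A(ped0)), diag(3), ignore_attr = TRUE)

  # non-inbred parent-offspring: a = 0.5, founder diagonal 1
  ped1 <- ped_tbl(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D"))
  A1 <- build_A(ped1)
  expect_equal(A1["S", "O"], 0.5)
  expect_equal(A1["S", "S"], 1)
  expect_equal(A1["O", "O"], 1)

  # offspring of two full sibs: diagonal 1.25
  ped2 <- ped_tbl(c("S", "D", "X", "Y", "Z"),
                  c(NA, NA, "S", "S", "X"),
                  c(NA, NA, "D", "D", "Y"))
  A2 <- build_A(ped2)
  expect_equal(A2["X", "Y"], 0.5)
  expect_equal(A2["Z", "Z"], 1.25)
  expect_equal(pedigree_inbreeding(ped2)[["Z"]], 0.25)
})

test_that("A-inverse follows Henderson's rules on a non-inbred trio", {
  ped <- ped_tbl(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D"))
  Ainv <- as.matrix(build_A_inverse(ped))
  expect_equal(Ainv["O", "O"], 2)
  expect_equal(Ainv["S", "O"], -1)
  expect_equal(Ainv["D", "O"], -1)
  expect_equal(Ainv["S", "D"], 0.5)
  expect_equal(Ainv["S", "S"], 1.5)
  # founders only -> identity
  ped0 <- ped_tbl(c("A", "B"), NA_character_, NA_character_)
  expect_equal(as.matrix(build_A_inverse(ped0)), diag(2), ignore_attr = TRUE)
})

test_that("A times A-inverse is the identity on a simulated pedigree", {
  cfg <- sim_config(n_founder_sires = 10, n_generations = 3, daughters_per_sire = 2,
                    n_chromosomes = 1, markers_per_chromosome = 2, n_qtl = 1, seed = 3)
  ped <- simulate_pedigree(cfg)
  expect_gte(nrow(ped), 150)
  A <- build_A(ped)
  Ainv <- as.matrix(build_A_inverse(ped))
  expect_lt(max(abs(A %*% Ainv - diag(nrow(A)))), 1e-8)
  # dense-inversion oracle
  expect_lt(max(abs(Ainv - solve(unclass(A)))), 1e-6)
  # diag(A) = 1 + F
  f <- pedigree_inbreeding(ped)
  expect_equal(unname(diag(unclass(A))), unname(1 + f), ignore_attr = TRUE)
})

test_that("the indirect A22 equals the dense A block", {
  st <- small_study()
  ped_s <- prune_pedigree(st$pedigree, unique(st$phenotypes$sire))
  ids <- sample(ped_s$animal, 15)
  A <- build_A(ped_s)
  A22 <- pedigree_A_submatrix(ped_s, ids)
  expect_equal(unclass(A22), unclass(A)[ids, ids], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("first-iteration weights satisfy the scale normalization", {
  panel <- hwe_panel(50, runif(40, 0.1, 0.5), seed = 2)
  w <- marker_weights(panel)
  expect_equal(sum(w$d * 2 * w$freq * (1 - w$freq)), 1, tolerance = 1e-10)
  expect_error(marker_weights(hwe_panel(10, c(0.3, 0.4), seed = 1), freq = c(0, 0.4)),
               "fixed markers")
})

test_that("G matches the hand-computed ZDZ' example", {
  # 1 individual, 2 markers, p = 0.5, genotypes (2,2): z = (1,1),
  # d = 1/(2 * 0.5) = 1 each -> G11 = 2
  g <- matrix(c(2L, 2L), 1, 2, dimnames = list("I1", c("M1", "M2")))
  map <- tibble::tibble(marker = c("M1", "M2"), chromosome = "1", bp = c(1L, 2L))
  panel <- marker_panel(g, map, freq = c(0.5, 0.5))
  G <- build_G(panel)
  expect_equal(G[1, 1], 2)

  # an individual sitting at the population mean has a zero G row
  g2 <- rbind(I1 = c(1L, 1L), I2 = c(2L, 0L), I3 = c(0L, 2L))
  colnames(g2) <- c("M1", "M2")
  panel2 <- marker_panel(g2, map, freq = c(0.5, 0.5))
  G2 <- build_G(panel2)
  expect_equal(unname(G2["I1", ]), c(0, 0, 0))
})

test_that("mean diagonal of G is ~1 for unrelated HWE founders", {
  p <- runif(400, 0.1, 0.5)
  panel <- hwe_panel(5000, p, n_chr = 4, seed = 6)
  G <- build_G(panel, marker_weights(panel, freq = p))
  expect_gt(mean(diag(G)), 0.98)
  expect_lt(mean(diag(G)), 1.02)
})

test_that("G is invariant to marker permutation", {
  p <- runif(30, 0.1, 0.5)
  panel <- hwe_panel(40, p, seed = 8)
  perm <- sample(30)
  panel_p <- subset_panel(panel, markers = perm, refreq = FALSE)
  G1 <- build_G(panel, marker_weights(panel, freq = p))
  G2 <- build_G(panel_p, marker_weights(panel_p, freq = p[perm]))
  expect_equal(unclass(G1), unclass(G2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("blending repairs singular G and stays a convex combination", {
  p <- runif(60, 0.1, 0.5)
  panel <- hwe_panel(20, p, seed = 4)
  g <- panel$genotypes
  g[20, ] <- g[19, ]  # duplicated individual -> singular G
  panel2 <- marker_panel(g, panel$map, freq = p)
  G <- build_G(panel2, marker_weights(panel2, freq = p))
  expect_lt(min(eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  A22 <- diag(20); dimnames(A22) <- list(rownames(g), rownames(g))
  Gs <- blend_G(G, A22, 0.05)
  expect_gt(min(eigen(unclass(Gs), symmetric = TRUE, only.values = TRUE)$values), 0)
  # alpha = 0 is the identity operation
  expect_equal(unclass(blend_G(G, A22, 0)), unclass(G), ignore_attr = TRUE)
  # convexity, elementwise
  lo <- pmin(unclass(G), A22); hi <- pmax(unclass(G), A22)
  expect_true(all(unclass(Gs) >= lo - 1e-12 & unclass(Gs) <= hi + 1e-12))
  expect_error(blend_G(G, A22, 1), "alpha")
})

test_that("H-inverse reduces to A-inverse and G-inverse in the limits", {
  st <- small_study()
  ped_s <- prune_pedigree(st$pedigree, unique(st$phenotypes$sire))
  Ainv <- build_A_inverse(ped_s)

  # empty genotyped set: H^-1 = A^-1 exactly
  G0 <- matrix(numeric(0), 0, 0)
  H0 <- build_H_inverse(Ainv, G0, G0)
  expect_equal(as.matrix(H0), as.matrix(Ainv), ignore_attr = TRUE)

  # all animals genotyped with A22 = A: H^-1 = G*^-1
  ids <- ped_s$animal
  A22 <- pedigree_A_submatrix(ped_s, ids)
  panel <- drop_fixed(subset_panel(st$panel, individuals = ids))
  Gs <- blend_G(build_G(panel), A22, 0.05)
  H1 <- build_H_inverse(Ainv, Gs, A22)
  expect_lt(max(abs(as.matrix(H1) - solve(unclass(Gs)))), 1e-6)

  # non-genotyped block is bit-identical to A-inverse
  gids <- unique(st$phenotypes$sire)[1:10]
  A22b <- pedigree_A_submatrix(ped_s, gids)
  panelb <- drop_fixed(subset_panel(st$panel, individuals = gids))
  Gsb <- blend_G(build_G(panelb), A22b, 0.05)
  Hb <- build_H_inverse(Ainv, Gsb, A22b)
  others <- setdiff(ids, gids)
  expect_identical(as.matrix(Hb[others, others]), as.matrix(Ainv[others, others]))
})

test_that("H matches the textbook blockwise construction", {
  st <- small_study()
  ped_s <- prune_pedigree(st$pedigree, unique(st$phenotypes$sire))
  A <- build_A(ped_s)
  Ainv <- build_A_inverse(ped_s)
  gids <- sort(sample(ped_s$animal, 10))
  idx <- match(gids, ped_s$animal)
  A22 <- pedigree_A_submatrix(ped_s, gids)
  panel <- drop_fixed(subset_panel(st$panel, individuals = gids))
  Gs <- blend_G(build_G(panel), A22, 0.05)
  H <- solve(as.matrix(build_H_inverse(Ainv, Gs, A22)))
  Ad <- unclass(A)
  A12 <- Ad[-idx, idx, drop = FALSE]
  A22i <- solve(Ad[idx, idx])
  Ho <- Ad
  Ho[-idx, idx] <- A12 %*% A22i %*% unclass(Gs)
  Ho[idx, -idx] <- t(Ho[-idx, idx])
  Ho[idx, idx] <- unclass(Gs)
  Ho[-idx, -idx] <- Ad[-idx, -idx] +
    A12 %*% A22i %*% (unclass(Gs) - Ad[idx, idx]) %*% A22i %*% t(A12)
  expect_lt(max(abs(H - Ho)), 1e-6)
})
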