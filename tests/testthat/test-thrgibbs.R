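tiny_frame <- function() {
  ped <- ped_tbl(c("S1", "S2"), NA_character_, NA_character_, role = "founder_sire")
  phen <- tibble::tibble(animal = c("a", "b", "c", "d"),
                         sire = c("S1", "S1", "S2", "S2"),
                         herd_year = c("H1", "H1", "H2", "H2"),
                         year_season = c("Y1", "Y2", "Y1", "Y2"),
                         y = c(1L, 0L, 0L, 1L))
  list(ped = ped, phen = phen)
}

test_that("model frame builds full-rank designs and factor maps", {
  tf <- tiny_frame()
  fr <- build_model_frame(tf$phen, tf$ped)
  expect_equal(ncol(fr$X), 2)                  # intercept + 1 contrast
  expect_equal(length(fr$hy_levels), 2)
  expect_equal(fr$sire_index, c(1L, 1L, 2L, 2L))
  # single year-season: intercept only
  ph2 <- tf$phen; ph2$year_season <- "Y1"
  fr2 <- build_model_frame(ph2, tf$ped)
  expect_equal(colnames(fr2$X), "(Intercept)")
  # unknown sire is an error
  ph3 <- tf$phen; ph3$sire[1] <- NA
  expect_error(build_model_frame(ph3, tf$ped), "unknown sire")
})

test_that("retained sample count follows floor((niter - burnin)/thin)", {
  cfg <- gibbs_config(n_iterations = 1037, burn_in = 200, thin = 7, seed = 1)
  st <- small_study()
  ped_s <- prune_pedigree(st$pedigree, unique(st$phenotypes$sire))
  fit <- gibbs_fit(build_model_frame(st$phenotypes, ped_s),
                   build_A_inverse(ped_s), cfg)
  expect_equal(nrow(fit$samples), (1037 - 200) %/% 7)
  expect_equal(nrow(fit$location), nrow(fit$samples))
})

test_that("every retained sample carries residual variance exactly 1", {
  st <- small_study()
  ped_s <- prune_pedigree(st$pedigree, unique(st$phenotypes$sire))
  fit <- gibbs_fit(build_model_frame(st$phenotypes, ped_s),
                   build_A_inverse(ped_s),
                   gibbs_config(n_iterations = 600, burn_in = 100, thin = 2, seed = 2))
  expect_true(all(fit$samples$sigma2_e == 1))
})

test_that("all-0 or all-1 outcomes are rejected", {
  tf <- tiny_frame()
  ph <- tf$phen; ph$y <- 1L
  fr <- build_model_frame(ph, tf$ped)
  Ainv <- build_A_inverse(tf$ped)
  expect_error(gibbs_fit(fr, Ainv, gibbs_config(n_iterations = 100, burn_in = 10)),
               "unidentifiable")
})

test_that("liability draws respect the sign constraint and truncated mean", {
  set.seed(4)
  x <- liabilityscan:::.rtnorm_pos(50000, 0)
  expect_true(all(x > 0))
  # E[N(0,1) | > 0] = sqrt(2/pi) = 0.7979
  expect_lt(abs(mean(x) - sqrt(2 / pi)), 4 * sd(x) / sqrt(length(x)))
  # far-tail truncation stays finite and positive
  y <- liabilityscan:::.rtnorm_pos(5000, -8)
  expect_true(all(y > 0 & is.finite(y)))
})

test_that("with observed Gaussian liabilities the sampler solves the MME", {
  st <- small_study()
  ped_s <- prune_pedigree(st$pedigree, unique(st$phenotypes$sire))
  Ainv <- build_A_inverse(ped_s)
  fr <- build_model_frame(st$phenotypes, ped_s)
  lam <- st$phenotypes$liability
  s2h <- 0.496; s2s <- 0.037
  fit <- gibbs_fit(fr, Ainv,
                   gibbs_config(n_iterations = 12000, burn_in = 1000, thin = 2,
                                seed = 6, start_sigma2_h = s2h, start_sigma2_s = s2s),
                   gaussian = TRUE, lambda_obs = lam)
  n <- length(lam)
  Zh <- Matrix::sparseMatrix(i = seq_len(n), j = fr$herd_index, x = 1,
                             dims = c(n, length(fr$hy_levels)))
  Zs <- Matrix::sparseMatrix(i = seq_len(n), j = fr$sire_index, x = 1,
                             dims = c(n, length(fr$animal_ids)))
  W <- cbind(Matrix::Matrix(fr$X), Zh, Zs)
  P <- Matrix::bdiag(Matrix::Diagonal(ncol(fr$X), 0),
                     Matrix::Diagonal(ncol(Zh)) / s2h, Ainv / s2s)
  sol <- as.numeric(Matrix::solve(Matrix::crossprod(W) + P,
                                  Matrix::crossprod(W, lam)))
  expect_lt(max(abs(colMeans(fit$location) - sol)), 0.05)
  expect_gt(cor(colMeans(fit$location), sol), 0.999)
})

test_that("posterior summaries match closed forms on known chains", {
  fake_chain <- function(x) {
    structure(list(samples = tibble::tibble(iteration = seq_along(x),
                                            sigma2_h = x, sigma2_s = x,
                                            sigma2_e = 1, h2 = x),
                   location = matrix(x, ncol = 1, dimnames = list(NULL, "sire:S1")),
                   animal_ids = "S1", hy_levels = "H1", ys_levels = "Y1",
                   n_records = 1L, config = gibbs_config(), gaussian = FALSE),
              class = "threshold_fit")
  }
  set.seed(9)
  z <- rnorm(10000)
  hpd <- hpd_interval(z, 0.95)
  expect_lt(abs(hpd[["lower"]] + 1.96), 0.08)
  expect_lt(abs(hpd[["upper"]] - 1.96), 0.08)
  # constant chain: zero SD, point HPD
  s <- summarize_chain(fake_chain(rep(2, 200)))
  expect_equal(s$sd[s$term == "h2"], 0)
  expect_equal(s$hpd_lower[s$term == "h2"], 2)
  expect_equal(s$hpd_upper[s$term == "h2"], 2)
  # mirrored chain: mean exactly zero
  m <- c(z[1:500], -z[1:500])
  expect_equal(mean(m), 0)
  s2 <- summarize_chain(fake_chain(m))
  expect_equal(s2$mean[s2$term == "h2"], 0)
  # too-short chains are refused
  expect_error(summarize_chain(fake_chain(rep(1, 50))), "100 retained")
})

test_that("heritability follows the sire-model closed form", {
  expect_equal(heritability_from_components(0, 0.5, 1), 0)
  expect_equal(heritability_from_components(1 / 3, 0, 1), 1)
  expect_equal(heritability_from_components(0.037, 0.496, 1),
               4 * 0.037 / 1.533, tolerance = 1e-12)
  expect_error(heritability_from_components(0, 0, 0), "positive")
})

test_that("tidy and glance return broom-shaped summaries", {
  st <- small_study()
  ped_s <- prune_pedigree(st$pedigree, unique(st$phenotypes$sire))
  fit <- gibbs_fit(build_model_frame(st$phenotypes, ped_s),
                   build_A_inverse(ped_s),
                   gibbs_config(n_iterations = 700, burn_in = 100, thin = 2, seed = 3))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_true(all(c("sigma2_s", "sigma2_h", "h2") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_retained, nrow(fit$samples))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
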