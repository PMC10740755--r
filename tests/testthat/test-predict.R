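# GBLUP/GFBLUP predictions and repeated cross-validation.

test_that("with no residual variance reference GEBVs reproduce the phenotypes", {
  g <- random_genotypes(30, 300, seed = 11)   # m > n: invertible GRM
  k <- build_grm(g)
  y <- setNames(rnorm(30), k$ids)
  fit <- gblup_predict(k, y, vc = fixed_vc(sigma2_u = 1, sigma2_e = 1e-10))
  expect_equal(unname(fit$gebv[names(y)]), unname(y - fit$mu_hat),
               tolerance = 1e-4)
})

test_that("GBLUP equals ridge-regression SNP-BLUP on shared markers", {
  g <- random_genotypes(30, 200, seed = 12)
  k <- build_grm(g)
  s2u <- 1.5; s2e <- 0.8
  ref <- k$ids[1:24]
  y <- setNames(rnorm(30, sd = 1.5), k$ids)[ref]
  fit <- gblup_predict(k, y, vc = fixed_vc(sigma2_u = s2u, sigma2_e = s2e))
  # independent marker-space route: ridge on the same standardized markers
  p <- colMeans(g$dosage) / 2
  W <- sweep(sweep(g$dosage, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  m <- ncol(W)
  Wref <- W[match(ref, k$ids), , drop = FALSE]
  lambda <- s2e / (s2u / m)
  ahat <- solve(crossprod(Wref) + diag(lambda, m),
                crossprod(Wref, y - fit$mu_hat))
  gebv_snp <- as.vector(W %*% ahat)
  expect_lt(max(abs(fit$gebv - gebv_snp)), 1e-6)
})

test_that("GFBLUP with identical kernels collapses to GBLUP", {
  g <- random_genotypes(40, 150, seed = 13)
  k <- build_grm(g)
  kf <- kinship(k$matrix, k$ids, k$n_snps_used, "feature")
  kr <- kinship(k$matrix, k$ids, k$n_snps_used, "remainder")
  ref <- k$ids[1:32]
  y <- setNames(rnorm(40), k$ids)[ref]
  vc2 <- fixed_vc(sigma2_f = 0.6, sigma2_r = 0.4, sigma2_e = 1)
  vc1 <- fixed_vc(sigma2_u = 1.0, sigma2_e = 1)
  fit_g <- gblup_predict(k, y, vc = vc1)
  fit_c <- gfblup_predict(kf, kr, y, vc = vc2, method = "combined")
  fit_t <- gfblup_predict(kf, kr, y, vc = vc2, method = "two_kernel")
  expect_lt(max(abs(fit_c$gebv - fit_g$gebv)), 1e-6)
  expect_lt(max(abs(fit_t$gebv - fit_g$gebv)), 1e-6)
})

test_that("the combined-kernel shortcut tracks the exact two-kernel solve", {
  g <- random_genotypes(50, 200, seed = 14)
  keys <- snp_keys(g)
  gf <- build_grm(g, snp_subset = keys[1:40], role = "feature")
  gr <- build_grm(g, snp_subset = keys[41:200], role = "remainder")
  ref <- gf$ids[1:40]
  y <- setNames(rnorm(50), gf$ids)[ref]
  vc <- fixed_vc(sigma2_f = 0.8, sigma2_r = 0.4, sigma2_e = 1)
  fit_c <- gfblup_predict(gf, gr, y, vc = vc, method = "combined")
  fit_t <- gfblup_predict(gf, gr, y, vc = vc, method = "two_kernel")
  expect_equal(fit_c$lambda, 0.8 / 1.2, tolerance = 1e-12)
  # the collapse is an approximation: close, but not identical in general
  expect_gt(cor(fit_c$gebv, fit_t$gebv), 0.98)
})

test_that("cross-validation partitions 651 individuals into 131/130 folds", {
  g <- random_genotypes(651, 120, seed = 15)
  k <- build_grm(g)
  y <- setNames(rnorm(651), k$ids)
  res <- cross_validate(y, k = k, model = "gblup", seed = 7,
                        vc = fixed_vc(sigma2_u = 0.4, sigma2_e = 0.6))
  expect_equal(nrow(res$splits), 25)
  sizes <- sort(res$splits$n_val[res$splits$rep == 1], decreasing = TRUE)
  expect_equal(sizes, c(131, 130, 130, 130, 130))
  expect_equal(sum(res$splits$n_val), 5 * 651)
})

test_that("cross-validation is deterministic given the seed and conserves its summary", {
  g <- random_genotypes(80, 150, seed = 16)
  k <- build_grm(g)
  cfg_y <- rnorm(80, sd = 2)
  y <- setNames(cfg_y, k$ids)
  a <- cross_validate(y, k = k, model = "gblup", n_repeats = 2, seed = 99,
                      vc = fixed_vc(sigma2_u = 1, sigma2_e = 1))
  b <- cross_validate(y, k = k, model = "gblup", n_repeats = 2, seed = 99,
                      vc = fixed_vc(sigma2_u = 1, sigma2_e = 1))
  expect_identical(a$splits, b$splits)
  acc <- a$splits$accuracy
  expect_equal(a$mean_accuracy, mean(acc), tolerance = 1e-12)
  expect_equal(a$se_accuracy, sd(acc) / sqrt(length(acc)), tolerance = 1e-12)
})

test_that("permuted phenotypes predict at chance level", {
  cfg <- sim_config(n_discovery = 150, n_target = 2, n_snps = 600,
                    n_chromosomes = 3, n_qtls = 60, seed = 27)
  g <- simulate_genotypes(cfg)$discovery
  sim <- simulate_phenotypes(g, cfg)
  k <- build_grm(g)
  set.seed(1)
  yperm <- setNames(sample(sim$phenotypes$trait), sim$phenotypes$iid)
  res <- cross_validate(yperm, k = k, model = "gblup", seed = 5,
                        vc = fixed_vc(sigma2_u = 0.1,
                                      sigma2_e = var(yperm)))
  expect_lt(abs(res$mean_accuracy), 2 * res$se_accuracy + 0.05)
})

test_that("GBLUP accuracy at study scale sits in the expected band", {
  cfg <- sim_config(n_discovery = 2, n_target = 651, n_snps = 5000,
                    n_chromosomes = 18, n_qtls = 500, h2_trait = 0.45,
                    seed = 61)
  sim <- simulate_study(cfg)
  g <- sim$target$genotypes
  k <- build_grm(g)
  ph <- correct_phenotypes(sim$target$phenotypes, k)
  y <- setNames(ph$corrected, ph$iid)
  res <- cross_validate(y, k = k, model = "gblup", seed = 3)
  expect_gt(res$mean_accuracy, 0.30)
  expect_lt(res$mean_accuracy, 0.60)
  expect_lt(res$mean_accuracy, sqrt(0.45) + 2 * res$se_accuracy)
})

test_that("degenerate inputs are refused with guidance", {
  g <- random_genotypes(20, 50, seed = 18)
  k <- build_grm(g)
  y <- setNames(rnorm(20), k$ids)
  expect_error(gblup_predict(k, unname(y)), "named")
  empty <- kinship(matrix(0, 0, 0), character(0), 0)
  expect_error(gfblup_predict(empty, empty, y), "empty feature")
  expect_error(cross_validate(y, model = "gblup"), "needs")
})
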