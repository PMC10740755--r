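# Synthetic-data generator: configuration checks, determinism, allele
# frequency and LD behaviour, trait architecture.

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(h2_trait = 1.2), "h2_trait")
  expect_error(sim_config(h2_trait = 0), "h2_trait")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(maf_range = c(0.3, 0.6)), "maf_range")
  expect_error(sim_config(maf_range = c(0, 0.3)), "maf_range")
  expect_error(sim_config(n_qtls = 100, n_snps = 50), "n_qtls")
  expect_error(sim_config(n_discovery = 1), "n_discovery")
})

test_that("a fixed seed reproduces genotypes, phenotypes and truth exactly", {
  cfg <- sim_config(n_discovery = 40, n_target = 30, n_snps = 120,
                    n_chromosomes = 3, n_qtls = 15, seed = 42)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$discovery$genotypes$dosage, b$discovery$genotypes$dosage)
  expect_identical(a$target$genotypes$dosage, b$target$genotypes$dosage)
  expect_identical(a$target$phenotypes, b$target$phenotypes)
  expect_identical(a$discovery$truth, b$discovery$truth)
})

test_that("genotypes are 0/1/2 with no missingness unless requested", {
  cfg <- sim_config(n_discovery = 50, n_target = 50, n_snps = 80,
                    n_chromosomes = 2, n_qtls = 10, seed = 3)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$discovery$dosage %in% 0:2))
  expect_true(all(g$target$dosage %in% 0:2))
  cfg2 <- sim_config(n_discovery = 50, n_target = 50, n_snps = 80,
                     n_chromosomes = 2, n_qtls = 10, seed = 3,
                     missing_rate = 0.1)
  g2 <- simulate_genotypes(cfg2)
  miss <- mean(is.na(g2$discovery$dosage))
  expect_gt(miss, 0.05)
  expect_lt(miss, 0.15)
})

test_that("ld_rho = 0 gives independent adjacent loci; ld_rho > 0 does not", {
  cfg0 <- sim_config(n_discovery = 2000, n_target = 2, n_snps = 50,
                     n_chromosomes = 1, n_qtls = 5, ld_rho = 0, seed = 11)
  X <- simulate_genotypes(cfg0)$discovery$dosage
  r0 <- sapply(seq_len(ncol(X) - 1), function(j) cor(X[, j], X[, j + 1]))
  expect_lt(mean(abs(r0)), 0.05)
  expect_lt(max(abs(r0)), 0.1)

  cfg1 <- sim_config(n_discovery = 2000, n_target = 2, n_snps = 50,
                     n_chromosomes = 1, n_qtls = 5, ld_rho = 0.8, seed = 11)
  X1 <- simulate_genotypes(cfg1)$discovery$dosage
  r1 <- sapply(seq_len(ncol(X1) - 1), function(j) cor(X1[, j], X1[, j + 1]))
  expect_gt(mean(r1), 0.3)
})

test_that("empirical MAF tracks the configured window", {
  cfg <- sim_config(n_discovery = 5000, n_target = 2, n_snps = 100,
                    n_chromosomes = 2, n_qtls = 5,
                    maf_range = c(0.3, 0.3), seed = 5)
  X <- simulate_genotypes(cfg)$discovery$dosage
  maf <- pmin(colMeans(X) / 2, 1 - colMeans(X) / 2)
  expect_true(all(abs(maf - 0.3) < 0.02))
})

test_that("cohorts share the base allele-frequency spectrum", {
  cfg <- sim_config(n_discovery = 500, n_target = 500, n_snps = 300,
                    n_chromosomes = 4, n_qtls = 20, seed = 9)
  g <- simulate_genotypes(cfg)
  fd <- colMeans(g$discovery$dosage) / 2
  ft <- colMeans(g$target$dosage) / 2
  expect_gt(cor(fd, ft), 0.9)
})

test_that("in the noise-free limit the genetic part recovers the breeding values", {
  cfg <- sim_config(n_discovery = 200, n_target = 2, n_snps = 150,
                    n_chromosomes = 2, n_qtls = 30, h2_trait = 0.9999,
                    seed = 21)
  g <- simulate_genotypes(cfg)$discovery
  sim <- simulate_phenotypes(g, cfg)
  ph <- sim$phenotypes
  fixed <- cfg$trait_mean + cfg$sex_effect * ph$sex +
    cfg$age_slope * (ph$age - mean(cfg$age_range))
  expect_gt(cor(ph$trait - fixed, sim$truth$true_breeding_values), 0.999)
  expect_gt(sim$truth$realized_h2, 0.999)
})

test_that("realized heritability converges to the target at large n", {
  cfg <- sim_config(n_discovery = 5000, n_target = 2, n_snps = 2000,
                    n_chromosomes = 10, n_qtls = 200, h2_trait = 0.45,
                    seed = 13)
  g <- simulate_genotypes(cfg)$discovery
  sim <- simulate_phenotypes(g, cfg)
  expect_lt(abs(sim$truth$realized_h2 - 0.45), 0.05)
  expect_length(sim$truth$qtl_keys, 200)
  expect_length(sim$truth$qtl_effects, 200)
  expect_length(sim$truth$true_breeding_values, 5000)
})

test_that("partially shared QTL architectures share keys and effects", {
  cfg <- sim_config(n_discovery = 60, n_target = 60, n_snps = 200,
                    n_chromosomes = 2, n_qtls = 40,
                    prop_shared_qtl = 0.5, seed = 17)
  sim <- simulate_study(cfg)
  shared <- intersect(sim$discovery$truth$qtl_keys, sim$target$truth$qtl_keys)
  expect_length(shared, 20)
  i <- match(shared, sim$discovery$truth$qtl_keys)
  j <- match(shared, sim$target$truth$qtl_keys)
  expect_equal(sim$discovery$truth$qtl_effects[i],
               sim$target$truth$qtl_effects[j])
})

test_that("withholding QTLs removes them from the typed panel only", {
  cfg <- sim_config(n_discovery = 40, n_target = 40, n_snps = 150,
                    n_chromosomes = 2, n_qtls = 20, qtl_in_panel = FALSE,
                    seed = 19)
  sim <- simulate_study(cfg)
  expect_length(intersect(sim$target$truth$qtl_keys,
                          snp_keys(sim$target$genotypes)), 0)
  expect_equal(ncol(sim$target$genotypes$dosage), 130)
})

test_that("truth records round-trip through their TSV sidecars", {
  cfg <- sim_config(n_discovery = 30, n_target = 2, n_snps = 60,
                    n_chromosomes = 2, n_qtls = 8, seed = 23)
  g <- simulate_genotypes(cfg)$discovery
  truth <- simulate_phenotypes(g, cfg)$truth
  prefix <- file.path(tempdir(), "truth")
  write_truth(truth, prefix)
  back <- read_truth(prefix)
  expect_equal(back$qtl_keys, truth$qtl_keys)
  expect_equal(back$qtl_effects, truth$qtl_effects, tolerance = 1e-12)
  expect_equal(back$true_breeding_values, truth$true_breeding_values,
               tolerance = 1e-12)
  expect_equal(back$realized_h2, truth$realized_h2, tolerance = 1e-12)
})

test_that("loin muscle area follows the caliper formula", {
  expect_equal(loin_muscle_area(10, 5), 35.0)
  expect_equal(loin_muscle_area(3, 7), loin_muscle_area(7, 3))
  expect_error(loin_muscle_area(0, 5), "positive")
  expect_error(loin_muscle_area(10, -1), "positive")
})
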