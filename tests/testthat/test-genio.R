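# PLINK binary round-trips, the exact Hardy-Weinberg test and quality
# control.

test_that("write_plink / read_plink round-trips dosage and metadata", {
  cfg <- sim_config(n_discovery = 37, n_target = 2, n_snps = 60,
                    n_chromosomes = 3, n_qtls = 5, seed = 4,
                    missing_rate = 0.05)
  g <- simulate_genotypes(cfg)$discovery
  prefix <- file.path(tempdir(), "rt")
  write_plink(g, prefix)
  g2 <- read_plink(prefix)
  expect_equal(unname(g2$dosage), unname(g$dosage))
  expect_equal(g2$snp_meta$key, g$snp_meta$key)
  expect_equal(g2$sample_meta$iid, g$sample_meta$iid)
  expect_equal(g2$sample_meta$sex, g$sample_meta$sex)
})

test_that("a hand-encoded bed fileset decodes to the hand-decoded matrix", {
  # 3 individuals x 2 SNPs, SNP-major, one byte per SNP.
  # SNP1 dosages (0, 1, NA) -> 2-bit codes 00, 10, 01 -> byte 00|01|10|00
  # SNP2 dosages (2, 2, 0)  -> codes 11, 11, 00      -> byte 00|00|11|11
  prefix <- file.path(tempdir(), "hand")
  writeBin(as.raw(c(0x6C, 0x1B, 0x01, 0x18, 0x0F)), paste0(prefix, ".bed"))
  writeLines(c("1\ts1\t0\t100\tA\tC", "1\ts2\t0\t200\tG\tT"),
             paste0(prefix, ".bim"))
  writeLines(c("f1\ti1\t0\t0\t1\t-9", "f2\ti2\t0\t0\t2\t-9",
               "f3\ti3\t0\t0\t1\t-9"), paste0(prefix, ".fam"))
  g <- read_plink(prefix)
  expect_equal(unname(g$dosage),
               matrix(c(0, 1, NA, 2, 2, 0), nrow = 3))
  expect_equal(g$snp_meta$key, c("1:100:A:C", "1:200:G:T"))
})

test_that("corrupt bed files are rejected", {
  g <- random_genotypes(8, 5)
  prefix <- file.path(tempdir(), "bad")
  write_plink(g, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 1e6)
  writeBin(raw[-length(raw)], paste0(prefix, ".bed"))   # truncate
  expect_error(read_plink(prefix), "corrupt")
  writeBin(as.raw(c(0x00, 0x1B, 0x01)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
})

test_that("phenotype tables round-trip through TSV", {
  ph <- data.frame(iid = c("a1", "a2"), trait = c(11.5, 12.1),
                   sex = c(0L, 1L), age = c(160.2, 171.5))
  path <- file.path(tempdir(), "ph.tsv")
  write_phenotypes(ph, path)
  expect_equal(read_phenotypes(path), ph)
})

test_that("Hardy-Weinberg exact test matches enumeration and its boundaries", {
  # Observed heterozygote count at the conditional mode: full mass.
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  # Total heterozygote deficit at 50/50 alleles: far beyond the QC cutoff.
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  # Monomorphic: a single possible configuration.
  expect_equal(hwe_exact_test(17, 0, 0), 1.0)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")

  # Cross-check one moderate case against a direct enumeration over
  # genotype configurations written with choose().
  hom1 <- 6; het <- 3; hom2 <- 5
  n <- hom1 + het + hom2; r <- 2 * min(hom1, hom2) + het
  hs <- seq(r %% 2, min(r, 2 * n - r), by = 2)
  probs <- sapply(hs, function(h) {
    choose(n, (r - h) / 2) * choose(n - (r - h) / 2, h) * 2^h /
      choose(2 * n, r) * choose(n - (r - h) / 2 - h, (2 * n - r - h) / 2)
  })
  probs <- probs / sum(probs)
  obs <- probs[match(het, hs)]
  expect_equal(hwe_exact_test(hom1, het, hom2),
               sum(probs[probs <= obs * (1 + 1e-10)]),
               tolerance = 1e-12)
})

test_that("the exact test is symmetric in the homozygote classes and in (0,1]", {
  set.seed(2)
  for (i in 1:25) {
    cnt <- rmultinom(1, 40, c(0.25, 0.5, 0.25))
    p1 <- hwe_exact_test(cnt[1], cnt[2], cnt[3])
    p2 <- hwe_exact_test(cnt[3], cnt[2], cnt[1])
    expect_equal(p1, p2)
    expect_gt(p1, 0)
    expect_lte(p1, 1)
  }
})

test_that("QC removes the forced cases and reconciles its counts", {
  set.seed(8)
  n <- 200
  X <- sapply(runif(18, 0.2, 0.4), function(p) rbinom(n, 2, p))
  # SNP 19: MAF 0.005 (2 copies in 400 alleles), all else clean
  X <- cbind(X, c(rep(1, 2), rep(0, n - 2)))
  # SNP 20: gross heterozygote deficit -> HWE failure
  X <- cbind(X, rep(c(0, 2), each = n / 2))
  g <- toy_genotypes(X)
  # individual 1 misses 15% of genotypes (call rate 0.85 < 0.90)
  g$dosage[1, 1:3] <- NA
  res <- apply_qc(g)
  rep_ <- res$report
  expect_equal(rep_$n_individuals_removed, 1)
  expect_equal(rep_$n_snps_removed_maf, 1)
  expect_equal(rep_$n_snps_removed_hwe, 1)
  expect_false("id1" %in% res$genotypes$sample_meta$iid)
  with(rep_, expect_equal(
    n_snps_removed_callrate + n_snps_removed_maf + n_snps_removed_hwe +
      n_snps_removed_sexchrom_or_uninformative + n_snps_retained,
    n_snps_input))
})

test_that("QC drops sex chromosomes and is idempotent", {
  set.seed(12)
  X <- sapply(runif(30, 0.2, 0.4), function(p) rbinom(150, 2, p))
  g <- toy_genotypes(X, chrom = c(rep("1", 25), rep("X", 5)))
  res <- apply_qc(g)
  expect_equal(res$report$n_snps_removed_sexchrom_or_uninformative, 5)
  expect_false(any(res$genotypes$snp_meta$chrom == "X"))
  res2 <- apply_qc(res$genotypes)
  expect_equal(res2$genotypes$dosage, res$genotypes$dosage)
  expect_equal(res2$report$n_individuals_removed, 0)
  expect_equal(res2$report$n_snps_retained, res$report$n_snps_retained)
})

test_that("a panel simulated under HWE almost never fails the HWE filter", {
  set.seed(33)
  n <- 1000
  X <- sapply(runif(500, 0.05, 0.5), function(p) rbinom(n, 2, p))
  g <- toy_genotypes(X)
  res <- apply_qc(g)
  expect_lte(res$report$n_snps_removed_hwe / 500, 0.001)
})

test_that("GRM text format round-trips", {
  g <- random_genotypes(12, 40, seed = 5)
  k <- build_grm(g)
  path <- file.path(tempdir(), "g.grm.gz")
  write_grm(k, path)
  k2 <- read_grm(path)
  expect_equal(k2$matrix, k$matrix, tolerance = 1e-6)
  expect_equal(k2$ids, k$ids)
  expect_equal(k2$n_snps_used, k$n_snps_used)
})
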