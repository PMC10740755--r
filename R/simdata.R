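# Synthetic two-cohort genotype/phenotype generator with known QTL
# architecture. Emulates the study design the package targets: a discovery
# cohort scanned by GWAS and a separate reference/validation cohort on
# which prediction accuracy is cross-validated.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the package was built around: a
#' 685-individual discovery cohort and a 651-individual
#' reference/validation cohort sharing a base allele-frequency spectrum
#' and QTL architecture, a moderately heritable trait (h-squared 0.45) on
#' the scale of loin muscle area (mean ~40 cm^2, SD ~4.9), and sex/age
#' fixed effects.
#'
#' @param n_discovery,n_target cohort sizes.
#' @param n_snps,n_chromosomes,n_qtls panel size, chromosome count (pig
#'   autosomes: 18), number of causal SNPs.
#' @param h2_trait narrow-sense heritability in (0, 1).
#' @param maf_range (low, high) in (0, 0.5]: per-SNP minor allele
#'   frequencies are drawn uniformly from this window.
#' @param ld_rho adjacent-locus haplotype correlation in \[0, 1) of the
#'   first-order Gaussian-copula Markov model used for local LD. The
#'   default 0.99 reproduces the strong local LD of dense (imputed)
#'   panels in livestock populations with small effective size: it leaves
#'   on the order of a few hundred effectively independent chromosome
#'   segments at the default panel size, the regime in which genomic
#'   prediction operates in commercial pig lines.
#' @param prop_shared_qtl fraction of QTLs (keys and effects) shared
#'   between the two cohorts' trait architectures.
#' @param seed RNG seed; identical configs give byte-identical output.
#' @param trait_mean,trait_var phenotype intercept and target phenotypic
#'   variance on the trait scale.
#' @param sex_effect additive fixed effect of sex (coded 0/1, balanced).
#' @param age_range,age_slope age window in days (uniform) and fixed
#'   regression of trait on age.
#' @param qtl_in_panel keep causal SNPs in the genotyped panel (default);
#'   if `FALSE` they are withheld, mimicking untyped causal variants.
#' @param missing_rate per-genotype missingness rate (default 0; only used
#'   to exercise quality control).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_discovery = 685, n_target = 651, n_snps = 5000,
                       n_chromosomes = 18, n_qtls = 200, h2_trait = 0.45,
                       maf_range = c(0.05, 0.5), ld_rho = 0.99,
                       prop_shared_qtl = 1.0, seed = 1L,
                       trait_mean = 40.3, trait_var = 24.3,
                       sex_effect = 2.0, age_range = c(140, 220),
                       age_slope = 0.05, qtl_in_panel = TRUE,
                       missing_rate = 0) {
  if (!is_count(n_discovery) || n_discovery < 2)
    stop_field("n_discovery", "must be an integer >= 2")
  if (!is_count(n_target) || n_target < 2)
    stop_field("n_target", "must be an integer >= 2")
  if (!is_count(n_snps) || n_snps < 1)
    stop_field("n_snps", "must be a positive integer")
  if (!is_count(n_chromosomes) || n_chromosomes < 1 || n_chromosomes > n_snps)
    stop_field("n_chromosomes", "must be a positive integer <= n_snps")
  if (!is_count(n_qtls) || n_qtls < 0 || n_qtls > n_snps)
    stop_field("n_qtls", "must be an integer in [0, n_snps]")
  if (!is.numeric(h2_trait) || h2_trait <= 0 || h2_trait >= 1)
    stop_field("h2_trait", "must lie strictly between 0 and 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 ||
      maf_range[1] > maf_range[2] || maf_range[2] > 0.5)
    stop_field("maf_range", "needs 0 < low <= high <= 0.5")
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1)
    stop_field("ld_rho", "must lie in [0, 1)")
  if (prop_shared_qtl < 0 || prop_shared_qtl > 1)
    stop_field("prop_shared_qtl", "must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_field("missing_rate", "must lie in [0, 1)")
  structure(list(n_discovery = n_discovery, n_target = n_target,
                 n_snps = n_snps, n_chromosomes = n_chromosomes,
                 n_qtls = n_qtls, h2_trait = h2_trait,
                 maf_range = maf_range, ld_rho = ld_rho,
                 prop_shared_qtl = prop_shared_qtl, seed = as.integer(seed),
                 trait_mean = trait_mean, trait_var = trait_var,
                 sex_effect = sex_effect, age_range = age_range,
                 age_slope = age_slope, qtl_in_panel = qtl_in_panel,
                 missing_rate = missing_rate),
            class = "sim_config")
}

# Haplotypes under a first-order Gaussian-copula Markov chain: a latent
# AR(1) process with lag-one correlation rho is thresholded at qnorm(p_j)
# per locus, giving local LD that decays geometrically with distance.
.sim_haplotypes <- function(n_hap, p, chrom, rho) {
  m <- length(p)
  H <- matrix(0L, n_hap, m)
  thr <- stats::qnorm(p)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    z <- stats::rnorm(n_hap)
    H[, idx[1]] <- as.integer(z < thr[idx[1]])
    if (length(idx) > 1) {
      sdr <- sqrt(1 - rho^2)
      for (j in idx[-1]) {
        z <- rho * z + sdr * stats::rnorm(n_hap)
        H[, j] <- as.integer(z < thr[j])
      }
    }
  }
  H
}

.sim_panel_meta <- function(config) {
  m <- config$n_snps
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- cumsum(sample(1000:5000, length(idx), replace = TRUE))
  }
  pairs <- t(vapply(seq_len(m), function(i) sample(c("A", "C", "G", "T"), 2),
                    character(2)))
  data.frame(chrom = as.character(chrom), pos = pos,
             id = paste0("snp", seq_len(m)),
             a1 = pairs[, 1], a2 = pairs[, 2])
}

.sim_cohort <- function(n, prefix, meta, p, config) {
  H1 <- .sim_haplotypes(n, p, meta$chrom, config$ld_rho)
  H2 <- .sim_haplotypes(n, p, meta$chrom, config$ld_rho)
  dosage <- H1 + H2
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(dosage)) < config$missing_rate
    dosage[drop] <- NA_integer_
  }
  sex <- sample(rep_len(c(0L, 1L), n))
  genotype_data(dosage, meta,
                data.frame(iid = sprintf("%s%04d", prefix, seq_len(n)),
                           sex = sex))
}

#' Simulate two cohorts of genotypes
#'
#' Draws per-SNP allele frequencies uniformly from `maf_range` once (the
#' shared base population) and then samples haplotypes for the discovery
#' and target cohorts independently from that spectrum, with first-order
#' Markov LD along each chromosome (see [sim_config()]). Each genotype is
#' the sum of two haplotypes; dosage counts the `a2` allele, whose
#' frequency is the drawn (minor) frequency.
#'
#' @param config a [sim_config()] object.
#' @return list with `discovery` and `target` (`genotype_data` sharing the
#'   same SNP panel) and `freq`, the base-population `a2` frequencies.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    meta <- .sim_panel_meta(config)
    p <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    disc <- .sim_cohort(config$n_discovery, "D", meta, p, config)
    targ <- .sim_cohort(config$n_target, "T", meta, p, config)
    list(discovery = disc, target = targ, freq = p)
  })
}

#' Simulate phenotypes over a genotype cohort
#'
#' Generates `y = intercept + sex_effect*sex + age_slope*(age - mean age)
#' + sum_q a_q x_q + e`. QTL effects are i.i.d. normal, scaled so the
#' genetic variance is `h2_trait * trait_var` in expectation, and the
#' residual variance is set from the empirically realized genetic variance
#' so that the genetic/(genetic+residual) ratio equals `h2_trait` in
#' expectation.
#'
#' @param genotypes a `genotype_data` cohort.
#' @param config a [sim_config()] object.
#' @param qtl optional list with `keys` and `effects` to reuse an existing
#'   architecture (e.g. to share QTLs across cohorts); drawn at random
#'   when `NULL`.
#' @param seed RNG seed (default derived from `config$seed`).
#' @return list with `phenotypes` (data.frame `iid`, `trait`, `sex`,
#'   `age`) and `truth` (class `truth_record`: `qtl_keys`, `qtl_effects`,
#'   `true_breeding_values`, `realized_h2`).
#' @export
simulate_phenotypes <- function(genotypes, config, qtl = NULL,
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes$dosage)
  if (n == 0) stop("genotype cohort is empty")
  if (config$n_qtls == 0 && is.null(qtl))
    stop_field("n_qtls", "cannot be 0 when h2_trait > 0")
  with_seed(seed, {
    keys <- snp_keys(genotypes)
    if (is.null(qtl)) {
      qidx <- sort(sample(length(keys), config$n_qtls))
      qtl <- list(keys = keys[qidx], effects = stats::rnorm(config$n_qtls))
      # scale effects so E[var(g)] = h2 * trait_var
      p <- colMeans(genotypes$dosage[, qidx, drop = FALSE], na.rm = TRUE) / 2
      evg <- sum(2 * p * (1 - p))
      qtl$effects <- qtl$effects *
        sqrt(config$h2_trait * config$trait_var / max(evg, 1e-12))
    }
    qidx <- match(qtl$keys, keys)
    if (anyNA(qidx)) stop("QTL keys not present in the genotype panel")
    X <- genotypes$dosage[, qidx, drop = FALSE]
    if (anyNA(X)) {            # mean-impute for the genetic value
      pm <- colMeans(X, na.rm = TRUE)
      for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- pm[j]
    }
    g <- as.vector(X %*% qtl$effects)
    var_g <- stats::var(g)
    var_e <- var_g * (1 - config$h2_trait) / config$h2_trait
    e <- stats::rnorm(n, 0, sqrt(var_e))
    sex <- genotypes$sample_meta$sex
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    y <- config$trait_mean + config$sex_effect * sex +
      config$age_slope * (age - mean(config$age_range)) + g + e
    truth <- structure(list(qtl_keys = qtl$keys, qtl_effects = qtl$effects,
                            true_breeding_values = stats::setNames(
                              g, genotypes$sample_meta$iid),
                            realized_h2 = var_g / stats::var(g + e)),
                       class = "truth_record")
    list(phenotypes = data.frame(iid = genotypes$sample_meta$iid,
                                 trait = y, sex = sex, age = age),
         truth = truth)
  })
}

#' Simulate a full two-cohort study
#'
#' Genotypes for both cohorts plus phenotypes with a QTL architecture
#' shared across cohorts according to `prop_shared_qtl`: that fraction of
#' the discovery QTLs (keys and effects) also acts in the target cohort;
#' the remainder of the target's QTLs are redrawn.
#'
#' @param config a [sim_config()] object.
#' @return list with `discovery` and `target`, each holding `genotypes`,
#'   `phenotypes` and `truth`, plus the base `freq`.
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config)
  disc <- simulate_phenotypes(geno$discovery, config, seed = config$seed + 1L)
  n_shared <- round(config$prop_shared_qtl * config$n_qtls)
  qtl_t <- with_seed(config$seed + 2L, {
    keys <- disc$truth$qtl_keys
    eff <- disc$truth$qtl_effects
    if (n_shared < config$n_qtls) {
      keep <- sort(sample(config$n_qtls, n_shared))
      pool <- setdiff(snp_keys(geno$target), keys)
      fresh <- sample(pool, config$n_qtls - n_shared)
      keys <- c(keys[keep], fresh)
      eff <- c(eff[keep], stats::rnorm(config$n_qtls - n_shared,
                                       sd = stats::sd(eff)))
    }
    list(keys = keys, effects = eff)
  })
  targ <- simulate_phenotypes(geno$target, config, qtl = qtl_t,
                              seed = config$seed + 3L)
  if (!config$qtl_in_panel) {   # withhold causal SNPs from the typed panel
    all_q <- union(disc$truth$qtl_keys, qtl_t$keys)
    geno$discovery <- subset_genotypes(
      geno$discovery, snps = setdiff(snp_keys(geno$discovery), all_q))
    geno$target <- subset_genotypes(
      geno$target, snps = setdiff(snp_keys(geno$target), all_q))
  }
  list(discovery = list(genotypes = geno$discovery,
                        phenotypes = disc$phenotypes, truth = disc$truth),
       target = list(genotypes = geno$target,
                     phenotypes = targ$phenotypes, truth = targ$truth),
       freq = geno$freq)
}

#' Write / read a simulation truth record as TSV sidecars
#'
#' `<prefix>.qtl.tsv` holds the QTL keys and effects; `<prefix>.tbv.tsv`
#' the per-individual true breeding values and the realized heritability.
#'
#' @param truth a `truth_record` from [simulate_phenotypes()].
#' @param prefix output path prefix.
#' @return `write_truth`: `prefix` invisibly; `read_truth`: a
#'   `truth_record`.
#' @export
write_truth <- function(truth, prefix) {
  utils::write.table(
    data.frame(key = truth$qtl_keys, effect = truth$qtl_effects),
    paste0(prefix, ".qtl.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(iid = names(truth$true_breeding_values),
               tbv = as.numeric(truth$true_breeding_values),
               realized_h2 = truth$realized_h2),
    paste0(prefix, ".tbv.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_truth
#' @export
read_truth <- function(prefix) {
  qtl <- utils::read.delim(paste0(prefix, ".qtl.tsv"),
                           colClasses = c(key = "character"))
  tbv <- utils::read.delim(paste0(prefix, ".tbv.tsv"),
                           colClasses = c(iid = "character"))
  structure(list(qtl_keys = qtl$key, qtl_effects = qtl$effect,
                 true_breeding_values = stats::setNames(tbv$tbv, tbv$iid),
                 realized_h2 = tbv$realized_h2[1]),
            class = "truth_record")
}

#' Loin muscle area from cross-sectional calipers
#'
#' The standard carcass approximation: area (cm^2) = height x width x 0.7,
#' from the maximum height and width of the longissimus dorsi
#' cross-section at the last rib.
#'
#' @param height,width caliper measurements in cm; must be positive.
#' @return area in cm^2.
#' @export
loin_muscle_area <- function(height, width) {
  if (any(height <= 0) || any(width <= 0))
    stop("height and width must be positive")
  height * width * 0.7
}
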