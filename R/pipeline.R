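# End-to-end study pipeline on synthetic data: simulate two cohorts, QC,
# discovery GWAS, SNP preselection, and cross-validated GBLUP/GFBLUP
# accuracy in the target cohort.

#' Run the full genomic-feature prediction study
#'
#' Simulates a discovery and a target cohort ([simulate_study()]), applies
#' quality control, corrects phenotypes for sex, age and the leading GRM
#' principal components, scans the discovery cohort by MLMA, preselects
#' SNPs at the p-value bins and intersects them with the target panel, and
#' finally cross-validates GBLUP (all SNPs) against GFBLUP (feature +
#' remainder kernels) per bin in the target cohort. Bins whose feature set
#' is empty, or that leave no remainder SNPs, are skipped with a note.
#'
#' @param config a [sim_config()].
#' @param thresholds p-value bins for preselection.
#' @param cv_seed seed for the cross-validation partitions.
#' @param n_folds,n_repeats cross-validation scheme.
#' @param n_pc principal components used in phenotype correction.
#' @return list with `sim` (simulated study incl. truth), `qc` (per-cohort
#'   reports), `assoc` (discovery scan), `features` (per-bin
#'   `feature_set`s), `feature_table` (per-bin SNP counts),
#'   `cv` (named `cv_result`s) and `accuracy_table` (model x bin, mean and
#'   SE over the 25 splits).
#' @export
run_study <- function(config = sim_config(),
                      thresholds = c(0.05, 0.005, 0.0005, 0.00005),
                      cv_seed = config$seed + 10L, n_folds = 5,
                      n_repeats = 5, n_pc = 3) {
  sim <- simulate_study(config)

  qc_d <- apply_qc(sim$discovery$genotypes)
  qc_t <- apply_qc(sim$target$genotypes)
  gd <- qc_d$genotypes
  gt <- qc_t$genotypes

  # discovery: GRM, phenotype correction, MLMA scan
  grm_d <- build_grm(gd)
  ph_d <- sim$discovery$phenotypes
  ph_d <- ph_d[ph_d$iid %in% gd$sample_meta$iid, ]
  ph_d <- correct_phenotypes(ph_d, grm_d, n_pc = n_pc)
  y_d <- stats::setNames(ph_d$corrected, ph_d$iid)
  assoc <- mlma_scan(gd, y_d, grm_d)

  # feature definition against the target panel
  fsets <- feature_sets(assoc, gt, thresholds)
  ftab <- feature_report(fsets)

  # target: GRM, phenotype correction, cross-validated prediction
  grm_t <- build_grm(gt)
  ph_t <- sim$target$phenotypes
  ph_t <- ph_t[ph_t$iid %in% gt$sample_meta$iid, ]
  ph_t <- correct_phenotypes(ph_t, grm_t, n_pc = n_pc)
  y_t <- stats::setNames(ph_t$corrected, ph_t$iid)

  cv <- list(GBLUP = cross_validate(y_t, k = grm_t, model = "gblup",
                                    n_folds = n_folds,
                                    n_repeats = n_repeats, seed = cv_seed))
  all_keys <- snp_keys(gt)
  for (nm in names(fsets)) {
    fk <- fsets[[nm]]$feature_keys
    rk <- setdiff(all_keys, fk)
    if (!length(fk) || !length(rk)) {
      message("skipping GFBLUP at ", nm,
              ": empty feature or remainder set")
      next
    }
    gf <- build_grm(gt, snp_subset = fk, role = "feature")
    gr <- build_grm(gt, snp_subset = rk, role = "remainder")
    cv[[paste("GFBLUP", nm)]] <- cross_validate(
      y_t, gf = gf, gr = gr, model = "gfblup", n_folds = n_folds,
      n_repeats = n_repeats, seed = cv_seed)
  }

  list(sim = sim, qc = list(discovery = qc_d$report, target = qc_t$report),
       assoc = assoc, features = fsets, feature_table = ftab,
       cv = cv, accuracy_table = cv_report(cv))
}
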