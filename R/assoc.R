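# Mixed-linear-model single-SNP association scan with the polygenic
# variance fixed from the null model, plus the genomic-inflation factor.

#' Mixed-model association scan (MLMA)
#'
#' Fits the null model `y = 1 mu + g + e`, `g ~ N(0, G sigma2_g)`, once by
#' REML, then fixes `V = G sigma2_g + I sigma2_e` and tests each SNP by
#' generalized least squares with the mean projected out:
#' `b_hat = x'Py / x'Px`, `se = 1/sqrt(x'Px)`, Wald chi-squared(1)
#' p-value. `V^-1` is formed once and reused across SNPs; the candidate
#' SNP stays in the GRM (no leave-one-chromosome-out). Missing dosages are
#' mean-imputed per SNP; zero-variance SNPs are flagged untestable rather
#' than dropped.
#'
#' @param g a `genotype_data` panel to scan.
#' @param pheno named numeric vector of (corrected) phenotypes; names are
#'   iids present in `g` and `k`.
#' @param k `kinship` built from the scan panel (accounts for
#'   relatedness/structure).
#' @param vc optional `variance_components` to reuse instead of fitting
#'   the null model (e.g. to force `sigma2_g = 0`).
#' @return data.frame of class `assoc_table` with columns `chrom`, `snp`,
#'   `pos`, `a1`, `a2`, `key`, `freq`, `b`, `se`, `p`, `testable`;
#'   attributes `sigma2_g`, `sigma2_e`, `n`.
#' @export
mlma_scan <- function(g, pheno, k, vc = NULL) {
  ids <- names(pheno)
  if (is.null(ids)) stop("pheno must be named by individual id")
  gi <- match(ids, g$sample_meta$iid)
  if (anyNA(gi)) stop("phenotyped ids missing from the genotype panel")
  kk <- subset_kinship(k, ids)
  y <- as.numeric(pheno)
  n <- length(y)
  if (is.null(vc)) {
    vc <- estimate_reml(mixed_model_spec(pheno, kernels = list(g = kk)))
  }
  s2g <- vc$components[[1]]
  s2e <- vc$components[["sigma2_e"]]
  V <- s2g * kk$matrix + diag(s2e, n)
  Vinv <- chol2inv(chol(V))
  one <- rep(1, n)
  Vinv1 <- Vinv %*% one
  P <- Vinv - Vinv1 %*% t(Vinv1) / sum(Vinv1)
  Py <- as.vector(P %*% y)

  X <- g$dosage[gi, , drop = FALSE]
  storage.mode(X) <- "double"
  freq <- colMeans(X, na.rm = TRUE) / 2
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- 2 * freq[j]
  }
  testable <- apply(X, 2, stats::var) > 0
  xPy <- as.vector(crossprod(X, Py))
  xPx <- colSums(X * (P %*% X))
  xPx[!testable | xPx <= 0] <- NA_real_
  testable <- testable & !is.na(xPx)
  b <- xPy / xPx
  se <- 1 / sqrt(xPx)
  chisq <- b^2 * xPx
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  out <- data.frame(chrom = g$snp_meta$chrom, snp = g$snp_meta$id,
                    pos = g$snp_meta$pos, a1 = g$snp_meta$a1,
                    a2 = g$snp_meta$a2, key = snp_keys(g),
                    freq = freq, b = b, se = se, p = p,
                    testable = testable)
  attr(out, "sigma2_g") <- s2g
  attr(out, "sigma2_e") <- s2e
  attr(out, "n") <- n
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Write an association table (GCTA .mlma-style TSV)
#'
#' @param tab an `assoc_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assoc <- function(tab, path) {
  out <- data.frame(Chr = tab$chrom, SNP = tab$snp, bp = tab$pos,
                    A1 = tab$a1, A2 = tab$a2, Freq = tab$freq,
                    b = tab$b, se = tab$se, p = tab$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Genomic inflation factor
#'
#' `lambda_gc` = median Wald chi-squared over the null median
#' (`qchisq(0.5, 1)` = 0.4549); values near 1 indicate a calibrated scan.
#'
#' @param tab an `assoc_table` with at least 100 tested SNPs.
#' @return `lambda_gc` as a number.
#' @export
genomic_inflation <- function(tab) {
  p <- tab$p[tab$testable & !is.na(tab$p)]
  if (length(p) < 100)
    stop("need at least 100 tested SNPs to estimate inflation")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}
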