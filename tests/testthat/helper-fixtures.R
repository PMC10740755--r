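# Small fixtures built in code.

# Hand-assembled genotype panel from a dosage matrix; metadata generated
# to be valid (one chromosome, increasing positions, A/C alleles).
toy_genotypes <- function(dosage, chrom = NULL) {
  m <- ncol(dosage); n <- nrow(dosage)
  genotype_data(dosage,
                snp_meta = data.frame(
                  chrom = if (is.null(chrom)) rep("1", m) else chrom,
                  pos = seq_len(m) * 1000L,
                  id = paste0("rs", seq_len(m)),
                  a1 = rep("A", m), a2 = rep("C", m)),
                sample_meta = data.frame(iid = paste0("id", seq_len(n)),
                                         sex = rep_len(c(0L, 1L), n)))
}

# Random valid panel: binomial dosages at given frequencies.
random_genotypes <- function(n, m, p = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  toy_genotypes(sapply(seq_len(m), function(j) rbinom(n, 2, p[j])))
}

# A small simulated instance for REML tests: y = Xb + u + e over a dense
# relationship matrix (generated from markers so it is PSD).
tiny_mixed_instance <- function(n = 20, m = 60, s2g = 2, s2e = 1,
                                seed = 1, p_fixed = 1) {
  set.seed(seed)
  # uncentered standard-normal markers: K is well-conditioned (smallest
  # eigenvalue bounded away from zero for m > n), so the restricted
  # likelihood is numerically well-defined over the whole parameter space
  W <- matrix(rnorm(n * m), n, m)
  K <- tcrossprod(W) / m
  K <- (K + t(K)) / 2
  X <- matrix(1, n, 1)
  if (p_fixed > 1) X <- cbind(X, matrix(rnorm(n * (p_fixed - 1)), n))
  L <- t(chol(K))
  y <- as.vector(X %*% rnorm(p_fixed) + sqrt(s2g) * (L %*% rnorm(n)) +
                   rnorm(n, 0, sqrt(s2e)))
  names(y) <- paste0("id", seq_len(n))
  list(y = y, X = X, K = kinship(K, names(y), m))
}
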