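# Genomic relationship matrices and the feature/remainder kernel
# combination used by GFBLUP.

#' Construct a kinship object
#'
#' @param matrix symmetric n x n relationship matrix.
#' @param ids individual ids in row/column order.
#' @param n_snps_used number of SNPs that entered the matrix.
#' @param role one of `"full"`, `"feature"`, `"remainder"`, `"combined"`.
#' @return An object of class `kinship`.
#' @export
kinship <- function(matrix, ids, n_snps_used,
                    role = c("full", "feature", "remainder", "combined")) {
  role <- match.arg(role)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("kinship matrix must be square")
  if (length(ids) != nrow(matrix))
    stop("ids length must match the matrix dimension")
  if (anyDuplicated(ids)) stop("kinship ids must be unique")
  if (length(matrix) && max(abs(matrix - t(matrix))) > 1e-10)
    stop("kinship matrix is not symmetric (tolerance 1e-10)")
  dimnames(matrix) <- list(ids, ids)
  structure(list(matrix = matrix, ids = as.character(ids),
                 n_snps_used = n_snps_used, role = role),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("kinship (%s): %d individuals, %d SNPs used\n",
              x$role, length(x$ids), x$n_snps_used))
  invisible(x)
}

#' Restrict a kinship to a set of individuals
#'
#' @param k a `kinship` object.
#' @param ids individual ids to keep (order preserved as given).
#' @return A `kinship` over the requested ids.
#' @export
subset_kinship <- function(k, ids) {
  i <- match(ids, k$ids)
  if (anyNA(i)) stop("unknown ids in kinship subset")
  kinship(k$matrix[i, i, drop = FALSE], k$ids[i], k$n_snps_used, k$role)
}

#' Build a genomic relationship matrix
#'
#' Default is the GCTA-style single-component estimator:
#' `G_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the m used SNPs, with `p_i` the sample frequency of the counted
#' allele. Missing dosages are mean-imputed (`2 p_i`) before centering;
#' zero-variance SNPs are skipped and m reduced accordingly.
#' `method = "vanraden1"` gives the ratio form
#' `(X - 2P)(X - 2P)' / (2 sum p q)`.
#'
#' @param g a `genotype_data` object with at least two individuals.
#' @param snp_subset optional SNP keys restricting the panel (e.g. a
#'   feature set).
#' @param allele_freq optional named vector of `a2` frequencies (names =
#'   SNP keys) to use instead of the sample frequencies; sharing
#'   frequencies across feature/remainder subsets makes the SNP-weighted
#'   partition identity exact.
#' @param method `"gcta"` (per-SNP standardization, default) or
#'   `"vanraden1"`.
#' @param role stored on the result, see [kinship()].
#' @return A `kinship` object.
#' @export
build_grm <- function(g, snp_subset = NULL, allele_freq = NULL,
                      method = c("gcta", "vanraden1"),
                      role = c("full", "feature", "remainder", "combined")) {
  method <- match.arg(method)
  role <- match.arg(role)
  if (nrow(g$dosage) < 2) stop("need at least two individuals")
  keys <- snp_keys(g)
  if (!is.null(snp_subset)) {
    ci <- which(keys %in% snp_subset)
    if (!length(ci)) stop("empty feature set: no SNPs matched the subset")
  } else ci <- seq_along(keys)
  X <- g$dosage[, ci, drop = FALSE]
  storage.mode(X) <- "double"
  kk <- keys[ci]
  if (!is.null(allele_freq)) {
    p <- allele_freq[kk]
    if (anyNA(p)) stop("allele_freq is missing entries for some SNPs")
    p <- as.numeric(p)
  } else {
    p <- colMeans(X, na.rm = TRUE) / 2
  }
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- 2 * p[j]
  }
  ok <- p > 0 & p < 1
  if (!any(ok)) stop("degenerate panel: no polymorphic SNPs")
  X <- X[, ok, drop = FALSE]; p <- p[ok]
  m <- ncol(X)
  W <- sweep(X, 2, 2 * p, "-")
  if (method == "gcta") {
    W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
    G <- tcrossprod(W) / m
  } else {
    G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  }
  G <- (G + t(G)) / 2
  kinship(G, g$sample_meta$iid, m, role)
}

#' Combine feature and remainder kernels
#'
#' Collapses the two GFBLUP kernels into a single matrix
#' `Gnew = lambda * Gf + (1 - lambda) * Gr` with weight
#' `lambda = sigma2_f / (sigma2_f + sigma2_r)`, so one-kernel BLUP with
#' `Gnew` and total genetic variance `sigma2_f + sigma2_r` approximates
#' the two-kernel model at a fraction of the cost.
#'
#' @param gf,gr `kinship` objects with identical id order (feature and
#'   remainder kernels).
#' @param sigma2_f,sigma2_r non-negative genetic variances attached to the
#'   two kernels; not both zero.
#' @return list with `kinship` (role `"combined"`) and `lambda`.
#' @export
combine_grms <- function(gf, gr, sigma2_f, sigma2_r) {
  if (!identical(gf$ids, gr$ids))
    stop("feature and remainder kinships must share the same id order")
  if (sigma2_f < 0 || sigma2_r < 0)
    stop("variances must be non-negative")
  if (sigma2_f + sigma2_r <= 0)
    stop("degenerate combination: sigma2_f and sigma2_r are both zero")
  lambda <- sigma2_f / (sigma2_f + sigma2_r)
  G <- lambda * gf$matrix + (1 - lambda) * gr$matrix
  list(kinship = kinship(G, gf$ids, gf$n_snps_used + gr$n_snps_used,
                         "combined"),
       lambda = lambda)
}

#' Write / read a GRM in GCTA text format
#'
#' Lower-triangle triplets `i j n_snps value` (tab-separated, optionally
#' gzipped when the path ends in `.gz`) plus an `.id` sidecar.
#'
#' @param k a `kinship` object.
#' @param path output path for the triplet table; `paste0(path, ".id")`
#'   holds the ids.
#' @return `write_grm`: `path` invisibly; `read_grm`: a `kinship`.
#' @export
write_grm <- function(k, path) {
  n <- length(k$ids)
  ij <- which(lower.tri(k$matrix, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  df <- data.frame(i = ij[, 1], j = ij[, 2], m = k$n_snps_used,
                   value = k$matrix[ij])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  writeLines(paste(k$ids, k$ids, sep = "\t"), paste0(path, ".id"))
  invisible(path)
}

#' @rdname write_grm
#' @param role role recorded on the read matrix.
#' @export
read_grm <- function(path, role = "full") {
  ids <- utils::read.table(paste0(path, ".id"),
                           colClasses = "character")[[2]]
  df <- utils::read.table(path)
  n <- length(ids)
  G <- matrix(0, n, n)
  G[cbind(df[[1]], df[[2]])] <- df[[4]]
  G[upper.tri(G)] <- t(G)[upper.tri(G)]
  kinship(G, ids, max(df[[3]]), role)
}
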