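# Genotype container, PLINK bed/bim/fam input/output, phenotype tables and
# quality control.

#' Construct a genotype_data object
#'
#' Container for a dosage matrix (individuals x SNPs, values 0/1/2 or `NA`
#' for missing) together with per-SNP and per-individual metadata. The
#' dosage convention is the count of the *second* listed allele (`a2` in
#' the bim file).
#'
#' @param dosage numeric/integer matrix, individuals in rows, SNPs in
#'   columns; entries in `{0, 1, 2, NA}`.
#' @param snp_meta data.frame with columns `chrom`, `pos` (1-based
#'   base-pair), `id`, `a1`, `a2`; one row per SNP column.
#' @param sample_meta data.frame with columns `iid` (unique) and `sex`
#'   (0/1); one row per dosage row.
#' @return An object of class `genotype_data` with a `key` column added to
#'   `snp_meta` (canonical `chrom:pos:alleleA:alleleB` key, alleles in
#'   alphabetical order).
#' @export
genotype_data <- function(dosage, snp_meta, sample_meta) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(sample_meta))
    stop("dosage has ", nrow(dosage), " rows but sample_meta has ",
         nrow(sample_meta))
  if (ncol(dosage) != nrow(snp_meta))
    stop("dosage has ", ncol(dosage), " columns but snp_meta has ",
         nrow(snp_meta), " rows")
  need <- c("chrom", "pos", "id", "a1", "a2")
  if (!all(need %in% names(snp_meta)))
    stop("snp_meta must have columns ", paste(need, collapse = ", "))
  if (!all(c("iid", "sex") %in% names(sample_meta)))
    stop("sample_meta must have columns iid, sex")
  if (anyDuplicated(sample_meta$iid))
    stop("individual ids must be unique")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA")
  snp_meta$key <- make_snp_keys(snp_meta$chrom, snp_meta$pos,
                                snp_meta$a1, snp_meta$a2)
  if (anyDuplicated(snp_meta$key))
    stop("SNP keys (chrom:pos:alleles) must be unique")
  rownames(dosage) <- as.character(sample_meta$iid)
  colnames(dosage) <- as.character(snp_meta$id)
  rownames(snp_meta) <- NULL
  rownames(sample_meta) <- NULL
  structure(list(dosage = dosage, snp_meta = snp_meta,
                 sample_meta = sample_meta),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "SNPs\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  chromosomes: %s; missing rate: %.4f\n",
              length(unique(x$snp_meta$chrom)), miss))
  invisible(x)
}

#' SNP keys of a genotype panel
#'
#' @param g a `genotype_data` object.
#' @return Character vector of canonical SNP keys, one per SNP column.
#' @export
snp_keys <- function(g) g$snp_meta$key

#' Subset a genotype panel
#'
#' @param g a `genotype_data` object.
#' @param snps SNP keys (or logical/integer index over SNP columns).
#' @param individuals iids (or logical/integer index over rows).
#' @return A `genotype_data` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(g, snps = NULL, individuals = NULL) {
  ri <- seq_len(nrow(g$dosage))
  ci <- seq_len(ncol(g$dosage))
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, g$snp_meta$key) else which(rep(TRUE, ncol(g$dosage)))[snps]
    if (anyNA(ci)) stop("unknown SNP keys in subset")
  }
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, g$sample_meta$iid) else which(rep(TRUE, nrow(g$dosage)))[individuals]
    if (anyNA(ri)) stop("unknown individual ids in subset")
  }
  genotype_data(g$dosage[ri, ci, drop = FALSE],
                g$snp_meta[ci, setdiff(names(g$snp_meta), "key"), drop = FALSE],
                g$sample_meta[ri, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# PLINK binary format. SNP-major .bed: magic 0x6C 0x1B, mode 0x01, then
# ceiling(n/4) bytes per SNP, 2 bits per genotype:
#   00 = homozygous a1 (dosage 0 of a2), 10 = heterozygous (1),
#   11 = homozygous a2 (2), 01 = missing.

.bed_code_from_dosage <- c(`0` = 0L, `1` = 2L, `2` = 3L)   # NA -> 1L
.bed_dosage_from_code <- c(0L, NA_integer_, 1L, 2L)        # index = code + 1

#' Write genotypes as PLINK bed/bim/fam
#'
#' @param g a `genotype_data` object.
#' @param prefix output path prefix; `prefix.bed`, `prefix.bim`,
#'   `prefix.fam` are written.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  # bim: chrom, id, cM (0), pos, a1, a2
  bim <- data.frame(g$snp_meta$chrom, g$snp_meta$id, 0L, g$snp_meta$pos,
                    g$snp_meta$a1, g$snp_meta$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(g$sample_meta$iid, g$sample_meta$iid, 0L, 0L,
                    as.integer(g$sample_meta$sex) + 1L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  codes <- matrix(1L, n, m)                      # missing by default
  ok <- !is.na(g$dosage)
  codes[ok] <- .bed_code_from_dosage[as.character(g$dosage[ok])]
  pad <- (4L - n %% 4L) %% 4L
  if (pad > 0L) codes <- rbind(codes, matrix(0L, pad, m))
  i4 <- seq(1L, nrow(codes), by = 4L)
  bytes <- codes[i4, , drop = FALSE] +
    4L * codes[i4 + 1L, , drop = FALSE] +
    16L * codes[i4 + 2L, , drop = FALSE] +
    64L * codes[i4 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read PLINK bed/bim/fam genotypes
#'
#' Decodes a SNP-major PLINK v1 binary fileset into a [genotype_data()]
#' object. Dosage is the count of the second bim allele (`a2`); the PLINK
#' missing code is preserved as `NA`.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` files.
#' @return A `genotype_data` object.
#' @export
read_plink <- function(prefix) {
  for (ext in c(".bed", ".bim", ".fam"))
    if (!file.exists(paste0(prefix, ext)))
      stop("missing file: ", paste0(prefix, ext))
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paste0(prefix, ".fam"), colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3L || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B))
    stop("not a PLINK bed file (bad magic bytes): ", prefix, ".bed")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported (mode byte != 0x01)")
  bps <- ceiling(n / 4)                          # bytes per SNP
  payload <- raw[-(1:3)]
  if (length(payload) != bps * m)
    stop("corrupt bed file: expected ", bps * m, " payload bytes, found ",
         length(payload))
  v <- as.integer(payload)
  codes <- rbind(bitwAnd(v, 3L),
                 bitwAnd(bitwShiftR(v, 2L), 3L),
                 bitwAnd(bitwShiftR(v, 4L), 3L),
                 bitwAnd(bitwShiftR(v, 6L), 3L))
  dim(codes) <- c(4L * bps, m)
  dosage <- matrix(.bed_dosage_from_code[codes[seq_len(n), , drop = FALSE] + 1L],
                   n, m)
  sex <- suppressWarnings(as.integer(fam[[5]])) - 1L
  sex[is.na(sex) | !(sex %in% c(0L, 1L))] <- 0L
  genotype_data(dosage,
                bim[, c("chrom", "pos", "id", "a1", "a2")],
                data.frame(iid = fam[[2]], sex = sex))
}

#' Write / read a phenotype table
#'
#' Tab-separated with header; columns `iid`, `trait`, `sex`, `age` and,
#' when present, `corrected`.
#'
#' @param pheno data.frame with at least `iid`, `trait`, `sex`, `age`.
#' @param path file path.
#' @return `write_phenotypes`: `path` invisibly; `read_phenotypes`: the
#'   data.frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, colClasses = c(iid = "character"))
}

# ---------------------------------------------------------------------------
# Quality control

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the allele
#' counts: the p-value sums the probabilities of all heterozygote counts
#' whose conditional probability does not exceed that of the observed
#' count (the PLINK-style exact test).
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (homozygote, heterozygote,
#'   homozygote).
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0))
    stop("genotype counts must be non-negative")
  n <- n_hom1 + n_het + n_hom2
  if (n <= 0) stop("total genotype count must be positive")
  r <- 2L * min(n_hom1, n_hom2) + n_het          # rare allele count
  if (r == 0L) return(1.0)                       # monomorphic: single config
  hs <- seq.int(r %% 2L, min(r, 2L * n - r), by = 2L)
  # log P(het = h | n, r) up to the common normalising constant
  logp <- lgamma(n + 1) - lgamma((r - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma(n - (r + hs) / 2 + 1) + hs * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hs)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Apply genotype quality control
#'
#' Filters are applied in a fixed order: individuals by call rate, then
#' SNPs by call rate, minor allele frequency, exact Hardy-Weinberg test,
#' and finally sex-chromosome and monomorphic removal. Allele frequencies
#' are recomputed after individual removal. Thresholds are exclusive
#' (e.g. call rate must exceed `ind_call_min` to be kept).
#'
#' @param g a `genotype_data` object.
#' @param ind_call_min minimum individual call rate (exclusive), default 0.90.
#' @param snp_call_min minimum SNP call rate (exclusive), default 0.90.
#' @param maf_min minimum minor allele frequency (exclusive), default 0.01.
#' @param hwe_p_min minimum Hardy-Weinberg exact p-value (exclusive),
#'   default 1e-6.
#' @param drop_sex_chromosomes drop SNPs on chromosomes labelled
#'   X/Y/XY/MT, default `TRUE`.
#' @return list with the filtered `genotypes` and a `report` of class
#'   `qc_report` whose per-stage removal counts sum, with the retained
#'   count, to the input SNP count.
#' @export
apply_qc <- function(g, ind_call_min = 0.90, snp_call_min = 0.90,
                     maf_min = 0.01, hwe_p_min = 1e-6,
                     drop_sex_chromosomes = TRUE) {
  if (nrow(g$dosage) == 0 || ncol(g$dosage) == 0)
    stop("empty genotype panel")
  m0 <- ncol(g$dosage)
  obs <- !is.na(g$dosage)

  ind_rate <- rowMeans(obs)
  keep_ind <- ind_rate > ind_call_min
  n_ind_removed <- sum(!keep_ind)
  if (!any(keep_ind)) stop("all individuals removed by call-rate filter")
  X <- g$dosage[keep_ind, , drop = FALSE]
  obs <- obs[keep_ind, , drop = FALSE]

  snp_rate <- colMeans(obs)
  keep <- snp_rate > snp_call_min
  n_callrate <- sum(!keep)

  freq <- colSums(X, na.rm = TRUE) / (2 * colSums(obs))
  freq[is.nan(freq)] <- 0
  maf <- pmin(freq, 1 - freq)
  fail_maf <- keep & !(maf > maf_min)
  n_maf <- sum(fail_maf)
  keep <- keep & !fail_maf

  hwe_p <- rep(1, ncol(X))
  idx <- which(keep)
  if (length(idx)) {
    n0 <- colSums(X[, idx, drop = FALSE] == 0, na.rm = TRUE)
    n1 <- colSums(X[, idx, drop = FALSE] == 1, na.rm = TRUE)
    n2 <- colSums(X[, idx, drop = FALSE] == 2, na.rm = TRUE)
    hwe_p[idx] <- vapply(seq_along(idx), function(i)
      hwe_exact_test(n0[i], n1[i], n2[i]), numeric(1))
  }
  fail_hwe <- keep & !(hwe_p > hwe_p_min)
  n_hwe <- sum(fail_hwe)
  keep <- keep & !fail_hwe

  sexchrom <- g$snp_meta$chrom %in% c("X", "Y", "XY", "MT")
  mono <- maf == 0
  fail_sex <- keep & ((drop_sex_chromosomes & sexchrom) | mono)
  n_sex <- sum(fail_sex)
  keep <- keep & !fail_sex

  if (!any(keep)) stop("empty panel: all SNPs removed by quality control")
  out <- genotype_data(X[, keep, drop = FALSE],
                       g$snp_meta[keep, setdiff(names(g$snp_meta), "key"),
                                  drop = FALSE],
                       g$sample_meta[keep_ind, , drop = FALSE])
  report <- structure(list(
    n_individuals_removed = n_ind_removed,
    n_snps_removed_callrate = n_callrate,
    n_snps_removed_maf = n_maf,
    n_snps_removed_hwe = n_hwe,
    n_snps_removed_sexchrom_or_uninformative = n_sex,
    n_snps_retained = sum(keep),
    n_snps_input = m0), class = "qc_report")
  stopifnot(with(report, n_snps_removed_callrate + n_snps_removed_maf +
                   n_snps_removed_hwe +
                   n_snps_removed_sexchrom_or_uninformative +
                   n_snps_retained == n_snps_input))
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("quality control report\n")
  cat("  individuals removed (call rate):", x$n_individuals_removed, "\n")
  cat("  SNPs removed: call rate", x$n_snps_removed_callrate,
      "| MAF", x$n_snps_removed_maf, "| HWE", x$n_snps_removed_hwe,
      "| sex-chrom/monomorphic",
      x$n_snps_removed_sexchrom_or_uninformative, "\n")
  cat("  SNPs retained:", x$n_snps_retained, "of", x$n_snps_input, "\n")
  invisible(x)
}
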