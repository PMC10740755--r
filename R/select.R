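# SNP preselection from discovery GWAS results and allele-aware
# intersection with the target panel to define genomic features.

#' Preselect SNPs at p-value bins
#'
#' For each cutoff, keeps the SNP keys with `p < cutoff` (strict
#' inequality), so the sets are nested from the loosest to the most
#' stringent bin. An empty bin produces a warning, not an error.
#'
#' @param tab an `assoc_table` from [mlma_scan()].
#' @param thresholds p-value cutoffs, default
#'   `c(0.05, 0.005, 0.0005, 0.00005)`.
#' @return Named list (`"p<0.05"` etc.) of SNP key vectors.
#' @export
preselect <- function(tab, thresholds = c(0.05, 0.005, 0.0005, 0.00005)) {
  if (nrow(tab) == 0) stop("association table is empty")
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  ok <- tab$testable & !is.na(tab$p)
  out <- lapply(thresholds, function(th) tab$key[ok & tab$p < th])
  names(out) <- paste0("p<", format(thresholds, scientific = FALSE,
                                    trim = TRUE, drop0trailing = TRUE))
  for (i in seq_along(out))
    if (!length(out[[i]]))
      warning("no SNPs selected at cutoff ", names(out)[i])
  out
}

#' Intersect discovery keys with a target panel
#'
#' Allele-aware, order-insensitive matching through the canonical
#' `chrom:pos:alleleA:alleleB` key: a discovery SNP is a feature only if
#' the target panel carries the same position with the same allele pair.
#'
#' @param keys character vector of discovery SNP keys.
#' @param target `genotype_data` of the target cohort.
#' @param threshold optional p-value cutoff recorded on the result.
#' @return An object of class `feature_set`: `threshold`,
#'   `discovery_keys`, `feature_keys`, `counts` (`n_discovery`,
#'   `n_feature`).
#' @export
intersect_with_panel <- function(keys, target, threshold = NA_real_) {
  feature <- intersect(keys, snp_keys(target))
  if (length(keys) && !length(feature))
    warning("no discovery SNPs found in the target panel (empty feature set)")
  structure(list(threshold = threshold, discovery_keys = keys,
                 feature_keys = feature,
                 counts = c(n_discovery = length(keys),
                            n_feature = length(feature))),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set (p<%s): %d discovery SNPs, %d in target panel\n",
              format(x$threshold), x$counts["n_discovery"],
              x$counts["n_feature"]))
  invisible(x)
}

#' Build feature sets for every p-value bin
#'
#' Convenience wrapper: [preselect()] then [intersect_with_panel()] per
#' threshold.
#'
#' @param tab an `assoc_table` from the discovery scan.
#' @param target `genotype_data` of the target cohort.
#' @param thresholds p-value cutoffs (see [preselect()]).
#' @return Named list of `feature_set` objects.
#' @export
feature_sets <- function(tab, target,
                         thresholds = c(0.05, 0.005, 0.0005, 0.00005)) {
  sel <- preselect(tab, thresholds)
  ths <- sort(unique(thresholds), decreasing = TRUE)
  out <- mapply(function(keys, th) intersect_with_panel(keys, target, th),
                sel, ths, SIMPLIFY = FALSE)
  names(out) <- names(sel)
  out
}

#' Per-threshold SNP counts report
#'
#' Two-column layout per bin: SNPs passing the cutoff in the discovery
#' scan, and those also present in the target panel (the feature kernel).
#'
#' @param fsets list of `feature_set` objects (see [feature_sets()]).
#' @return data.frame with `threshold`, `n_discovery`, `n_feature`.
#' @export
feature_report <- function(fsets) {
  data.frame(threshold = vapply(fsets, function(f) f$threshold, numeric(1)),
             n_discovery = vapply(fsets, function(f)
               unname(f$counts["n_discovery"]), numeric(1)),
             n_feature = vapply(fsets, function(f)
               unname(f$counts["n_feature"]), numeric(1)),
             row.names = NULL)
}

#' Write / read a feature list (one SNP key per line)
#'
#' @param keys character vector of SNP keys (or a `feature_set`).
#' @param path file path.
#' @return `write_features`: `path` invisibly; `read_features`: character
#'   vector of keys.
#' @export
write_features <- function(keys, path) {
  if (inherits(keys, "feature_set")) keys <- keys$feature_keys
  writeLines(keys, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) readLines(path)
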