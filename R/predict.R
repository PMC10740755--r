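# GBLUP and GFBLUP breeding-value prediction and repeated k-fold
# cross-validated accuracy. Training only ever sees reference phenotypes:
# predictors receive a phenotype vector restricted to the reference ids,
# so validation phenotypes are unread by construction.

#' GBLUP breeding-value prediction
#'
#' Single-kernel BLUP: the overall mean is estimated by GLS on the
#' reference block and GEBVs for every individual in the kinship follow
#' from `u_hat = sigma2_u G[, ref] V_ref^-1 (y_ref - mu_hat)` with
#' `V_ref = G_ref sigma2_u + I sigma2_e`.
#'
#' @param k `kinship` over all individuals (reference and validation).
#' @param pheno named numeric vector of reference phenotypes; its names
#'   define the reference set and must be a subset of `k$ids`.
#' @param vc optional `variance_components`; estimated by REML on the
#'   reference block when `NULL`.
#' @return An object of class `mixed_model_fit`: `mu_hat`, `gebv` (named,
#'   all kinship ids), `vc`, `kernel_role`.
#' @export
gblup_predict <- function(k, pheno, vc = NULL) {
  ref <- names(pheno)
  if (is.null(ref)) stop("pheno must be named by individual id")
  ri <- match(ref, k$ids)
  if (anyNA(ri)) stop("reference ids missing from the kinship")
  y <- as.numeric(pheno)
  n <- length(y)
  if (is.null(vc))
    vc <- estimate_reml(mixed_model_spec(pheno,
                                         kernels = list(u = subset_kinship(k, ref))))
  s2u <- sum(vc$components[-length(vc$components)])
  s2e <- vc$components[["sigma2_e"]]
  Grr <- k$matrix[ri, ri, drop = FALSE]
  V <- s2u * Grr + diag(s2e, n)
  Vinv <- tryCatch(chol2inv(chol(V)), error = function(e)
    stop("reference-block covariance is numerically singular (condition ",
         format(kappa(V)), ")"))
  one <- rep(1, n)
  Vinv1 <- Vinv %*% one
  mu <- sum(Vinv1 * y) / sum(Vinv1)
  w <- Vinv %*% (y - mu)
  gebv <- as.vector(s2u * k$matrix[, ri, drop = FALSE] %*% w)
  names(gebv) <- k$ids
  structure(list(mu_hat = mu, gebv = gebv, vc = vc, kernel_role = k$role),
            class = "mixed_model_fit")
}

#' GFBLUP breeding-value prediction
#'
#' Two-kernel model `y = 1 mu + f + r + e` with a feature kernel `Gf`
#' (preselected SNPs) and a remainder kernel `Gr`. Variance components
#' `(sigma2_f, sigma2_r, sigma2_e)` are estimated by two-kernel REML on
#' the reference block; by default the kernels are then collapsed via
#' [combine_grms()] (`Gnew = lambda Gf + (1-lambda) Gr`,
#' `lambda = sigma2_f/(sigma2_f+sigma2_r)`) and a single-kernel BLUP with
#' total genetic variance `sigma2_f + sigma2_r` produces the GEBVs.
#' `method = "two_kernel"` instead solves the exact two-effect model
#' (`u_hat = (sigma2_f Gf + sigma2_r Gr)[, ref] V_ref^-1 (y - mu)`), kept
#' as an internal cross-check of the collapsed approximation.
#'
#' @param gf,gr feature and remainder `kinship` objects (identical id
#'   order, all individuals).
#' @param pheno named numeric vector of reference phenotypes.
#' @param vc optional three-component `variance_components` to reuse.
#' @param method `"combined"` (default) or `"two_kernel"`.
#' @return A `mixed_model_fit` (see [gblup_predict()]) with `lambda`
#'   attached.
#' @export
gfblup_predict <- function(gf, gr, pheno, vc = NULL,
                           method = c("combined", "two_kernel")) {
  method <- match.arg(method)
  if (!length(gf$ids) || !length(gr$ids))
    stop("empty feature or remainder kernel: fall back to gblup_predict()")
  if (!identical(gf$ids, gr$ids))
    stop("feature and remainder kinships must share the same id order")
  ref <- names(pheno)
  if (is.null(ref)) stop("pheno must be named by individual id")
  if (is.null(vc)) {
    vc <- estimate_reml(mixed_model_spec(
      pheno, kernels = list(f = subset_kinship(gf, ref),
                            r = subset_kinship(gr, ref))))
    if (!vc$converged)
      warning("two-kernel REML did not converge; predictions use the ",
              "last accepted estimates")
  }
  s2f <- vc$components[["sigma2_f"]]
  s2r <- vc$components[["sigma2_r"]]
  s2e <- vc$components[["sigma2_e"]]
  if (method == "combined") {
    cmb <- combine_grms(gf, gr, s2f, s2r)
    vc_one <- vc
    vc_one$components <- c(sigma2_u = s2f + s2r, sigma2_e = s2e)
    fit <- gblup_predict(cmb$kinship, pheno, vc = vc_one)
    fit$vc <- vc
    fit$lambda <- cmb$lambda
    fit$kernel_role <- "combined"
    return(fit)
  }
  ri <- match(ref, gf$ids)
  if (anyNA(ri)) stop("reference ids missing from the kinship")
  y <- as.numeric(pheno)
  Gtot <- s2f * gf$matrix + s2r * gr$matrix
  V <- Gtot[ri, ri, drop = FALSE] + diag(s2e, length(y))
  Vinv <- chol2inv(chol(V))
  one <- rep(1, length(y))
  Vinv1 <- Vinv %*% one
  mu <- sum(Vinv1 * y) / sum(Vinv1)
  w <- Vinv %*% (y - mu)
  gebv <- as.vector(Gtot[, ri, drop = FALSE] %*% w)
  names(gebv) <- gf$ids
  structure(list(mu_hat = mu, gebv = gebv, vc = vc,
                 kernel_role = "two_kernel",
                 lambda = s2f / (s2f + s2r)),
            class = "mixed_model_fit")
}

#' Repeated k-fold cross-validated prediction accuracy
#'
#' Per repeat, a fresh uniform random partition into `n_folds` groups
#' (sizes differing by at most one); per fold the remaining groups are the
#' reference, the held-out group's phenotypes are treated as missing, and
#' accuracy is the Pearson correlation between the held-out (corrected)
#' phenotypes and their GEBVs. Variance components are re-estimated within
#' each training split. For GFBLUP the feature kernel is a fixed external
#' input (no per-fold re-selection).
#'
#' @param pheno named numeric vector of (corrected) phenotypes over the
#'   whole cohort.
#' @param k `kinship` for GBLUP (`model = "gblup"`).
#' @param gf,gr feature/remainder kinships for GFBLUP
#'   (`model = "gfblup"`).
#' @param model `"gblup"` or `"gfblup"`.
#' @param n_folds,n_repeats cross-validation scheme (default 5 x 5 = 25
#'   splits).
#' @param seed RNG seed for the fold partitions; recorded on the result.
#' @param ... passed to the predictor (e.g. `method` for GFBLUP).
#' @return An object of class `cv_result`: `splits` (data.frame `rep`,
#'   `fold`, `n_val`, `accuracy`), `mean_accuracy`, `se_accuracy`,
#'   `scheme`, `seed`, `model`. Splits whose held-out phenotypes have zero
#'   variance are flagged `NA` with a warning and excluded from the mean.
#' @export
cross_validate <- function(pheno, k = NULL, gf = NULL, gr = NULL,
                           model = c("gblup", "gfblup"), n_folds = 5,
                           n_repeats = 5, seed = 1L, ...) {
  model <- match.arg(model)
  ids <- names(pheno)
  if (is.null(ids)) stop("pheno must be named by individual id")
  n <- length(ids)
  if (model == "gblup" && is.null(k))
    stop("gblup cross-validation needs `k`")
  if (model == "gfblup" && (is.null(gf) || is.null(gr)))
    stop("gfblup cross-validation needs `gf` and `gr`")
  folds <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) sample(rep_len(seq_len(n_folds), n)))
  })
  rows <- list()
  for (r in seq_len(n_repeats)) {
    fold <- folds[[r]]
    for (f in seq_len(n_folds)) {
      val <- ids[fold == f]
      ref <- ids[fold != f]
      yref <- pheno[ref]
      fit <- if (model == "gblup") {
        gblup_predict(k, yref, ...)
      } else {
        gfblup_predict(gf, gr, yref, ...)
      }
      yval <- pheno[val]
      acc <- if (stats::sd(yval) == 0 || stats::sd(fit$gebv[val]) == 0) {
        warning("zero variance in held-out split (repeat ", r, ", fold ",
                f, "): excluded from the average")
        NA_real_
      } else {
        stats::cor(yval, fit$gebv[val])
      }
      rows[[length(rows) + 1L]] <- data.frame(rep = r, fold = f,
                                              n_val = length(val),
                                              accuracy = acc)
    }
  }
  splits <- do.call(rbind, rows)
  acc <- splits$accuracy[!is.na(splits$accuracy)]
  structure(list(splits = splits,
                 mean_accuracy = mean(acc),
                 se_accuracy = stats::sd(acc) / sqrt(length(acc)),
                 scheme = c(n_folds = n_folds, n_repeats = n_repeats),
                 seed = seed, model = model),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation (%d folds x %d repeats, seed %s)\n",
              x$model, x$scheme["n_folds"], x$scheme["n_repeats"],
              format(x$seed)))
  cat(sprintf("  accuracy = %.3f +/- %.3f (mean +/- SE over %d splits)\n",
              x$mean_accuracy, x$se_accuracy,
              sum(!is.na(x$splits$accuracy))))
  invisible(x)
}

#' Accuracy summary table across models and p-value bins
#'
#' @param results named list of `cv_result` objects; names label the rows
#'   (e.g. `"GBLUP"`, `"GFBLUP p<0.05"`).
#' @return data.frame with `model`, `mean_accuracy`, `se_accuracy`,
#'   `n_splits`.
#' @export
cv_report <- function(results) {
  data.frame(model = names(results),
             mean_accuracy = vapply(results, function(r)
               r$mean_accuracy, numeric(1)),
             se_accuracy = vapply(results, function(r)
               r$se_accuracy, numeric(1)),
             n_splits = vapply(results, function(r)
               sum(!is.na(r$splits$accuracy)), numeric(1)),
             row.names = NULL)
}
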