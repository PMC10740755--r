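# Variance-component estimation by average-information REML with an EM
# fallback, heritability with delta-method standard errors, principal
# components of a genomic relationship matrix, and fixed-effect phenotype
# correction.

#' Specify a mixed model
#'
#' `y = X b + sum_k u_k + e`, with `u_k ~ N(0, K_k sigma2_k)` and
#' `e ~ N(0, I sigma2_e)`. Ids are aligned: the response must be named (or
#' `ids` given) and every kernel must contain all response ids.
#'
#' @param response named numeric vector of phenotypes.
#' @param fixed_design design matrix for fixed effects; defaults to an
#'   intercept column. Must be full column rank.
#' @param kernels a `kinship` object or (named) list of them; matrices are
#'   accepted and wrapped.
#' @param ids optional ids overriding `names(response)`.
#' @return An object of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(response, fixed_design = NULL, kernels,
                             ids = names(response)) {
  y <- as.numeric(response)
  n <- length(y)
  if (is.null(ids)) stop("response must be named by individual id (or give `ids`)")
  if (inherits(kernels, "kinship") || is.matrix(kernels))
    kernels <- list(g = kernels)
  kernels <- lapply(kernels, function(k) {
    if (inherits(k, "kinship")) k else kinship(k, ids, NA_integer_)
  })
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    names(kernels) <- paste0("g", seq_along(kernels))
  kernels <- lapply(kernels, subset_kinship, ids = ids)
  if (is.null(fixed_design)) fixed_design <- matrix(1, n, 1,
                                                    dimnames = list(NULL, "mu"))
  fixed_design <- as.matrix(fixed_design)
  if (nrow(fixed_design) != n)
    stop("fixed_design must have one row per response element")
  if (qr(fixed_design)$rank < ncol(fixed_design))
    stop("fixed_design is not full column rank")
  structure(list(y = y, X = fixed_design, kernels = kernels,
                 ids = as.character(ids)),
            class = "mixed_model_spec")
}

# --- REML inner computations ------------------------------------------------
# Both engines return, at the current variances theta = (kernel vars, e):
#   ll      restricted log-likelihood -0.5(log|V| + log|X'V^-1 X| + y'Py)
#   score   gradient dll/dtheta
#   AI      average-information matrix
#   ypkpy   y'P K_k P y per component (K_e = I), for the EM update

# Single-kernel engine: one eigendecomposition of K makes every iteration
# O(n p^2).
.reml_inner_eigen <- function(ed, yt, Xt, theta) {
  v <- theta[1] * ed$values + theta[2]
  vinv <- 1 / v
  XtV <- Xt * vinv
  XtVX <- crossprod(Xt, XtV)
  B <- solve(XtVX)
  Papply <- function(u) vinv * u - XtV %*% (B %*% crossprod(Xt, vinv * u))
  Py <- Papply(yt)
  ll <- -0.5 * (sum(log(v)) + determinant(XtVX, logarithm = TRUE)$modulus +
                  sum(yt * Py))
  d <- ed$values
  trPK <- c(sum(d * vinv) - sum(diag(B %*% crossprod(Xt, XtV * (d * vinv)))),
            sum(vinv) - sum(diag(B %*% crossprod(Xt, XtV * vinv))))
  tk <- list(d * Py, Py)                      # K_k P y
  ypkpy <- vapply(tk, function(t) sum(Py * t), numeric(1))
  sk <- lapply(tk, Papply)
  AI <- matrix(0, 2, 2)
  for (a in 1:2) for (b in a:2)
    AI[a, b] <- AI[b, a] <- 0.5 * sum(tk[[a]] * sk[[b]])
  score <- -0.5 * (trPK - ypkpy)
  list(ll = as.numeric(ll), score = score, AI = AI, ypkpy = ypkpy)
}

# General engine for any number of kernels (dense O(n^3) per iteration).
.reml_inner_dense <- function(y, X, Ks, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Ks)) V <- V + theta[k] * Ks[[k]]
  R <- chol(V)
  Vinv <- chol2inv(R)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  B <- solve(XtVX)
  P <- Vinv - VinvX %*% tcrossprod(B, VinvX)
  Py <- as.vector(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(R))) +
                  determinant(XtVX, logarithm = TRUE)$modulus +
                  sum(y * Py))
  nk <- length(Ks) + 1L
  trPK <- numeric(nk); tk <- vector("list", nk)
  for (k in seq_along(Ks)) {
    trPK[k] <- sum(P * Ks[[k]])
    tk[[k]] <- as.vector(Ks[[k]] %*% Py)
  }
  trPK[nk] <- sum(diag(P))
  tk[[nk]] <- Py
  ypkpy <- vapply(tk, function(t) sum(Py * t), numeric(1))
  sk <- lapply(tk, function(t) as.vector(P %*% t))
  AI <- matrix(0, nk, nk)
  for (a in seq_len(nk)) for (b in a:nk)
    AI[a, b] <- AI[b, a] <- 0.5 * sum(tk[[a]] * sk[[b]])
  score <- -0.5 * (trPK - ypkpy)
  list(ll = as.numeric(ll), score = score, AI = AI, ypkpy = ypkpy,
       trPK = trPK)
}

#' Estimate variance components by AI-REML
#'
#' Average-information REML with an EM fallback: an AI step is accepted
#' only if it keeps every variance above the floor and does not decrease
#' the restricted likelihood; otherwise an EM step (step-halved if needed)
#' is taken, so the likelihood never decreases across accepted iterations.
#' Standard errors come from the inverse AI matrix at the optimum and the
#' heritability standard error from the delta method.
#'
#' @param spec a [mixed_model_spec()].
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-8); convergence additionally requires
#'   the relative parameter change to drop below 1e-6, which guards
#'   flat likelihood directions.
#' @param max_iter maximum iterations (default 200); non-convergence is
#'   flagged, not an error.
#' @param var_floor variances are constrained to at least
#'   `var_floor * var(y)` (default 1e-8) to keep the AI matrix invertible;
#'   estimates at the floor are flagged `boundary`.
#' @return An object of class `variance_components`: named `components`
#'   (`sigma2_<kernel>`, `sigma2_e`), `se`, `h2` (sum of kernel variances
#'   over total), `h2_se`, `loglik`, `n_iter`, `converged`, `boundary`.
#' @export
estimate_reml <- function(spec, tol = 1e-8, max_iter = 200L,
                          var_floor = 1e-8) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  y <- spec$y; X <- spec$X
  n <- length(y)
  if (stats::var(y) == 0) stop("response has zero phenotypic variance")
  if (n < 30)
    warning("fewer than 30 individuals: variance components will be noisy")
  Ks <- lapply(spec$kernels, function(k) k$matrix)
  for (k in Ks) {
    if (max(abs(k - diag(n))) < 1e-8)
      stop("kernel equals the identity: genetic and residual variances ",
           "are not identifiable")
  }
  nk <- length(Ks) + 1L
  floor_ <- var_floor * stats::var(y)
  theta <- rep(stats::var(y) / nk, nk)

  single <- length(Ks) == 1L
  if (single) {
    ed <- eigen(Ks[[1]], symmetric = TRUE)
    yt <- as.vector(crossprod(ed$vectors, y))
    Xt <- crossprod(ed$vectors, X)
    inner <- function(th) .reml_inner_eigen(ed, yt, Xt, th)
  } else {
    inner <- function(th) .reml_inner_dense(y, X, Ks, th)
  }

  cur <- inner(theta)
  ll_path <- cur$ll
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    try_cand <- function(cand) {
      if (!all(is.finite(cand))) return(NULL)
      res <- tryCatch(inner(cand), error = function(e) list(ll = -Inf))
      if (is.finite(res$ll) && res$ll >= cur$ll - 1e-10)
        list(theta = cand, res = res) else NULL
    }
    # AI proposal. A component may shrink at most 20-fold per accepted
    # step (prevents overshooting into a near-singular V); when the raw
    # AI step drives a component below the floor, pin it there and take
    # the AI step in the free coordinates (active set), which avoids the
    # slow EM crawl toward a zero variance component.
    step <- tryCatch(as.vector(solve(cur$AI + diag(1e-10, nk), cur$score)),
                     error = function(e) NULL)
    prop <- NULL
    if (!is.null(step)) {
      lower <- pmax(floor_, theta * 0.05)
      pin <- which(theta + step < floor_ & cur$score < 0)
      free <- setdiff(seq_len(nk), pin)
      if (length(pin) && length(free)) {
        cand <- theta
        cand[pin] <- pmax(floor_, theta[pin] * 0.05)
        fs <- tryCatch(as.vector(
          solve(cur$AI[free, free, drop = FALSE] +
                  diag(1e-10, length(free)), cur$score[free])),
          error = function(e) NULL)
        if (!is.null(fs)) {
          cand[free] <- pmax(theta[free] + fs, lower[free])
          prop <- try_cand(cand)
        }
      }
      if (is.null(prop))
        prop <- try_cand(pmax(theta + step, lower))
    }
    if (is.null(prop)) {   # EM fallback (guaranteed ascent), with halving
      em <- pmax(theta + theta^2 * (2 * cur$score) / n, floor_)
      cand <- em
      for (h in 1:12) {
        prop <- try_cand(cand)
        if (!is.null(prop)) break
        cand <- theta + (cand - theta) / 2
      }
      if (is.null(prop)) break                 # cannot improve further
    }
    delta_ll <- prop$res$ll - cur$ll
    delta_th <- max(abs(prop$theta - theta) / pmax(theta, floor_))
    theta <- prop$theta; cur <- prop$res
    ll_path <- c(ll_path, cur$ll)
    # converged when both the restricted likelihood and the parameters
    # have stabilized (the latter guards flat likelihood directions)
    if (abs(delta_ll) < tol && delta_th < 1e-6) { converged <- TRUE; break }
  }

  knames <- names(spec$kernels)
  comp_names <- c(paste0("sigma2_", knames), "sigma2_e")
  names(theta) <- comp_names
  AIinv <- tryCatch(solve(cur$AI), error = function(e)
    matrix(NA_real_, nk, nk))
  se <- sqrt(pmax(diag(AIinv), 0))
  names(se) <- comp_names
  tot <- sum(theta)
  gen <- sum(theta[-nk])
  h2 <- gen / tot
  grad <- c(rep((tot - gen) / tot^2, nk - 1L), -gen / tot^2)
  h2_se <- sqrt(max(0, as.numeric(t(grad) %*% AIinv %*% grad)))
  structure(list(components = theta, se = se, h2 = h2, h2_se = h2_se,
                 loglik = cur$ll, n_iter = iter, converged = converged,
                 boundary = any(theta <= floor_ * 1.01)),
            class = "variance_components", ll_path = ll_path)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance components (AI-REML)\n")
  for (i in seq_along(x$components))
    cat(sprintf("  %-12s %10.4f  (SE %.4f)\n", names(x$components)[i],
                x$components[i], x$se[i]))
  cat(sprintf("  h2 = %.4f (SE %.4f); logL = %.4f; %d iterations%s%s\n",
              x$h2, x$h2_se, x$loglik, x$n_iter,
              if (x$converged) "" else " [NOT converged]",
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Principal components of a genomic relationship matrix
#'
#' Top eigenvectors of the GRM scaled by the square root of their
#' eigenvalues, with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param k a `kinship` object.
#' @param n_pc number of components, `1 <= n_pc <= n - 1`.
#' @return n x n_pc matrix of scores (rows named by id, columns
#'   `PC1..`), with the eigenvalues as attribute `eigenvalues`.
#' @export
principal_components <- function(k, n_pc = 3) {
  n <- length(k$ids)
  if (!is_count(n_pc) || n_pc < 1 || n_pc > n - 1)
    stop("n_pc must be an integer in [1, n-1]")
  ed <- eigen(k$matrix, symmetric = TRUE)
  U <- ed$vectors[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(n_pc)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  scores <- U %*% diag(sqrt(pmax(ed$values[seq_len(n_pc)], 0)), n_pc)
  dimnames(scores) <- list(k$ids, paste0("PC", seq_len(n_pc)))
  attr(scores, "eigenvalues") <- ed$values
  scores
}

# GLS fixed-effect solve at given variance components.
.gls_fixed <- function(spec, vc) {
  n <- length(spec$y)
  theta <- vc$components
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(spec$kernels))
    V <- V + theta[k] * spec$kernels[[k]]$matrix
  Vinv <- chol2inv(chol(V))
  VinvX <- Vinv %*% spec$X
  b <- solve(crossprod(spec$X, VinvX), crossprod(VinvX, spec$y))
  list(b = as.vector(b), Vinv = Vinv)
}

#' Correct phenotypes for fixed effects
#'
#' Fits the animal model `y = X b + u + e` (u with a genomic kernel) by
#' REML, estimates the fixed effects by generalized least squares at the
#' REML variances, and strips them: corrected value = `y - X b_hat`. The
#' genetic and residual parts are deliberately retained - they carry the
#' signal genomic prediction needs.
#'
#' @param pheno data.frame with columns `iid`, `trait` and the requested
#'   covariates.
#' @param k a `kinship` over (at least) the phenotyped ids.
#' @param covariates covariate column names entering the fixed design
#'   (default sex and age).
#' @param n_pc number of GRM principal components added as fixed effects
#'   (default 3; 0 for none).
#' @return `pheno` with a `corrected` column; the REML fit is attached as
#'   attribute `fit` and the GLS coefficients as attribute `coef`.
#' @export
correct_phenotypes <- function(pheno, k, covariates = c("sex", "age"),
                               n_pc = 3) {
  if (!all(c("iid", "trait") %in% names(pheno)))
    stop("pheno must have columns iid and trait")
  missing_cov <- setdiff(covariates, names(pheno))
  if (length(missing_cov))
    stop("covariates not found in pheno: ", paste(missing_cov, collapse = ", "))
  ids <- as.character(pheno$iid)
  kk <- subset_kinship(k, ids)
  X <- cbind(mu = 1, as.matrix(pheno[, covariates, drop = FALSE]))
  if (n_pc > 0) X <- cbind(X, principal_components(kk, n_pc))
  spec <- mixed_model_spec(stats::setNames(pheno$trait, ids), X,
                           list(g = kk))
  vc <- estimate_reml(spec)
  gls <- .gls_fixed(spec, vc)
  pheno$corrected <- as.vector(pheno$trait - X %*% gls$b)
  attr(pheno, "fit") <- vc
  attr(pheno, "coef") <- stats::setNames(gls$b, colnames(X))
  pheno
}
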