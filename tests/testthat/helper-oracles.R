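# Independent oracles used across tests. These deliberately avoid the
# package's computational paths (eigen/chol shortcuts, cached projections)
# and use plain dense linear algebra.

# Restricted log-likelihood evaluated directly from V = sum theta_k K_k +
# theta_e I, using solve() and determinant() only.
reml_ll_direct <- function(theta, y, X, Ks) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Ks)) V <- V + theta[k] * Ks[[k]]
  Vinv <- solve(V)
  XtVX <- t(X) %*% Vinv %*% X
  P <- Vinv - Vinv %*% X %*% solve(XtVX) %*% t(X) %*% Vinv
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtVX, logarithm = TRUE)$modulus +
                       t(y) %*% P %*% y))
}

# Brute-force REML: numerical maximization of the restricted likelihood
# with Nelder-Mead from several fixed starts, over the same constrained
# space as the estimator (variances >= floor, via theta = floor + exp(l)).
reml_brute_force <- function(y, X, Ks, var_floor = 1e-8) {
  nk <- length(Ks) + 1L
  floor_ <- var_floor * stats::var(y)
  obj <- function(lt) {
    v <- tryCatch(-reml_ll_direct(floor_ + exp(lt), y, X, Ks),
                  error = function(e) Inf)
    if (is.finite(v)) v else 1e10
  }
  vy <- stats::var(y)
  starts <- list(rep(log(vy / nk), nk),
                 log(c(rep(vy * 0.1, nk - 1), vy * 0.9)),
                 log(c(rep(vy * 0.9, nk - 1), vy * 0.1)))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(theta = floor_ + exp(best$par), ll = -best$value)
}

# Per-SNP generalized least squares, solved directly (no caching): fit
# y = mu + b x under covariance V.
gls_snp_direct <- function(y, x, V) {
  Vinv <- solve(V)
  X2 <- cbind(1, x)
  b <- solve(t(X2) %*% Vinv %*% X2, t(X2) %*% Vinv %*% y)
  vb <- solve(t(X2) %*% Vinv %*% X2)
  c(b = b[2], se = sqrt(vb[2, 2]))
}

# Fixed variance components for predictors (skips REML when a test wants
# a deterministic covariance).
fixed_vc <- function(...) {
  comp <- c(...)
  structure(list(components = comp, se = rep(NA_real_, length(comp)),
                 h2 = sum(comp[-length(comp)]) / sum(comp), h2_se = NA_real_,
                 loglik = NA_real_, n_iter = 0L, converged = TRUE,
                 boundary = FALSE),
            class = "variance_components")
}
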