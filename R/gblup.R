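# Kernel BLUP by spectral REML.  The model is g = mu + Z u + e with
# u ~ N(0, K sigma_u^2) over genotypes and i.i.d. errors; eigendecomposition
# of Z K Z' reduces REML to a one-dimensional search over the variance ratio
# lambda = sigma_e^2 / sigma_u^2.

#' Fit a GBLUP model by spectral REML
#'
#' @param g numeric vector of observations (family BLUPs used as response).
#' @param Z design matrix mapping observations to genotypes, or `NULL` for
#'   the identity (one observation per genotype, in `K` order).
#' @param K genomic relationship (or Gaussian) kernel over genotypes,
#'   symmetric PSD; row/column names are the genotype ids.
#' @param lambda optional fixed variance ratio (skips REML).
#' @return object of class `gblup_fit`: `mu`, `sigma_u2`, `sigma_e2`,
#'   `lambda`, `h2`, `u` (genotype BLUPs), `fitted`, `loglik` (REML),
#'   `trace_H` (effective degrees of freedom of the smoother including the
#'   mean projection), `gcv`.
#' @export
fit_gblup <- function(g, Z = NULL, K, lambda = NULL) {
  n <- length(g)
  K <- as.matrix(K)
  if (is.null(Z)) Z <- diag(nrow(K))
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == n, ncol(Z) == nrow(K))
  if (sd(g) == 0) {
    # constant outcome: no genetic variance, BLUPs identically zero
    u0 <- setNames(rep(0, nrow(K)), rownames(K))
    return(structure(list(mu = g[1L], sigma_u2 = 0, sigma_e2 = 0,
                          lambda = Inf, h2 = 0, u = u0,
                          fitted = rep(g[1L], n), loglik = NA_real_,
                          trace_H = 1, gcv = 0,
                          U = diag(n), d = rep(0, n), v = rep(1, n),
                          r = rep(0, n), Z = Z,
                          genotype_ids = rownames(K), g = g),
                     class = "gblup_fit"))
  }
  H0 <- Z %*% K %*% t(Z)
  eg <- eigen((H0 + t(H0)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("K is not positive semidefinite within tolerance")
  U <- eg$vectors
  yt <- drop(crossprod(U, g))
  xt <- drop(crossprod(U, rep(1, n)))

  prof <- function(loglam) {
    lam <- exp(loglam)
    v <- d + lam
    sxx <- sum(xt^2 / v)
    mu <- sum(xt * yt / v) / sxx
    r <- yt - xt * mu
    s2u <- sum(r^2 / v) / (n - 1)
    if (s2u <= 0) return(list(obj = 1e10))
    neg2 <- (n - 1) * log(s2u) + sum(log(v)) + log(sxx) + (n - 1) * (1 + log(2 * pi))
    list(obj = neg2, mu = mu, s2u = s2u, lam = lam, r = r, v = v)
  }
  if (is.null(lambda)) {
    op <- optimize(function(l) prof(l)$obj, interval = c(-12, 12), tol = 1e-8)
    sol <- prof(op$minimum)
  } else sol <- prof(log(lambda))
  if (is.null(sol$mu)) stop("degenerate GBLUP fit")

  w <- sol$r / sol$v                       # V^{-1} (g - mu) up to sigma_u2
  u <- drop(K %*% crossprod(Z, U %*% w))   # genotype BLUPs
  fitted <- sol$mu + drop(Z %*% u)
  # trace of the smoother g -> ghat (mean projection + kernel part)
  s <- (xt / sol$v) / sum(xt^2 / sol$v)
  trH <- sum(d / sol$v) + 1 - sum(s * xt * d / sol$v)
  gcv_val <- gcv(g, fitted, trH)
  structure(list(mu = sol$mu, sigma_u2 = sol$s2u,
                 sigma_e2 = sol$s2u * sol$lam, lambda = sol$lam,
                 h2 = 1 / (1 + sol$lam), u = setNames(u, rownames(K)),
                 fitted = fitted, loglik = -sol$obj / 2, trace_H = trH,
                 gcv = gcv_val, U = U, d = d, v = sol$v, r = sol$r,
                 Z = Z, genotype_ids = rownames(K), g = g),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("gblup_fit: n = %d, h2 = %.3f (sigma_u2 = %.4g, sigma_e2 = %.4g)\n",
              length(x$g), x$h2, x$sigma_u2, x$sigma_e2))
  invisible(x)
}

#' Predict unphenotyped genotypes from a GBLUP fit
#'
#' Standard kernel-BLUP extension:
#' \eqn{\hat u_{test} = K_{test,train} Z' (Z K Z' + \lambda I)^{-1}
#' (g - \hat\mu)}, evaluated through the stored spectral decomposition;
#' predictions are \eqn{\hat\mu + \hat u_{test}}.
#'
#' @param fit a `gblup_fit`.
#' @param K_full kernel covering training and test genotypes (named).
#' @param test_ids genotype ids to predict.
#' @return named numeric predictions.
#' @export
predict_gblup <- function(fit, K_full, test_ids) {
  K_full <- as.matrix(K_full)
  if (is.null(rownames(K_full))) stop("K_full needs genotype ids")
  if (!all(test_ids %in% rownames(K_full)) ||
      !all(fit$genotype_ids %in% colnames(K_full)))
    stop("genotype id mismatch between fit and K_full")
  Kct <- K_full[test_ids, fit$genotype_ids, drop = FALSE]
  w <- fit$r / fit$v
  u_test <- drop(Kct %*% crossprod(fit$Z, fit$U %*% w))
  setNames(fit$mu + u_test, test_ids)
}

#' Generalized cross-validation criterion
#'
#' \eqn{GCV = \frac{(1/n) (g - \hat g)'(g - \hat g)}
#' {(1 - tr(H)/n)^2}}, the trace-corrected training mean squared error of a
#' linear smoother \eqn{\hat g = H g}; it approximates the leave-one-out
#' mean squared error from a single fit.
#'
#' @param g observed values.
#' @param g_hat fitted values.
#' @param trace_H trace of the smoother matrix (including the fixed-mean
#'   projection); must be `< n`.
#' @return the criterion value.
#' @export
gcv <- function(g, g_hat, trace_H) {
  n <- length(g)
  if (trace_H >= n) stop("degenerate smoother: trace(H) >= n")
  mean((g - g_hat)^2) / (1 - trace_H / n)^2
}

#' Tune a single parameter by GCV over a grid
#'
#' Fits the model at every grid value on the full training set and returns
#' the value minimizing GCV (ties broken towards the smallest parameter).
#'
#' @param model_builder function taking one grid value and returning a list
#'   (or `gblup_fit`) with at least element `gcv`; may throw for infeasible
#'   values, which are skipped.
#' @param grid numeric candidate values.
#' @return object of class `tune_result`: `grid`, `gcv`, `selected`.
#' @export
tune_by_gcv <- function(model_builder, grid) {
  stopifnot(length(grid) >= 1L)
  vals <- vapply(grid, function(v)
    tryCatch(model_builder(v)$gcv, error = function(e) NA_real_),
    numeric(1L))
  if (all(is.na(vals))) stop("all fits failed during tuning")
  best <- min(grid[which(vals == min(vals, na.rm = TRUE))])
  structure(list(grid = grid, gcv = vals, selected = best),
            class = "tune_result")
}

#' Tuning grids for the RKHS scale parameter and the FDR threshold
#'
#' Both grids cover the open unit interval: steps of 0.025 for the Gaussian
#' kernel scale, steps of 0.05 for the feature-selection FDR threshold.
#'
#' @name tuning_grids
#' @export
rkhs_scale_grid <- function() seq(0.025, 0.975, by = 0.025)

#' @rdname tuning_grids
#' @export
fdr_threshold_grid <- function() seq(0.05, 0.95, by = 0.05)
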