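# Outcome-informed feature weighting and selection for the -wG and -sG
# model variants.  All of these touch the outcome and must therefore be
# recomputed inside every training fold during cross-validation.

#' Marginal correlation p-values of features against an outcome
#'
#' Two-sided p-value from the Pearson-correlation t-test of each feature
#' column versus the outcome (`t = r sqrt(n-2) / sqrt(1-r^2)`, `n - 2` df).
#' Constant features get `p = 1`.
#'
#' @param X feature matrix (genotypes x features).
#' @param g outcome vector.
#' @return named p-value vector over features.
#' @export
marginal_feature_pvalues <- function(X, g) {
  n <- length(g)
  if (n < 3L) stop("need >= 3 genotypes")
  sds <- apply(X, 2L, sd)
  p <- rep(1, ncol(X))
  ok <- which(sds > 0 & sd(g) > 0)
  if (length(ok) > 0) {
    r <- drop(cor(X[, ok, drop = FALSE], g))
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p[ok] <- 2 * pt(-abs(tval), df = n - 2)
  }
  setNames(p, colnames(X))
}

#' Weight features by significance
#'
#' Scales feature column `j` by \eqn{\sqrt{-\log_{10} p_j}}, so the induced
#' GBLUP kernel weights each feature by \eqn{-\log_{10}(p_j)}.  Features
#' with `p = 1` (weight 0) are dropped; `p = 0` is capped at the smallest
#' representable double.
#'
#' @param X feature matrix.
#' @param p per-feature p-values in `[0, 1]`.
#' @return a `feature_matrix` with the weighted (possibly fewer) columns.
#' @export
weight_features <- function(X, p) {
  stopifnot(ncol(X) == length(p))
  p <- pmax(p, .Machine$double.xmin)
  w <- -log10(p)
  keep <- which(w > 0)
  out <- sweep(X[, keep, drop = FALSE], 2L, sqrt(w[keep]), "*")
  new_feature_matrix(out, paste0(attr(X, "transform") %||% "", "-wG"),
                     colnames(X)[keep], attr(X, "scope"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Storey q-values
#'
#' False-discovery-rate q-values with the null proportion \eqn{\hat\pi_0}
#' estimated by smoothing \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} /
#' (m(1-\lambda))} over a lambda grid (natural cubic smoothing spline,
#' evaluated at the largest lambda).  With `pi0 = 1` the result is exactly
#' the Benjamini-Hochberg adjusted p-value.
#'
#' @param p p-values in `[0, 1]`.
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return q-values, same order as `p`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  m <- length(p)
  if (m == 0L) stop("empty p-value vector")
  stopifnot(all(p >= 0 & p <= 1))
  if (is.null(pi0)) {
    lam <- seq(0.05, 0.95, by = 0.05)
    pl <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1L))
    pi0 <- if (m < 100L) min(1, pl[1L]) else {
      sp <- stats::smooth.spline(lam, pl, df = 3)
      min(1, max(stats::predict(sp, x = max(lam))$y, 0))
    }
    if (pi0 <= 0) pi0 <- 1 / m
  }
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  setNames(out, names(p))
}

#' Select features by FDR threshold
#'
#' Keeps columns with q-value strictly below the threshold.  An empty
#' selection is returned as a zero-column matrix flagged
#' `attr(,"empty_selection")`, for which model fits fall back to the
#' intercept-only predictor.
#'
#' @param X feature matrix.
#' @param q per-feature q-values.
#' @param threshold FDR threshold in `(0, 1)`.
#' @return a `feature_matrix` of the selected columns.
#' @export
select_features_sG <- function(X, q, threshold) {
  stopifnot(threshold > 0, threshold < 1, ncol(X) == length(q))
  keep <- which(q < threshold)
  out <- new_feature_matrix(X[, keep, drop = FALSE],
                            paste0(attr(X, "transform") %||% "", "-sG"),
                            colnames(X)[keep], attr(X, "scope"))
  attr(out, "empty_selection") <- length(keep) == 0L
  out
}

#' Prior proportion of variance explained, via one HEM update
#'
#' Fits GBLUP on the Base kernel, back-solves the equivalent ridge marker
#' effects, reweights markers by the heteroscedastic-effects-model update
#' \eqn{w_j \propto \hat\beta_j^2 / (1 - h_{jj})} (with \eqn{h_{jj}} the
#' marker's ridge leverage), rebuilds the weighted kernel, refits, and
#' returns the resulting \eqn{h^2 = \sigma_u^2/(\sigma_u^2+\sigma_e^2)}
#' clamped to `[0.01, 0.99]`.  Used to set the prior variance share for the
#' Bayesian regression models.
#'
#' @param g outcome vector (one observation per genotype).
#' @param X_base Base feature matrix (genotypes x markers).
#' @return scalar in `[0.01, 0.99]`.
#' @export
hem_prior_r2 <- function(g, X_base) {
  X <- unclass(X_base)
  n <- nrow(X)
  fit0 <- fit_gblup(g, Z = NULL, K = grm_named(X))
  # a signal-free base fit leaves nothing meaningful to reweight (the
  # beta-hat^2 weights would only chase noise), so clamp immediately
  if (fit0$h2 < 0.01) return(0.01)
  # equivalent ridge: K = XX'/c  =>  beta = X' alpha / c with
  # alpha = (XX'/c + lambda I)^{-1} (g - mu)
  cnorm <- sum(apply(X, 2L, var))
  lam_r <- fit0$lambda * cnorm          # ridge penalty on raw XX' scale
  S <- solve(tcrossprod(X) + lam_r * diag(n))
  alpha <- S %*% (g - fit0$mu)
  beta <- drop(crossprod(X, alpha))
  h <- colSums(X * (S %*% X))           # ridge leverages h_jj in [0, 1)
  h <- pmin(h, 1 - 1e-8)
  w <- beta^2 / (1 - h)
  if (sum(w) <= 0 || !all(is.finite(w))) return(0.01)
  w <- w / mean(w)
  Xw <- sweep(X, 2L, sqrt(w), "*")
  vw <- sum(apply(Xw, 2L, var))
  if (vw <= 0) return(0.01)
  fit1 <- fit_gblup(g, Z = NULL, K = grm_named(Xw))
  min(max(fit1$h2, 0.01), 0.99)
}

# grm() that tolerates bare matrices and keeps row names on K
grm_named <- function(X) {
  K <- grm(X)
  rownames(K) <- colnames(K) <- rownames(X)
  K
}
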