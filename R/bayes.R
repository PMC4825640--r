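#' Bayesian whole-genome regression (BayesA / BayesB) by Gibbs sampling
#'
#' Fits `g = mu + X b + e` with per-feature effect variances
#' \eqn{\sigma_{b_j}^2 \sim \chi^{-2}(df_b, S_b^2)} (BayesA), optionally
#' mixed with a point mass at zero with probability \eqn{\pi \sim
#' Beta(0.2, 1.8)} (BayesB).  The scale \eqn{S_b^2} carries a Gamma
#' hyperprior and the residual variance a scaled-inverse-chi-square prior.
#' Hyperparameters follow the usual heuristic: prior modes are matched so
#' that the implied proportion of variance explained equals `prior_R2`
#' given the features' summed sample variances (for BayesB, inflated by the
#' prior mean inclusion probability).
#'
#' @param g outcome vector (one value per genotype).
#' @param X complete feature matrix (genotypes x features).
#' @param variant `"A"` or `"B"`.
#' @param prior_R2 prior proportion of variance explained, in `(0, 1)`
#'   (e.g. from [hem_prior_r2()]).
#' @param burn_in,n_iter,thin chain settings (defaults: 5000 burn-in,
#'   15000 sampling iterations, no thinning).
#' @param df_b,df_e prior degrees of freedom.
#' @param seed RNG seed for the chain.
#' @return object of class `bayes_fit`: posterior means `mu`, `b`,
#'   `sigma_e2`, `S_b2`, `pi`, `inclusion` (BayesB), plus the settings.
#' @export
fit_bayes <- function(g, X, variant = c("A", "B"), prior_R2,
                      burn_in = 5000L, n_iter = 15000L, thin = 1L,
                      df_b = 5, df_e = 5, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(prior_R2 > 0, prior_R2 < 1, nrow(X) == length(g))
  if (anyNA(X)) stop("X must be complete")
  X <- unclass(X)
  vy <- var(g)
  if (vy == 0) vy <- 1e-8
  msx <- sum(apply(X, 2L, var))
  if (msx == 0) msx <- 1e-8
  pi_a <- 0.2; pi_b <- 1.8
  prior_incl <- pi_b / (pi_a + pi_b)   # pi is the exclusion probability
  target_s2b <- vy * prior_R2 / msx
  if (variant == "B") target_s2b <- target_s2b / prior_incl
  S_b2_mode <- target_s2b * (df_b + 2) / df_b
  r_b <- 1.1
  s_b <- r_b / S_b2_mode               # Gamma rate: prior mean = S_b2_mode
  S_e2 <- vy * (1 - prior_R2) * (df_e + 2) / df_e
  res <- with_seed(seed,
    .bayes_gibbs(as.numeric(g), X, variant == "B", df_b, r_b, s_b, df_e,
                 S_e2, pi_a, pi_b, as.integer(burn_in), as.integer(n_iter),
                 as.integer(thin)))
  structure(list(variant = variant, mu = res$mu,
                 b = setNames(res$b, colnames(X)),
                 sigma_e2 = res$sigma_e2, S_b2 = res$S_b2, pi = res$pi,
                 inclusion = if (variant == "B")
                   setNames(res$inclusion, colnames(X)) else NULL,
                 prior_R2 = prior_R2, burn_in = burn_in, n_iter = n_iter,
                 thin = thin, n_kept = res$n_kept, seed = seed),
            class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf("bayes_fit (Bayes%s): %d features, %d kept draws, sigma_e2 = %.4g\n",
              x$variant, length(x$b), x$n_kept, x$sigma_e2))
  invisible(x)
}

#' Predict from a Bayesian regression fit
#'
#' @param object a `bayes_fit`.
#' @param newdata feature matrix with the fit's features as columns.
#' @param ... unused.
#' @return named predictions `mu + X b`.
#' @export
predict.bayes_fit <- function(object, newdata, ...) {
  X <- unclass(newdata)
  if (!is.null(names(object$b))) X <- X[, names(object$b), drop = FALSE]
  stopifnot(ncol(X) == length(object$b))
  setNames(object$mu + drop(X %*% object$b), rownames(newdata))
}

#' Random-forest regression on marker features
#'
#' Thin wrapper around [randomForest::randomForest()] with the benchmark's
#' settings: 200 trees, bootstrap samples of size `n`, and random subsets
#' of `q/3` features at each split (at least 1).
#'
#' @param g outcome vector.
#' @param X complete feature matrix.
#' @param n_trees number of trees.
#' @param feature_fraction fraction of features tried per split.
#' @param seed RNG seed.
#' @return a `randomForest` object.
#' @export
fit_rf <- function(g, X, n_trees = 200L, feature_fraction = 1 / 3,
                   seed = 1L) {
  if (anyNA(X)) stop("X must be complete")
  X <- unclass(X)
  mtry <- max(1L, floor(ncol(X) * feature_fraction))
  with_seed(seed,
    randomForest::randomForest(x = X, y = as.numeric(g), ntree = n_trees,
                               mtry = mtry, replace = TRUE,
                               sampsize = nrow(X)))
}
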