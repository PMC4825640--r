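# Genetic analyses supporting the prediction benchmark: genomic
# correlations between outcomes, an EMMAX-style association scan with
# forward-BIC multi-marker modelling, and the multi-kernel partition of
# genomic heritability by degree of tagging.

# Dense REML negative log-likelihood (times 2) for y = X beta + N(0, V);
# also returns the profile quantities needed downstream.
dense_reml_neg2ll <- function(y, X, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE))
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cx)) return(list(ok = FALSE))
  beta <- backsolve(cx, forwardsolve(t(cx), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  yPy <- drop(crossprod(r, Vi_r))
  p <- ncol(X)
  neg2 <- logdetV + 2 * sum(log(diag(cx))) + yPy +
    (length(y) - p) * log(2 * pi)
  list(ok = TRUE, neg2 = neg2, beta = drop(beta), Vi_r = drop(Vi_r),
       logdetV = logdetV)
}

#' Bivariate GBLUP genomic correlation between two outcomes
#'
#' Fits the two-outcome GBLUP model with genetic covariance
#' \eqn{\Sigma_g \otimes K} and independent within-outcome errors by dense
#' REML (Nelder-Mead over log standard deviations and the atanh-transformed
#' correlation, initialized from univariate fits).  The genomic correlation
#' is \eqn{r_g = \sigma_{g12} / (\sigma_{g1}\sigma_{g2})}; its significance
#' comes from a likelihood-ratio test against `rg = 0`, referred to the
#' conservative 50:50 mixture of a point mass and chi-square(1).
#'
#' @param g1,g2 named outcome vectors (shared genotype ids; genotypes
#'   missing one outcome are dropped from that outcome's rows).
#' @param K named kernel covering the union of genotypes.
#' @return object of class `genomic_correlation`: `rg`, `p_value`,
#'   `genetic_cov` (2x2), `error_var` (length 2), `loglik`,
#'   `loglik_rg0`, `converged`.
#' @export
bivariate_gblup <- function(g1, g2, K) {
  K <- as.matrix(K)
  ids <- rownames(K)
  i1 <- match(names(g1), ids); i2 <- match(names(g2), ids)
  if (anyNA(i1) || anyNA(i2)) stop("genotype ids missing from K")
  y <- c(unname(g1), unname(g2))
  n1 <- length(g1); n2 <- length(g2)
  X <- rbind(cbind(rep(1, n1), 0), cbind(0, rep(1, n2)))
  K11 <- K[i1, i1]; K22 <- K[i2, i2]; K12 <- K[i1, i2]

  build_V <- function(s1, s2, rg, e1, e2) {
    V11 <- s1 * K11 + diag(e1, n1)
    V22 <- s2 * K22 + diag(e2, n2)
    V12 <- rg * sqrt(s1 * s2) * K12
    rbind(cbind(V11, V12), cbind(t(V12), V22))
  }
  obj <- function(par, fix_rg0 = FALSE) {
    s1 <- exp(par[1L]); s2 <- exp(par[2L])
    rg <- if (fix_rg0) 0 else tanh(par[3L])
    e1 <- exp(par[if (fix_rg0) 3L else 4L])
    e2 <- exp(par[if (fix_rg0) 4L else 5L])
    if (any(abs(par) > 20)) return(1e10)
    res <- dense_reml_neg2ll(y, X, build_V(s1, s2, rg, e1, e2))
    if (!res$ok) return(1e10)
    res$neg2
  }
  f1 <- fit_gblup(unname(g1), K = K11)
  f2 <- fit_gblup(unname(g2), K = K22)
  par0 <- c(log(max(f1$sigma_u2, 1e-4)), log(max(f2$sigma_u2, 1e-4)),
            atanh(0.1),
            log(max(f1$sigma_e2, 1e-4)), log(max(f2$sigma_e2, 1e-4)))
  op <- optim(par0, obj, method = "Nelder-Mead",
              control = list(maxit = 4000L, reltol = 1e-10))
  op2 <- optim(op$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000L, reltol = 1e-10))
  if (op2$value < op$value) op <- op2
  op0 <- optim(par0[-3L], obj, fix_rg0 = TRUE, method = "Nelder-Mead",
               control = list(maxit = 4000L, reltol = 1e-10))
  s1 <- exp(op$par[1L]); s2 <- exp(op$par[2L]); rg <- tanh(op$par[3L])
  lr <- max(op0$value - op$value, 0)
  p <- 0.5 * pchisq(lr, df = 1L, lower.tail = FALSE)  # 50:50 mixture
  structure(list(rg = rg, p_value = p,
                 genetic_cov = matrix(c(s1, rg * sqrt(s1 * s2),
                                        rg * sqrt(s1 * s2), s2), 2L),
                 error_var = c(exp(op$par[4L]), exp(op$par[5L])),
                 loglik = -op$value / 2, loglik_rg0 = -op0$value / 2,
                 converged = op$convergence == 0),
            class = "genomic_correlation")
}

#' @export
print.genomic_correlation <- function(x, ...) {
  cat(sprintf("genomic_correlation: rg = %.3f (p = %.3g)\n", x$rg,
              x$p_value))
  invisible(x)
}

#' EMMAX-style genome-wide association scan
#'
#' Estimates the GBLUP variance components once under the null model, then
#' tests each marker with minor allele frequency above `maf_min` as a fixed
#' effect by generalized least squares with the variance structure held
#' fixed (two-sided t test).  No population-structure covariates are
#' included.  Markers are flagged significant at Storey q-value `< 0.05`.
#'
#' @param g named outcome vector (one value per genotype).
#' @param M dosage matrix (genotypes x markers; rows matched to `g` by
#'   name).
#' @param K named kernel (typically `grm` of the Base features).
#' @param maf_min MAF threshold for testing.
#' @return object of class `gwas_result`: data.frame (`marker_id`, `maf`,
#'   `beta`, `se`, `p`, `q`, `significant`) plus null-model components in
#'   attributes.
#' @export
gwas_emmax <- function(g, M, K, maf_min = 0.05) {
  K <- as.matrix(K)
  ids <- names(g)
  M <- M[ids, , drop = FALSE]
  K <- K[ids, ids]
  null_fit <- fit_gblup(unname(g), K = K)
  lam <- null_fit$lambda
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  wts <- 1 / sqrt(pmax(eg$values, 0) + lam)
  Ut <- t(eg$vectors)
  ys <- wts * drop(Ut %*% unname(g))
  one_s <- wts * drop(Ut %*% rep(1, length(g)))
  p_freq <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p_freq, 1 - p_freq)
  test_idx <- which(maf > maf_min)
  Ms <- (Ut %*% impute_dosage(M[, test_idx, drop = FALSE])) * wts
  n <- length(g)
  res <- vapply(seq_along(test_idx), function(jj) {
    x <- Ms[, jj]
    Xs <- cbind(one_s, x)
    XtX <- crossprod(Xs)
    sol <- tryCatch(solve(XtX), error = function(e) NULL)
    if (is.null(sol)) return(c(NA_real_, NA_real_, 1))
    bh <- drop(sol %*% crossprod(Xs, ys))
    rr <- ys - drop(Xs %*% bh)
    s2 <- sum(rr^2) / (n - 2L)
    se <- sqrt(s2 * sol[2L, 2L])
    tval <- bh[2L] / se
    c(bh[2L], se, 2 * pt(-abs(tval), df = n - 2L))
  }, numeric(3L))
  out <- data.frame(marker_id = colnames(M)[test_idx],
                    maf = maf[test_idx],
                    beta = res[1L, ], se = res[2L, ], p = res[3L, ],
                    stringsAsFactors = FALSE)
  out$q <- qvalues(out$p)
  out$significant <- out$q < 0.05
  structure(out, null_h2 = null_fit$h2, lambda = lam,
            class = c("gwas_result", "data.frame"))
}

#' Forward stepwise marker selection by BIC in a mixed model
#'
#' Greedily adds, from the candidate set, the marker whose inclusion as a
#' fixed effect most lowers the BIC of the mixed model with genomic random
#' term (`K`), refitting the variance components by maximum likelihood at
#' each step; stops when no candidate lowers the BIC.  Near-collinear
#' candidates (with the current fixed effects) are skipped.
#'
#' @param g named outcome vector.
#' @param M dosage matrix (columns include the candidates).
#' @param candidates marker ids to consider (e.g. the significant GWAS
#'   set).
#' @param K named kernel.
#' @return list: `selected` (ids in selection order), `bic_path`,
#'   `loglik_full`, `loglik_null`, `r2_lr` (likelihood-ratio R-squared of
#'   the final fixed-marker model against the null).
#' @export
forward_bic <- function(g, M, candidates, K) {
  ids <- names(g)
  K <- as.matrix(K)[ids, ids]
  M <- impute_dosage(M[ids, , drop = FALSE])
  n <- length(g)
  y <- unname(g)
  ml_fit <- function(X) {
    fml <- function(loglam) {
      # ML with V = s2u (K + lam I); s2u profiled analytically
      lam <- exp(loglam)
      ch <- tryCatch(chol(K + diag(lam, n)), error = function(e) NULL)
      if (is.null(ch)) return(list(obj = 1e10))
      Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
      Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
      beta <- tryCatch(solve(crossprod(X, Vi_X), crossprod(X, Vi_y)),
                       error = function(e) NULL)
      if (is.null(beta)) return(list(obj = 1e10))
      r <- y - drop(X %*% beta)
      Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
      rss <- drop(crossprod(r, Vi_r))
      s2u <- rss / n
      if (s2u <= 0) return(list(obj = 1e10))
      obj <- n * log(s2u) + 2 * sum(log(diag(ch))) + n * (1 + log(2 * pi))
      list(obj = obj, beta = drop(beta), s2u = s2u, lam = lam)
    }
    op <- optimize(function(l) fml(l)$obj, c(-12, 12), tol = 1e-7)
    fml(op$minimum)
  }
  bic_of <- function(fit, p_fix) fit$obj + (p_fix + 2) * log(n)
  X0 <- matrix(1, n, 1L)
  cur <- ml_fit(X0)
  loglik_null <- -cur$obj / 2
  selected <- character(0)
  bic_path <- bic_of(cur, 1L)
  pool <- candidates
  Xcur <- X0
  while (length(pool) > 0) {
    best <- NULL
    for (cand in pool) {
      xc <- M[, cand]
      Xtry <- cbind(Xcur, xc)
      if (qr(Xtry)$rank < ncol(Xtry)) next  # collinear with current set
      fit <- ml_fit(Xtry)
      if (is.null(fit$beta)) next
      bic <- bic_of(fit, ncol(Xtry))
      if (is.null(best) || bic < best$bic)
        best <- list(cand = cand, bic = bic, fit = fit, X = Xtry)
    }
    if (is.null(best) || best$bic >= bic_path[length(bic_path)]) break
    selected <- c(selected, best$cand)
    bic_path <- c(bic_path, best$bic)
    Xcur <- best$X
    cur <- best$fit
    pool <- setdiff(pool, best$cand)
  }
  loglik_full <- -cur$obj / 2
  list(selected = selected, bic_path = bic_path,
       loglik_full = loglik_full, loglik_null = loglik_null,
       r2_lr = if (length(selected) > 0)
         r2_lr(loglik_full, loglik_null, n) else 0)
}

#' Likelihood-ratio R-squared
#'
#' \eqn{R^2_{LR} = 1 - \exp(-\frac{2}{n}(\ell_{full} - \ell_{null}))}.
#'
#' @param loglik_full,loglik_null log-likelihoods of nested models
#'   (`loglik_full >= loglik_null`).
#' @param n sample size.
#' @return value in `[0, 1)`.
#' @export
r2_lr <- function(loglik_full, loglik_null, n) {
  if (loglik_full < loglik_null - 1e-8)
    stop("negative likelihood ratio: full model fits worse than null")
  1 - exp(-(2 / n) * max(loglik_full - loglik_null, 0))
}

#' Partition genomic heritability by degree-of-tagging tertiles
#'
#' Splits markers into three classes at the nearest-rank tertiles of their
#' degree of tagging (ties to the lower class), builds one genomic
#' relationship kernel per class from the Base features, and fits the
#' multi-kernel model \eqn{y = \mu + u_1 + u_2 + u_3 + e},
#' \eqn{u_j \sim N(0, K_j \sigma_{u_j}^2)} by dense REML (Nelder-Mead over
#' log variances with a restart).  The contribution of class `j` is
#' \eqn{\sigma_{u_j}^2 / (\sum_{j'} \sigma_{u_{j'}}^2 + \sigma_e^2)}.
#'
#' @param g named outcome vector.
#' @param x_base Base feature matrix (genotypes x markers).
#' @param tagging named degree-of-tagging vector over the markers.
#' @return object of class `h2_partition`: `contributions` (low,
#'   intermediate, high), `varcomp`, `classes` (per marker), `loglik`.
#' @export
partition_heritability <- function(g, x_base, tagging) {
  ids <- names(g)
  X <- unclass(x_base)[ids, , drop = FALSE]
  tagging <- tagging[colnames(X)]
  if (anyNA(tagging)) stop("tagging values missing for some markers")
  qs <- quantile(tagging, c(1 / 3, 2 / 3), type = 1L)
  cls <- cut(tagging, unique(c(-Inf, qs, Inf)),
             labels = c("low", "intermediate", "high")[
               seq_len(length(unique(c(-Inf, qs, Inf))) - 1L)])
  use <- names(which(table(cls) >= 3L))  # degenerate tiny classes get 0
  if (length(use) == 0L) stop("every tagging class has fewer than 3 markers")
  Ks <- lapply(use, function(lv) grm_named(X[, cls == lv, drop = FALSE]))
  names(Ks) <- use
  nk <- length(Ks)
  y <- unname(g)
  n <- length(y)
  Xf <- matrix(1, n, 1L)
  obj <- function(par) {
    if (any(abs(par) > 20)) return(1e10)
    v <- exp(par)
    V <- diag(v[nk + 1L], n)
    for (j in seq_len(nk)) V <- V + v[j] * Ks[[j]]
    res <- dense_reml_neg2ll(y, Xf, V)
    if (!res$ok) return(1e10)
    res$neg2
  }
  vy <- var(y)
  par0 <- log(c(rep(vy / (2 * nk), nk), vy / 2))
  op <- optim(par0, obj, method = "Nelder-Mead",
              control = list(maxit = 4000L, reltol = 1e-10))
  op2 <- optim(op$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000L, reltol = 1e-10))
  if (op2$value < op$value) op <- op2
  v <- exp(op$par)
  tot <- sum(v)
  contributions <- setNames(rep(0, 3L), c("low", "intermediate", "high"))
  contributions[use] <- v[seq_len(nk)] / tot
  contributions <- contributions[c("low", "intermediate", "high")]
  structure(list(contributions = contributions,
                 varcomp = setNames(v, c(use, "residual")),
                 classes = setNames(cls, colnames(X)),
                 loglik = -op$value / 2),
            class = "h2_partition")
}

#' @export
print.h2_partition <- function(x, ...) {
  cat("h2_partition (share of total variance):\n")
  print(round(x$contributions, 3))
  invisible(x)
}
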