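# Sparse-MME REML engine for the phenotype mixed models.
#
# Model: y = 1 mu + sum_r Z_r u_r + e,  u_r ~ N(0, sigma_e^2 theta_r G_r),
# e ~ N(0, sigma_e^2 I), with G_r = I for i.i.d. terms and
# G_r = AR1(rho_row) x AR1(rho_col) for the spatial plot term.  The residual
# variance is profiled out, so the optimization runs over log variance
# ratios (and atanh-transformed AR1 correlations) only; each evaluation is a
# sparse Cholesky update of the mixed-model-equation coefficient matrix.

ar1_precision <- function(n, rho) {
  # tridiagonal inverse of the unit-variance AR1 correlation matrix
  if (n == 1L) return(Matrix::Diagonal(1L))
  d <- c(1, rep(1 + rho^2, n - 2L), 1) / (1 - rho^2)
  od <- rep(-rho / (1 - rho^2), n - 1L)
  Matrix::bandSparse(n, k = c(-1L, 0L, 1L),
                     diagonals = list(od, d, od), symmetric = FALSE)
}

indicator_matrix <- function(f) {
  f <- droplevels(as.factor(f))
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f),
                       x = 1, dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

#' REML fit of a variance-components mixed model by sparse MME
#'
#' Fits `y = mu + sum_r u_r + e` with independent random terms given as
#' factors, and optionally a spatially correlated plot term with separable
#' first-order autoregressive row/column covariance.  The residual variance
#' is profiled analytically; the remaining variance ratios (and AR1
#' correlations) are maximized by derivative-free Nelder-Mead on an
#' unbounded scale (log ratios, atanh correlations), solving the sparse
#' mixed-model equations at each evaluation.
#'
#' @param y numeric response.
#' @param random named list of factors (one entry per i.i.d. random term).
#' @param spatial optional list with `row` and `col` integer indices per
#'   observation; adds a plot effect over the implied grid.
#' @param pev_term name of the random term for which prediction-error
#'   variances of the BLUPs are returned.
#' @param control list: `maxit`, `reltol`, `restarts`.
#' @return list with `varcomp` (named variances, includes `residual`),
#'   `rho` (length-2, spatial only), `blup` (list of named vectors),
#'   `pev` (for `pev_term`), `mu`, `loglik` (REML), `bic`,
#'   `n`, `k_varpar`, `convergence`.
#' @export
reml_mixed <- function(y, random, spatial = NULL, pev_term = NULL,
                       control = list()) {
  n <- length(y)
  stopifnot(n > 2L, length(random) >= 1L, !is.null(names(random)))
  ctrl <- utils::modifyList(list(maxit = 3000L, reltol = 1e-10,
                                 restarts = 1L), control)
  Zs <- lapply(random, indicator_matrix)
  qs <- vapply(Zs, ncol, integer(1L))
  has_sp <- !is.null(spatial)
  if (has_sp) {
    n_row <- max(spatial$row); n_col <- max(spatial$col)
    cell <- factor((spatial$row - 1L) * n_col + spatial$col,
                   levels = seq_len(n_row * n_col))
    Zp <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(cell), x = 1,
                               dims = c(n, n_row * n_col))
    Zs <- c(Zs, list(.plot = Zp))
    qs <- c(qs, .plot = ncol(Zp))
  }
  Z <- do.call(cbind, Zs)
  X <- Matrix::Matrix(1, n, 1L)
  W <- cbind(X, Z)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Wty <- Matrix::crossprod(W, y)
  yty <- sum(y^2)
  p <- 1L
  n_terms <- length(Zs)
  offs <- p + c(0L, cumsum(qs))[seq_len(n_terms)]  # start index per term in W

  chol_cache <- new.env(parent = emptyenv())
  eval_neg2ll <- function(par, want_fit = FALSE) {
    lt <- par[seq_len(n_terms)]
    if (any(abs(lt) > 18)) return(if (want_fit) NULL else 1e10)
    theta <- exp(lt)
    if (has_sp) {
      rho <- tanh(par[n_terms + 1:2])
      rho <- pmax(pmin(rho, 0.99), -0.99)
    }
    Binvs <- vector("list", n_terms)
    logdetG <- 0
    for (r in seq_len(n_terms)) {
      nm <- names(Zs)[r]
      if (has_sp && nm == ".plot") {
        Q <- Matrix::kronecker(ar1_precision(n_row, rho[1L]),
                               ar1_precision(n_col, rho[2L]))
        Binvs[[r]] <- Q / theta[r]
        logdetG <- logdetG + qs[r] * log(theta[r]) +
          n_col * (n_row - 1L) * log(1 - rho[1L]^2) / 1 +
          n_row * (n_col - 1L) * log(1 - rho[2L]^2) / 1
      } else {
        Binvs[[r]] <- Matrix::Diagonal(qs[r], 1 / theta[r])
        logdetG <- logdetG + qs[r] * log(theta[r])
      }
    }
    B <- Matrix::bdiag(c(list(Matrix::Matrix(0, p, p)), Binvs))
    C <- Matrix::forceSymmetric(WtW + B)
    # the sparsity pattern is constant across evaluations only without the
    # spatial term (whose AR1 precision bands vanish at rho = 0), so the
    # symbolic factorization is reused only in the i.i.d. case
    ch <- tryCatch({
      if (has_sp) {
        Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
      } else if (is.null(chol_cache$sym)) {
        chol_cache$sym <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
        chol_cache$sym
      } else Matrix::update(chol_cache$sym, C)
    }, error = function(e) NULL)
    if (is.null(ch)) return(if (want_fit) NULL else 1e10)
    logdetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    bhat <- Matrix::solve(ch, Wty, system = "A")
    ssr <- yty - sum(bhat * Wty)
    if (ssr <= 0) return(if (want_fit) NULL else 1e10)
    sigma_e2 <- ssr / (n - p)
    neg2 <- as.numeric((n - p) * (log(sigma_e2) + 1 + log(2 * pi)) +
                         logdetG + logdetC)
    if (!want_fit) return(neg2)
    list(neg2 = neg2, sigma_e2 = sigma_e2, theta = theta,
         rho = if (has_sp) rho else NULL, bhat = as.numeric(bhat), ch = ch)
  }

  par0 <- rep(log(1 / n_terms), n_terms)
  if (has_sp) par0 <- c(par0, atanh(0.3), atanh(0.3))
  if (length(par0) == 1L) {
    op <- optimize(function(x) eval_neg2ll(x), c(-18, 18), tol = 1e-9)
    best <- list(par = op$minimum, value = op$objective, convergence = 0L)
  } else {
    best <- optim(par0, eval_neg2ll, method = "Nelder-Mead",
                  control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    for (i in seq_len(ctrl$restarts)) {
      again <- optim(best$par, eval_neg2ll, method = "Nelder-Mead",
                     control = list(maxit = ctrl$maxit,
                                    reltol = ctrl$reltol))
      if (again$value < best$value) best <- again
    }
  }
  fit <- eval_neg2ll(best$par, want_fit = TRUE)
  if (is.null(fit)) stop("REML optimization failed at the optimum")

  varcomp <- setNames(fit$sigma_e2 * fit$theta, names(Zs))
  names(varcomp)[names(varcomp) == ".plot"] <- "plot"
  varcomp <- c(varcomp, residual = fit$sigma_e2)
  blup <- list()
  for (r in seq_len(n_terms)) {
    idx <- offs[r] + seq_len(qs[r])
    blup[[names(Zs)[r]]] <- setNames(fit$bhat[idx], colnames(Zs[[r]]))
  }
  names(blup)[names(blup) == ".plot"] <- "plot"
  pev <- NULL
  if (!is.null(pev_term)) {
    r <- match(pev_term, names(random))
    if (is.na(r)) stop("unknown pev_term")
    idx <- offs[r] + seq_len(qs[r])
    E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                              dims = c(ncol(W), length(idx)))
    Cinv_cols <- Matrix::solve(fit$ch, E, system = "A")
    pev <- setNames(fit$sigma_e2 * Matrix::diag(Matrix::crossprod(E, Cinv_cols)),
                    colnames(Zs[[r]]))
  }
  k <- n_terms + 1L + if (has_sp) 2L else 0L
  loglik <- -fit$neg2 / 2
  list(varcomp = varcomp, rho = fit$rho, blup = blup, pev = pev,
       mu = fit$bhat[1L], loglik = loglik, bic = fit$neg2 + k * log(n),
       n = n, k_varpar = k, convergence = best$convergence)
}
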