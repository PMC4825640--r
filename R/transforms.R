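# Marker-data transformations.  All four produce an m x q feature matrix X
# whose cross-product (suitably normalized) is the genomic relationship
# kernel of a GBLUP model: Base keeps centered dosages, PCA rotates them,
# Cor whitens them through the inverse local correlation matrix, LD rescales
# them by tagging weights.  A feature_matrix is a plain numeric matrix with
# attributes "transform", "provenance" (feature -> marker id; NULL for PCA)
# and "scope".

new_feature_matrix <- function(values, transform, provenance, scope = NULL) {
  structure(values, transform = transform, provenance = provenance,
            scope = scope, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix (%s): %d genotypes x %d features\n",
              attr(x, "transform"), nrow(x), ncol(x)))
  invisible(x)
}

#' Base transformation: centered allelic dosages
#'
#' Subtracts each marker's mean dosage within the declared scope (the set of
#' individuals passed in), i.e. `X = M - P` with `P` carrying uniform
#' columns of mean dosages.  Missing dosages are mean-imputed first.
#'
#' @param dm a `dosage_matrix` or bare numeric matrix.
#' @param individuals optional subset of row ids defining the scope.
#' @param scope label stored on the result.
#' @return a `feature_matrix` with transform tag `"Base"`.
#' @export
base_transform <- function(dm, individuals = NULL, scope = NULL) {
  V <- if (inherits(dm, "dosage_matrix")) dm$values else dm
  if (!is.null(individuals)) V <- V[individuals, , drop = FALSE]
  V <- impute_dosage(V)
  X <- scale(V, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  new_feature_matrix(X, "Base", colnames(V), scope)
}

#' PCA transformation of centered dosages
#'
#' Rotates the Base features onto their right singular vectors:
#' `X_PCA = X_Base V = U D` from the thin singular value decomposition, with
#' as many components as genotypes, ordered by decreasing singular value.
#' In a GBLUP kernel this is exactly equivalent to Base since `V'V = I`.
#'
#' @param x_base a Base `feature_matrix`.
#' @return a `feature_matrix` with transform tag `"PCA"` (no feature ->
#'   marker provenance).
#' @export
pca_transform <- function(x_base) {
  sv <- svd(x_base, nu = nrow(x_base), nv = 0L)
  d <- numeric(nrow(x_base))
  d[seq_along(sv$d)] <- sv$d
  X <- sv$u %*% diag(d, nrow(x_base))
  rownames(X) <- rownames(x_base)
  colnames(X) <- sprintf("PC%03d", seq_len(ncol(X)))
  new_feature_matrix(X, "PCA", NULL, attr(x_base, "scope"))
}

#' Cor transformation: whitening through the local LD precision matrix
#'
#' Per chromosome block, computes \eqn{\Theta = R^{-1}}, factors
#' \eqn{\Theta = L L'} with `L` lower triangular, and maps the block's Base
#' columns through `L`.  The induced GBLUP kernel equals
#' \eqn{X_{Base} \Theta X_{Base}'}, i.e. Base with local LD accounted for.
#'
#' @param x_base a Base `feature_matrix`.
#' @param cb PD-adjusted `corr_blocks` covering the Base markers.
#' @return a `feature_matrix` with transform tag `"Cor"`.
#' @export
cor_transform <- function(x_base, cb) {
  stopifnot(inherits(cb, "corr_blocks"))
  ids <- colnames(x_base)
  out <- matrix(0, nrow(x_base), ncol(x_base),
                dimnames = dimnames(x_base))
  for (b in cb$blocks) {
    idx <- match(b$marker_ids, ids)
    if (anyNA(idx)) stop("correlation block markers missing from features")
    Theta <- tryCatch(chol2inv(chol(b$R)),
                      error = function(e) stop("block not PD; run nearest_pd first"))
    L <- t(chol(Theta))  # lower triangular, L L' = Theta
    out[, idx] <- x_base[, idx, drop = FALSE] %*% L
  }
  new_feature_matrix(out, "Cor", ids, attr(x_base, "scope"))
}

#' LD transformation: tagging-weight rescaling
#'
#' Scales Base column `j` by \eqn{\sqrt{w_j}} using the LDAK-style weights
#' and drops columns with weight exactly zero, so the induced GBLUP kernel
#' equals \eqn{X_{Base} W X_{Base}'}.
#'
#' @param x_base a Base `feature_matrix`.
#' @param weights named nonnegative weights from [ld_weights()].
#' @return a `feature_matrix` with transform tag `"LD"` (possibly fewer
#'   columns than Base).
#' @export
ld_transform <- function(x_base, weights) {
  w <- weights[colnames(x_base)]
  if (anyNA(w)) stop("weights missing for some markers")
  if (any(w < 0)) stop("negative tagging weight")
  keep <- which(w > 0)
  X <- sweep(x_base[, keep, drop = FALSE], 2L, sqrt(w[keep]), "*")
  new_feature_matrix(X, "LD", colnames(x_base)[keep], attr(x_base, "scope"))
}

#' Genomic relationship kernel from marker features
#'
#' `K = X X' / sum_j var(X_j)` with sample variances over the feature
#' columns, so the kernel is scale-stable across transformations.
#'
#' @param x a `feature_matrix` (or numeric matrix).
#' @return object of class `kernel_matrix`: the m x m matrix with
#'   attributes `kind = "GRM"` and `normalizer`.
#' @export
grm <- function(x) {
  if (nrow(x) < 2L) stop("need >= 2 genotypes")
  norm <- sum(apply(x, 2L, var))
  if (norm == 0) stop("all-zero feature matrix")
  K <- tcrossprod(unclass(x)) / norm
  structure(K, kind = "GRM", normalizer = norm,
            class = c("kernel_matrix", "matrix", "array"))
}

#' Scaled Euclidean distances between genotypes
#'
#' Pairwise Euclidean distances on the feature rows, divided by the maximum
#' pairwise distance, so the largest off-diagonal entry is exactly 1.
#'
#' @param x a `feature_matrix`.
#' @return m x m symmetric matrix with zero diagonal.
#' @export
scaled_distance <- function(x) {
  if (nrow(x) < 2L) stop("need >= 2 genotypes")
  D <- as.matrix(dist(unclass(x)))
  mx <- max(D)
  if (mx == 0) stop("all genotypes identical: maximum distance is zero")
  D / mx
}

#' Gaussian kernel from scaled distances
#'
#' `K_ij = exp(-d_ij^2 / theta)`; with distances scaled to max 1 the kernel
#' entries lie in `[exp(-1/theta), 1]` and the diagonal is exactly 1.
#'
#' @param distances scaled distance matrix (see [scaled_distance()]).
#' @param theta scale parameter, `> 0` (tuned on `(0, 1)` in practice).
#' @return a `kernel_matrix` of kind `"Gaussian"`.
#' @export
gaussian_kernel <- function(distances, theta) {
  if (theta <= 0) stop("theta must be positive")
  K <- exp(-distances^2 / theta)
  structure(K, kind = "Gaussian", normalizer = theta,
            class = c("kernel_matrix", "matrix", "array"))
}
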