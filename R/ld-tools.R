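# Low-level: per-chromosome Pearson correlation blocks from a complete
# numeric matrix (individuals x markers).
block_correlation_matrix <- function(values, chrom) {
  stopifnot(ncol(values) == length(chrom))
  sds <- apply(values, 2L, sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance marker column '%s'",
                 colnames(values)[which(sds == 0)[1L]]))
  blocks <- lapply(unique(chrom), function(cc) {
    idx <- which(chrom == cc)
    R <- cor(values[, idx, drop = FALSE])
    list(chrom = cc, marker_ids = colnames(values)[idx], R = R)
  })
  structure(list(blocks = blocks, pd_adjusted = FALSE, floor = NA_real_),
            class = "corr_blocks")
}

#' Block-diagonal marker correlation matrix
#'
#' Builds the per-chromosome Pearson correlation blocks of the marker
#' dosages (cross-chromosome correlations are implicitly zero, i.e. only
#' local LD is represented).  Missing dosages are mean-imputed per column
#' before computing correlations.
#'
#' @param dm a `dosage_matrix` (or a bare numeric matrix if `chrom` is
#'   given).
#' @param chrom chromosome labels per marker (taken from `dm$marker_info`
#'   when `dm` is a `dosage_matrix`).
#' @return object of class `corr_blocks`: list of blocks (`chrom`,
#'   `marker_ids`, `R`), with `pd_adjusted` flag and eigenvalue `floor`.
#' @export
block_correlation <- function(dm, chrom = NULL) {
  if (inherits(dm, "dosage_matrix")) {
    values <- impute_dosage(dm$values)
    chrom <- dm$marker_info$chrom
  } else values <- impute_dosage(dm)
  if (nrow(values) < 2L) stop("need >= 2 individuals")
  block_correlation_matrix(values, chrom)
}

#' Project correlation blocks to positive definiteness
#'
#' Each block is run through the alternating-projection algorithm of Higham
#' (eigenvalue clipping alternated with unit-diagonal restoration, via
#' [Matrix::nearPD()]) until its smallest eigenvalue is at least
#' `floor_frac` times its largest, which guarantees a Cholesky factorization
#' in double precision.  Blocks that already satisfy the floor are returned
#' unchanged.
#'
#' @param cb a `corr_blocks` object (or a single symmetric matrix).
#' @param floor_frac eigenvalue floor relative to the largest eigenvalue.
#' @return the input with PD-adjusted blocks, `pd_adjusted = TRUE` and the
#'   floor recorded.
#' @export
nearest_pd <- function(cb, floor_frac = 1e-8) {
  fix_block <- function(R) {
    if (!isSymmetric(unname(R), tol = 1e-10)) stop("block must be symmetric")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= floor_frac * max(ev)) return(R)
    out <- Matrix::nearPD(R, corr = TRUE, posd.tol = floor_frac,
                          maxit = 200L)
    if (!out$converged) stop("nearest-PD projection did not converge")
    M <- as.matrix(out$mat)
    dimnames(M) <- dimnames(R)
    M
  }
  if (is.matrix(cb)) return(fix_block(cb))
  stopifnot(inherits(cb, "corr_blocks"))
  cb$blocks <- lapply(cb$blocks, function(b) { b$R <- fix_block(b$R); b })
  cb$pd_adjusted <- TRUE
  cb$floor <- floor_frac
  cb
}

#' Degree of tagging per marker
#'
#' For marker `j`, the sum of squared correlations between `j` and every
#' marker on the same chromosome, self-term included (so the minimum value
#' is 1).  High values indicate redundant marker signal.
#'
#' @param cb a `corr_blocks` object.
#' @return named numeric vector over markers, in block order.
#' @export
degree_of_tagging <- function(cb) {
  stopifnot(inherits(cb, "corr_blocks"))
  out <- unlist(lapply(cb$blocks, function(b)
    setNames(rowSums(b$R^2), b$marker_ids)))
  out
}

# Dense tableau simplex for min c'x s.t. Ax = b, x >= 0, with b >= 0 and an
# initial identity basis supplied by the caller.  Bland's rule prevents
# cycling.  Small-scale by design: the tagging-weight LPs are solved per
# chromosome block.
simplex_solve <- function(A, b, cost, basis, max_iter = NULL) {
  m <- nrow(A); nv <- ncol(A)
  if (is.null(max_iter)) max_iter <- 50L * (m + nv)
  Tb <- cbind(A, b)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) stop("simplex iteration limit reached")
    cb <- cost[basis]
    # reduced costs: c - c_B B^{-1} A; tableau is kept in basis-canonical form
    red <- cost - drop(crossprod(cb, Tb[, seq_len(nv), drop = FALSE]))
    enter <- which(red < -1e-10)
    if (length(enter) == 0L) break
    j <- min(enter)  # Bland
    col <- Tb[, j]
    pos <- which(col > 1e-12)
    if (length(pos) == 0L) stop("unbounded LP")
    ratio <- Tb[pos, nv + 1L] / col[pos]
    leave_candidates <- pos[ratio <= min(ratio) + 1e-12]
    i <- leave_candidates[which.min(basis[leave_candidates])]  # Bland
    # pivot
    Tb[i, ] <- Tb[i, ] / Tb[i, j]
    others <- setdiff(seq_len(m), i)
    Tb[others, ] <- Tb[others, ] - outer(Tb[others, j], Tb[i, ])
    basis[i] <- j
  }
  x <- numeric(nv)
  x[basis] <- Tb[, nv + 1L]
  list(x = x, objective = sum(cost * x), basis = basis, iterations = it)
}

# min || A w - b ||_1 subject to w >= 0, via the standard LP split
# A w + s+ - s- = b with slack costs 1; requires b >= 0 so that s+ = b is a
# starting basic feasible solution.
l1_nonneg_fit <- function(A, b) {
  stopifnot(all(b >= 0))
  m <- nrow(A); q <- ncol(A)
  Afull <- cbind(A, diag(m), -diag(m))
  cost <- c(rep(0, q), rep(1, 2 * m))
  basis <- q + seq_len(m)
  sol <- simplex_solve(Afull, b, cost, basis)
  w <- sol$x[seq_len(q)]
  w[w < 0] <- 0
  list(w = w, objective = sol$objective)
}

#' LDAK-style tagging weights
#'
#' Per chromosome block, solves the least-absolute-error problem
#' \eqn{\min_w \| (R \circ R) w - 1 \|_1} subject to \eqn{w_j \ge 0}, where
#' \eqn{R \circ R} is the elementwise-squared correlation block.  Markers in
#' highly redundant LD neighbourhoods receive low (possibly exactly zero)
#' weights; isolated markers receive weights near 1.
#'
#' @param cb a `corr_blocks` object (PD adjustment not required; only the
#'   squared correlations enter).
#' @return named nonnegative weight vector over markers, in block order,
#'   with per-block L1 objectives in attribute `"objective"`.
#' @export
ld_weights <- function(cb) {
  stopifnot(inherits(cb, "corr_blocks"))
  fits <- lapply(cb$blocks, function(b) {
    f <- l1_nonneg_fit(b$R^2, rep(1, nrow(b$R)))
    list(w = setNames(f$w, b$marker_ids), obj = f$objective)
  })
  w <- unlist(lapply(fits, `[[`, "w"))
  attr(w, "objective") <- vapply(fits, `[[`, numeric(1L), "obj")
  w
}

#' Tagging statistics table
#'
#' Convenience wrapper joining [degree_of_tagging()] and [ld_weights()] into
#' one per-marker table.
#'
#' @param cb a `corr_blocks` object.
#' @return data.frame: `marker_id`, `chrom`, `degree_of_tagging`,
#'   `ld_weight`.
#' @export
tag_stats <- function(cb) {
  dot <- degree_of_tagging(cb)
  w <- ld_weights(cb)
  chrom <- unlist(lapply(cb$blocks, function(b)
    rep(b$chrom, length(b$marker_ids))))
  data.frame(marker_id = names(dot), chrom = chrom,
             degree_of_tagging = unname(dot),
             ld_weight = unname(w[names(dot)]),
             stringsAsFactors = FALSE)
}
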