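# Genotype-likelihood machinery shared by the EM fit and the posterior-mean
# dosage call.  Reads are modelled per marker: given true dosage d in {0,1,2}
# and error rate eps, each read shows the alternate allele with probability
# pi_d = (d/2)(1 - eps) + (1 - d/2) eps; the alternate count is Binomial and
# the binomial coefficient cancels in every posterior, so it is omitted.
hwe_prior <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

dosage_loglik_matrix <- function(ref, alt, eps) {
  # rows: individuals, cols: d = 0, 1, 2 (unnormalized log-likelihood);
  # 0 * log(0) is treated as 0 so that eps = 0 stays well defined
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  pi_d <- c(eps, 0.5, 1 - eps)
  out <- sapply(pi_d, function(pd) xlogy(alt, pd) + xlogy(ref, 1 - pd))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  out
}

#' Fit per-marker allele frequency and sequencing error rate by EM
#'
#' For one marker, treats each individual's true dosage as a latent variable
#' with Hardy-Weinberg prior \eqn{(1-p)^2, 2p(1-p), p^2} and a binomial read
#' likelihood, and maximizes the marginal likelihood over the allele
#' frequency `p` and the error rate \eqn{\epsilon} by
#' expectation-maximization.  The E-step computes genotype posteriors; the
#' M-step updates `p` from the posterior mean dosage and \eqn{\epsilon} from
#' the posterior-expected mismatch fraction (reads at heterozygotes carry no
#' information on \eqn{\epsilon} beyond the current estimate).
#'
#' @param ref_counts,alt_counts nonnegative integer vectors over individuals.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter iteration cap.
#' @return object of class `marker_em_fit`: list with `error_rate`,
#'   `allele_freq`, `loglik`, `loglik_trace`, `n_iterations`, `converged`,
#'   `fit_ok`.
#' @export
em_fit_marker <- function(ref_counts, alt_counts, tol = 1e-6,
                          max_iter = 200L) {
  stopifnot(length(ref_counts) == length(alt_counts))
  if (any(ref_counts < 0) || any(alt_counts < 0)) stop("counts must be >= 0")
  depth <- ref_counts + alt_counts
  use <- which(depth > 0)
  if (length(use) == 0L) {
    return(structure(list(error_rate = NA_real_, allele_freq = NA_real_,
                          loglik = NA_real_, loglik_trace = numeric(0),
                          n_iterations = 0L, converged = FALSE,
                          fit_ok = FALSE), class = "marker_em_fit"))
  }
  r <- ref_counts[use]; a <- alt_counts[use]; n <- depth[use]
  eps_lo <- 1e-6; eps_hi <- 0.5 - 1e-6
  p <- min(max(sum(a) / sum(n), 1e-3), 1 - 1e-3)
  eps <- 0.01
  ll_trace <- numeric(0)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    lg <- dosage_loglik_matrix(r, a, eps)
    lp <- sweep(lg, 2L, log(pmax(hwe_prior(p), 1e-300)), "+")
    mx <- apply(lp, 1L, max)
    w <- exp(lp - mx)
    ll <- sum(mx + log(rowSums(w)))
    gam <- w / rowSums(w)
    # M-step
    p <- sum(gam %*% c(0, 1, 2)) / (2 * length(r))
    mism <- gam[, 1L] * a + gam[, 3L] * r + gam[, 2L] * eps * n
    eps <- min(max(sum(mism) / sum(n), eps_lo), eps_hi)
    p <- min(max(p, 0), 1)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  structure(list(error_rate = eps, allele_freq = p,
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, n_iterations = it,
                 converged = converged, fit_ok = TRUE),
            class = "marker_em_fit")
}

#' Posterior-mean allelic dosage given read counts
#'
#' Bayes rule over latent dosages `d = 0, 1, 2` with the Hardy-Weinberg prior
#' at allele frequency `p` and binomial read likelihood at error rate `eps`;
#' returns the posterior-weighted sum of dosages.  With zero depth the
#' posterior equals the prior and the expected dosage is `2p`.
#'
#' @param ref_count,alt_count nonnegative counts (vectors allowed).
#' @param eps error rate in `[0, 0.5)`.
#' @param p allele frequency in `[0, 1]`.
#' @return expected dosage(s) in `[0, 2]`.
#' @export
expected_dosage <- function(ref_count, alt_count, eps, p) {
  stopifnot(eps >= 0, eps < 0.5, p >= 0, p <= 1)
  # degenerate priors pin the dosage regardless of reads
  if (p == 0) return(rep(0, length(ref_count)))
  if (p == 1) return(rep(2, length(ref_count)))
  prior <- hwe_prior(p)
  lg <- dosage_loglik_matrix(ref_count, alt_count, eps)
  if (is.null(dim(lg))) lg <- matrix(lg, nrow = 1L)
  lg[ref_count + alt_count == 0, ] <- 0  # zero depth: posterior = prior
  po <- exp(sweep(lg, 1L, apply(lg, 1L, max), "-"))
  po <- sweep(po, 2L, prior, "*")
  drop(po %*% c(0, 1, 2) / rowSums(po))
}

#' Call an expected-dosage matrix from read counts, per population
#'
#' Runs [em_fit_marker()] for every marker within each population separately
#' and fills individuals' dosages from their own population's fit via
#' [expected_dosage()].  Markers whose EM fit fails in a population (no
#' reads at all) are set missing for that population.
#'
#' @param counts a `read_counts` object (`ref`/`alt` matrices, individuals x
#'   markers).
#' @param populations named character vector of population labels, one per
#'   individual (row).
#' @param marker_info optional marker metadata data.frame (`marker_id`,
#'   `chrom`, `pos`, `annotated`); defaults to bare ids with missing
#'   locations.
#' @param tol,max_iter passed to [em_fit_marker()].
#' @return object of class `dosage_matrix`: list with `values` (individuals
#'   x markers, NA allowed), `marker_info`, `populations`, and `em_fits`
#'   (per population, list of `marker_em_fit`).
#' @export
call_dosage_matrix <- function(counts, populations, marker_info = NULL,
                               tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(counts, "read_counts"))
  n <- nrow(counts$ref); q <- ncol(counts$ref)
  ids <- rownames(counts$ref)
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(n))
  if (!all(names(populations) %in% ids) && !is.null(names(populations)))
    stop("unknown individual in population labels")
  if (is.null(names(populations))) names(populations) <- ids
  populations <- populations[ids]
  if (anyNA(populations)) stop("unknown population label for some individuals")
  if (any(table(populations) < 2L)) stop("each population needs >= 2 individuals")
  mk <- colnames(counts$ref)
  if (is.null(mk)) mk <- sprintf("m%05d", seq_len(q))
  if (is.null(marker_info))
    marker_info <- data.frame(marker_id = mk, chrom = NA_character_,
                              pos = NA_integer_, annotated = FALSE,
                              stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, n, q, dimnames = list(ids, mk))
  em_fits <- list()
  for (pop in unique(populations)) {
    rows <- which(populations == pop)
    fits <- vector("list", q)
    for (j in seq_len(q)) {
      fit <- em_fit_marker(counts$ref[rows, j], counts$alt[rows, j],
                           tol = tol, max_iter = max_iter)
      fits[[j]] <- fit
      if (fit$fit_ok)
        vals[rows, j] <- expected_dosage(counts$ref[rows, j],
                                         counts$alt[rows, j],
                                         fit$error_rate, fit$allele_freq)
    }
    names(fits) <- mk
    em_fits[[pop]] <- fits
  }
  new_dosage_matrix(vals, marker_info, populations, em_fits = em_fits)
}

#' Construct a dosage matrix object
#'
#' @param values numeric matrix, individuals x markers, entries in `[0, 2]`
#'   or NA.
#' @param marker_info data.frame with one row per marker (`marker_id`,
#'   `chrom`, `pos`, `annotated`).
#' @param populations per-individual population labels.
#' @param em_fits optional per-population EM fits.
#' @return object of class `dosage_matrix`.
#' @export
new_dosage_matrix <- function(values, marker_info, populations,
                              em_fits = NULL) {
  if (nrow(marker_info) != ncol(values))
    stop("marker_info must have one row per marker")
  bad <- which(!is.na(values) & (values < 0 | values > 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("dosage outside [0,2] at individual '%s', marker '%s'",
                 rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
  if (anyDuplicated(marker_info$marker_id))
    stop("duplicate marker ids")
  structure(list(values = values, marker_info = marker_info,
                 populations = populations, em_fits = em_fits),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d individuals x %d markers (%d populations, %.1f%% missing)\n",
              nrow(x$values), ncol(x$values), length(unique(x$populations)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Chi-square test for Hardy-Weinberg equilibrium on a dosage column
#'
#' Expected dosages are rounded to the nearest integer genotype class; the
#' observed `{0, 1, 2}` counts are compared to the HWE expectation at the
#' sample allele frequency with a 1-df chi-square test (no continuity
#' correction).  Monomorphic columns return `p = 1` by convention.
#'
#' @param dosage_column numeric vector in `[0, 2]`, NA allowed.
#' @return p-value in `[0, 1]`.
#' @export
hwe_pvalue <- function(dosage_column) {
  d <- round(dosage_column[!is.na(dosage_column)])
  if (length(d) == 0L) stop("need at least one non-missing value")
  n <- length(d)
  counts <- tabulate(d + 1L, nbins = 3L)
  p <- (counts[2L] + 2 * counts[3L]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * hwe_prior(p)
  stat <- sum((counts - expd)^2 / expd)
  pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Marker quality-control filters on an expected-dosage matrix
#'
#' Applies, in order: (i) proportion of missing values strictly lower than
#' 5\%; (ii) polymorphism: minor allele frequency strictly greater than
#' `1/(2N)` and variance higher than `2 (1/2N) (1 - 1/2N)`, with `N` the
#' number of non-missing genotypes in the filter's scope; (iii) HWE within
#' each population separately (chi-square p strictly higher than `1e-4` in
#' every population); (iv) availability of genomic-location information
#' (chromosome, position and annotation present).  A marker is charged to
#' the first rule it violates.
#'
#' @param dm a `dosage_matrix`.
#' @param scope `"across"` (default; MAF/variance computed on all
#'   individuals) or `"within"` (computed within each population; a marker
#'   must pass in every population).
#' @return list with the filtered `dosage_matrix` and a `filter_report`
#'   (`kept`, `removed_by` counts, per-marker verdict).
#' @export
qc_filter <- function(dm, scope = c("across", "within")) {
  scope <- match.arg(scope)
  stopifnot(inherits(dm, "dosage_matrix"))
  V <- dm$values
  pops <- dm$populations
  verdict <- rep("kept", ncol(V))
  # "maf" / "variance" / "ok" for one dosage column
  poly_check <- function(col) {
    x <- col[!is.na(col)]
    N <- length(x)
    if (N < 2L) return("maf")
    thr <- 1 / (2 * N)
    p <- mean(x) / 2
    if (!(min(p, 1 - p) > thr)) return("maf")
    if (!(var(x) > 2 * thr * (1 - thr))) return("variance")
    "ok"
  }
  for (j in seq_len(ncol(V))) {
    col <- V[, j]
    if (!(mean(is.na(col)) < 0.05)) { verdict[j] <- "missingness"; next }
    poly <- if (scope == "across") poly_check(col) else {
      res <- vapply(unique(pops), function(pp) poly_check(col[pops == pp]),
                    character(1L))
      if (any(res == "maf")) "maf" else if (any(res == "variance"))
        "variance" else "ok"
    }
    if (poly != "ok") { verdict[j] <- poly; next }
    hwe_fail <- any(vapply(unique(pops), function(pp) {
      cc <- col[pops == pp]
      if (all(is.na(cc))) return(TRUE)
      !(hwe_pvalue(cc) > 1e-4)
    }, logical(1L)))
    if (hwe_fail) { verdict[j] <- "hwe"; next }
    mi <- dm$marker_info[j, ]
    if (is.na(mi$chrom) || is.na(mi$pos) || !isTRUE(mi$annotated)) {
      verdict[j] <- "location"; next
    }
  }
  keep <- verdict == "kept"
  report <- list(
    n_input = ncol(V), n_kept = sum(keep),
    removed_by = c(missingness = sum(verdict == "missingness"),
                   maf = sum(verdict == "maf"),
                   variance = sum(verdict == "variance"),
                   hwe = sum(verdict == "hwe"),
                   location = sum(verdict == "location")),
    verdict = setNames(verdict, colnames(V)), scope = scope)
  class(report) <- "filter_report"
  out <- new_dosage_matrix(V[, keep, drop = FALSE],
                           dm$marker_info[keep, , drop = FALSE],
                           pops, em_fits = dm$em_fits)
  list(dosage = out, report = report)
}

# Internal: mean-impute missing dosages column-wise (per scope); used by
# transforms and correlation builders, never persisted.
impute_dosage <- function(values) {
  nas <- which(colSums(is.na(values)) > 0)
  for (j in nas) {
    col <- values[, j]
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    values[, j] <- col
  }
  values
}
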