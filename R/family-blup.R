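# Half-sib family BLUPs from field-trial records.  Two model surfaces: the
# plant-level model carries family, block, year, all two-way interactions,
# the three-way interaction, an optional AR1 x AR1 plot effect and a plant
# residual; the plot-level model drops the three-way term and the spatial
# effect, its residual being the pooled plot error.

check_identifiable <- function(factors) {
  for (nm in c("g", "b", "t")) {
    if (nlevels(droplevels(factors[[nm]])) < 2L)
      stop(sprintf("term '%s' is not identifiable: factor '%s' has a single level",
                   nm, c(g = "family", b = "block", t = "year")[nm]))
  }
}

build_model_factors <- function(records, three_way = TRUE) {
  g <- factor(records$family)
  b <- factor(records$block)
  t_ <- factor(records$year)
  out <- list(g = g, b = b, t = t_,
              gb = interaction(g, b, drop = FALSE),
              gt = interaction(g, t_, drop = FALSE),
              bt = interaction(b, t_, drop = FALSE))
  if (three_way) out$gbt <- interaction(g, b, t_, drop = FALSE)
  out
}

finish_family_fit <- function(fit, level, spatial) {
  blups <- fit$blup$g
  blups <- blups - mean(blups)  # deviations; REML solution is mean-zero up
                                # to numerical noise anyway
  sigma_g2 <- unname(fit$varcomp["g"])
  rel <- if (sigma_g2 <= 0) setNames(rep(0, length(blups)), names(blups))
         else pmin(pmax(1 - fit$pev / sigma_g2, 0), 1)
  structure(list(blups = blups, reliabilities = rel, pev = fit$pev,
                 varcomp = fit$varcomp, rho = fit$rho, mu = fit$mu,
                 loglik = fit$loglik, bic = fit$bic, n = fit$n,
                 k_varpar = fit$k_varpar, level = level,
                 spatial = spatial), class = "family_blups")
}

#' @export
print.family_blups <- function(x, ...) {
  cat(sprintf("family_blups: %d families (%s model%s)\n  sigma_g2 = %.4g, mean reliability = %.3f, BIC = %.2f\n",
              length(x$blups), x$level, if (x$spatial) " + spatial plot" else "",
              x$varcomp["g"], mean(x$reliabilities), x$bic))
  invisible(x)
}

#' Fit the plant-level mixed model and extract family BLUPs
#'
#' REML fit of
#' \eqn{y = \mu + g + b + t + gb + gt + bt + gbt (+ plot) + \epsilon}
#' with all terms random and i.i.d. normal, and optionally a plot effect
#' with separable AR1 row-by-column covariance.  Family BLUPs, their
#' prediction-error variances and reliabilities come from the mixed-model
#' equations at the REML optimum.
#'
#' @param records data.frame with columns `family`, `block`, `year`,
#'   `value`, and `row`/`col` when `spatial = TRUE` (one outcome at a time).
#' @param spatial include the AR1 x AR1 plot term?
#' @param control passed to [reml_mixed()].
#' @return a `family_blups` object.
#' @export
fit_plant_model <- function(records, spatial = FALSE, control = list()) {
  fac <- build_model_factors(records, three_way = TRUE)
  check_identifiable(fac)
  sp <- NULL
  if (spatial) {
    if (is.null(records$row) || is.null(records$col) ||
        anyNA(records$row) || anyNA(records$col))
      stop("spatial model requires complete 'row' and 'col' grid indices")
    sp <- list(row = as.integer(records$row), col = as.integer(records$col))
  }
  fit <- reml_mixed(records$value, random = fac, spatial = sp,
                    pev_term = "g", control = control)
  finish_family_fit(fit, "plant", spatial)
}

#' Fit the plot-level mixed model and extract family BLUPs
#'
#' As [fit_plant_model()] but without the three-way interaction and the
#' spatial plot term: the residual is the pooled error of a plot in a year.
#'
#' @param records plot-level data.frame (`family`, `block`, `year`,
#'   `value`).
#' @param control passed to [reml_mixed()].
#' @return a `family_blups` object.
#' @export
fit_plot_model <- function(records, control = list()) {
  fac <- build_model_factors(records, three_way = FALSE)
  check_identifiable(fac)
  fit <- reml_mixed(records$value, random = fac, pev_term = "g",
                    control = control)
  finish_family_fit(fit, "plot", FALSE)
}

#' Reliability of family BLUPs
#'
#' The inferred squared correlation between a true family effect and its
#' BLUP, \eqn{1 - PEV_i / \hat\sigma_g^2}, clamped to `[0, 1]`; zero by
#' convention when \eqn{\hat\sigma_g^2 = 0}.
#'
#' @param fit a `family_blups` object.
#' @return named per-family reliabilities.
#' @export
reliability <- function(fit) {
  stopifnot(inherits(fit, "family_blups"))
  fit$reliabilities
}

#' Descriptive statistics and reliability for one outcome
#'
#' Range, mean and SD of the raw records plus the mean (and SD across
#' families) of the BLUP reliabilities from the fitted mixed model — the
#' usual summary table for a multi-year family trial.
#'
#' @param records records for a single outcome (see [fit_plant_model()]).
#' @param level `"plant"` or `"plot"` (selects the model).
#' @param spatial passed to [fit_plant_model()].
#' @param control passed to [reml_mixed()].
#' @return list: `range`, `mean`, `sd`, `reliability_mean`,
#'   `reliability_sd`, `fit`.
#' @export
outcome_descriptives <- function(records, level = c("plant", "plot"),
                                 spatial = FALSE, control = list()) {
  level <- match.arg(level)
  fit <- if (level == "plant")
    fit_plant_model(records, spatial = spatial, control = control)
  else fit_plot_model(records, control = control)
  rel <- reliability(fit)
  list(range = range(records$value), mean = mean(records$value),
       sd = sd(records$value), reliability_mean = mean(rel),
       reliability_sd = sd(rel), fit = fit)
}

#' Choose the spatial plot term by BIC
#'
#' Fits the plant model with and without the AR1 x AR1 plot effect and
#' returns `TRUE` when the spatial fit has the strictly lower Bayesian
#' information criterion (`-2 loglik_REML + k log n` with `k` the number of
#' variance parameters); ties keep the simpler model.
#'
#' @param records plant-level records with grid indices.
#' @param control passed to [reml_mixed()].
#' @return logical flag, with both fits in attribute `"fits"`.
#' @export
select_spatial_by_bic <- function(records, control = list()) {
  f0 <- fit_plant_model(records, spatial = FALSE, control = control)
  f1 <- fit_plant_model(records, spatial = TRUE, control = control)
  structure(f1$bic < f0$bic, fits = list(nonspatial = f0, spatial = f1))
}
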