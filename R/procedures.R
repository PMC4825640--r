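# Prediction procedures = marker-data transformation x prediction model.
# Transformations are outcome-free and computed once per genotype scope; the
# outcome-informed pieces (feature weighting/selection, tuning, model fits)
# only ever see training observations.

#' Build a cached feature set for a genotype scope
#'
#' Computes the Base transformation eagerly and the PCA/Cor/LD
#' transformations (and their prerequisites: PD-adjusted correlation
#' blocks, tagging weights) lazily, caching each.  All transformations are
#' functions of the marker data only, so a feature set can be shared across
#' cross-validation folds without leaking outcome information.
#'
#' @param dm a `dosage_matrix`, or a numeric matrix with `chrom` supplied.
#' @param chrom chromosome labels (ignored for a `dosage_matrix`).
#' @param individuals optional subset of individuals defining the scope.
#' @param scope label stored on the features.
#' @return object of class `feature_set` with `$features(tag)` returning
#'   the requested `feature_matrix` and fields `genotype_ids`,
#'   `corr_blocks()`, `tag_weights()`.
#' @export
build_feature_set <- function(dm, chrom = NULL, individuals = NULL,
                              scope = NULL) {
  if (inherits(dm, "dosage_matrix")) {
    chrom <- dm$marker_info$chrom
    values <- dm$values
  } else values <- dm
  if (!is.null(individuals)) values <- values[individuals, , drop = FALSE]
  # markers monomorphic within this scope carry no information here and
  # would break correlation blocks; drop them for this scope only
  keep <- which(apply(values, 2L, function(v) var(v, na.rm = TRUE)) > 0 &
                  colSums(!is.na(values)) >= 2L)
  values <- values[, keep, drop = FALSE]
  chrom <- chrom[keep]
  x_base <- base_transform(values, scope = scope)
  cache <- new.env(parent = emptyenv())
  get_blocks <- function() {
    if (is.null(cache$cb))
      cache$cb <- nearest_pd(block_correlation(values, chrom = chrom))
    cache$cb
  }
  get_weights <- function() {
    if (is.null(cache$w)) cache$w <- ld_weights(get_blocks())
    cache$w
  }
  features <- function(tag) {
    switch(tag,
           Base = x_base,
           PCA = {
             if (is.null(cache$pca)) cache$pca <- pca_transform(x_base)
             cache$pca
           },
           Cor = {
             if (is.null(cache$cor))
               cache$cor <- cor_transform(x_base, get_blocks())
             cache$cor
           },
           LD = {
             if (is.null(cache$ld))
               cache$ld <- ld_transform(x_base, get_weights())
             cache$ld
           },
           stop(sprintf("unknown transformation '%s'", tag)))
  }
  structure(list(features = features, genotype_ids = rownames(values),
                 corr_blocks = get_blocks, tag_weights = get_weights,
                 scope = scope),
            class = "feature_set")
}

gs_transforms <- function() c("Base", "PCA", "Cor", "LD")
gs_models <- function() c("GBLUP", "GBLUP-wG", "GBLUP-sG", "RKHS",
                          "RKHS-wG", "RKHS-sG", "BayesA", "BayesB", "RF")

# intercept-only fallback used when -sG selects nothing
intercept_procedure <- function(g_train, n_train) {
  mu <- mean(g_train)
  list(predict = function(test_ids) setNames(rep(mu, length(test_ids)),
                                             test_ids),
       gcv = gcv(g_train, rep(mu, length(g_train)), 1),
       empty_selection = TRUE)
}

# kernel-model fit (GBLUP or RKHS) on a given feature matrix; returns the
# fitted gblup_fit plus a full-scope kernel for prediction
fit_kernel_model <- function(X_all, g_train, train_geno, Z, rkhs,
                             theta = NULL) {
  ids <- rownames(X_all)
  if (rkhs) {
    D <- scaled_distance(X_all)
    K_full <- gaussian_kernel(D, theta)
    rownames(K_full) <- colnames(K_full) <- ids
  } else {
    K_full <- grm_named(unclass(X_all))
  }
  geno_train <- unique(train_geno)
  K_tr <- K_full[geno_train, geno_train, drop = FALSE]
  fit <- fit_gblup(g_train, Z = Z, K = K_tr)
  list(fit = fit, K_full = K_full)
}

#' Fit one prediction procedure
#'
#' Composes a marker-data transformation with a prediction model:
#' transformation from the (outcome-free) feature set; optional
#' significance weighting (`-wG`) or FDR selection (`-sG`, threshold tuned
#' by GCV) computed on the training observations only; then the model fit.
#' The returned object predicts any genotypes present in the feature set.
#'
#' @param transform one of `"Base"`, `"PCA"`, `"Cor"`, `"LD"`.
#' @param model one of `"GBLUP"`, `"GBLUP-wG"`, `"GBLUP-sG"`, `"RKHS"`,
#'   `"RKHS-wG"`, `"RKHS-sG"`, `"BayesA"`, `"BayesB"`, `"RF"`.
#' @param fs a `feature_set` covering training and test genotypes.
#' @param g_train numeric training observations.
#' @param train_geno genotype id of each training observation (duplicates
#'   allowed, e.g. across-environment learning).
#' @param seed seed for the stochastic models (Bayes chains, forests).
#' @param bayes_chain list overriding `burn_in`, `n_iter`, `thin`.
#' @return object of class `gs_procedure` with `$predict(test_ids)`,
#'   `$gcv`, and tuning metadata.
#' @export
fit_procedure <- function(transform, model, fs, g_train, train_geno,
                          seed = 1L, bayes_chain = list()) {
  stopifnot(transform %in% gs_transforms(), model %in% gs_models(),
            inherits(fs, "feature_set"),
            length(g_train) == length(train_geno))
  X_all <- fs$features(transform)
  geno_train <- unique(train_geno)
  Z <- outer(train_geno, geno_train, "==") * 1
  kernel_model <- grepl("^(GBLUP|RKHS)", model)
  rkhs <- grepl("^RKHS", model)
  weighted <- grepl("-wG$", model)
  selected <- grepl("-sG$", model)
  tuned <- list()

  if (kernel_model) {
    Xw <- X_all
    if (weighted || selected) {
      X_obs <- unclass(X_all)[train_geno, , drop = FALSE]
      pv <- marginal_feature_pvalues(X_obs, g_train)
    }
    if (weighted) Xw <- weight_features(X_all, pv)
    make_fit <- function(X, theta = NULL)
      fit_kernel_model(X, g_train, train_geno, Z, rkhs, theta)

    if (selected) {
      qv <- qvalues(pv)
      builder <- function(par) {
        thr <- if (rkhs) par[[1L]] else par
        Xs <- select_features_sG(X_all, qv, thr)
        if (attr(Xs, "empty_selection"))
          return(intercept_procedure(g_train, length(g_train)))
        km <- make_fit(Xs, theta = if (rkhs) par[[2L]] else NULL)
        list(km = km, gcv = km$fit$gcv)
      }
      grid <- if (rkhs)
        expand.grid(thr = fdr_threshold_grid(), theta = rkhs_scale_grid())
      else data.frame(thr = fdr_threshold_grid())
      vals <- vapply(seq_len(nrow(grid)), function(i)
        tryCatch(builder(as.list(grid[i, ]))$gcv, error = function(e) NA_real_),
        numeric(1L))
      if (all(is.na(vals))) stop("all fits failed during -sG tuning")
      best_i <- which(vals == min(vals, na.rm = TRUE))
      best_i <- best_i[order(grid$thr[best_i],
                             if (rkhs) grid$theta[best_i] else best_i)][1L]
      tuned <- as.list(grid[best_i, , drop = FALSE])
      sel <- builder(as.list(grid[best_i, ]))
      if (!is.null(sel$empty_selection))
        return(structure(c(sel, list(transform = transform, model = model,
                                     tuned = tuned)),
                         class = "gs_procedure"))
      km <- sel$km
    } else if (rkhs) {
      tr <- tune_by_gcv(function(th) make_fit(Xw, theta = th)$fit,
                        rkhs_scale_grid())
      tuned <- list(theta = tr$selected)
      km <- make_fit(Xw, theta = tr$selected)
    } else {
      km <- make_fit(Xw)
    }
    fit <- km$fit
    K_full <- km$K_full
    pred <- function(test_ids) predict_gblup(fit, K_full, test_ids)
    out <- list(predict = pred, gcv = fit$gcv, fit = fit,
                transform = transform, model = model, tuned = tuned,
                seed = seed)
  } else if (model %in% c("BayesA", "BayesB")) {
    X_obs <- unclass(X_all)[train_geno, , drop = FALSE]
    r2 <- hem_prior_r2(g_train, fs$features("Base")[train_geno, ,
                                                    drop = FALSE])
    args <- utils::modifyList(list(burn_in = 5000L, n_iter = 15000L,
                                   thin = 1L), bayes_chain)
    bf <- fit_bayes(g_train, X_obs, variant = sub("Bayes", "", model),
                    prior_R2 = r2, burn_in = args$burn_in,
                    n_iter = args$n_iter, thin = args$thin, seed = seed)
    pred <- function(test_ids)
      predict(bf, unclass(X_all)[test_ids, , drop = FALSE])
    out <- list(predict = pred, gcv = NA_real_, fit = bf,
                transform = transform, model = model,
                tuned = list(prior_R2 = r2), seed = seed)
  } else {  # RF
    X_obs <- unclass(X_all)[train_geno, , drop = FALSE]
    rf <- fit_rf(g_train, X_obs, seed = seed)
    pred <- function(test_ids) {
      p <- predict(rf, unclass(X_all)[test_ids, , drop = FALSE])
      setNames(as.numeric(p), test_ids)
    }
    out <- list(predict = pred, gcv = NA_real_, fit = rf,
                transform = transform, model = model, tuned = list(),
                seed = seed)
  }
  structure(out, class = "gs_procedure")
}

#' @export
print.gs_procedure <- function(x, ...) {
  cat(sprintf("gs_procedure: %s - %s%s\n", x$transform, x$model,
              if (length(x$tuned))
                paste0(" (tuned: ",
                       paste(names(x$tuned), unlist(x$tuned), sep = "=",
                             collapse = ", "), ")") else ""))
  invisible(x)
}
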