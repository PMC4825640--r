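# Reproducible benchmark harnesses exercising the pipeline end to end on
# synthetic data: kernel-equivalence checks, oracle gaps, parameter
# recovery, statistical calibration, and the directional comparison of the
# Cor and Base transformations.  Each harness seeds every stochastic stage
# from its `seed` argument.

#' Transformation-equivalence deviations on a random fixture
#'
#' Generates independent dosages (blocks smaller than the sample so every
#' correlation block is full rank), builds the four transformations, and
#' returns the maximum absolute deviation of each GBLUP kernel identity:
#' `grm(PCA) = grm(Base)`, `grm(Cor) = X Theta X' / c`,
#' `grm(LD) = X W X' / c`.
#'
#' @param seed RNG seed.
#' @param n,q genotypes and markers.
#' @param n_chrom chromosome count (`q` divisible by it).
#' @return list of deviations `pca`, `cor`, `ld`.
#' @export
benchmark_transform_equivalence <- function(seed, n = 50, q = 200,
                                            n_chrom = 8) {
  with_seed(seed, {
    p <- runif(q, 0.1, 0.5)
    G <- sapply(p, function(pp) rbinom(n, 2, pp))
    dimnames(G) <- list(sprintf("g%03d", 1:n), sprintf("m%03d", 1:q))
    chrom <- rep(sprintf("c%d", 1:n_chrom), each = q / n_chrom)
    Xb <- base_transform(G)
    cb <- nearest_pd(block_correlation(G, chrom = chrom))
    w <- ld_weights(cb)
    Xc <- cor_transform(Xb, cb)
    Xl <- ld_transform(Xb, w)
    Theta <- as.matrix(Matrix::bdiag(lapply(cb$blocks,
                                            function(b) solve(b$R))))
    Xbm <- unclass(Xb)
    list(
      pca = max(abs(grm(pca_transform(Xb)) - grm(Xb))),
      cor = max(abs(grm(Xc) - Xbm %*% Theta %*% t(Xbm) /
                      sum(apply(unclass(Xc), 2, var)))),
      ld = max(abs(grm(Xl) - Xbm %*% diag(w) %*% t(Xbm) /
                     sum(apply(unclass(Xl), 2, var)))))
  })
}

#' EM dosage-caller accuracy against a grid-search oracle
#'
#' Simulates markers with known allele frequency and error rate, fits the
#' per-marker EM, and compares its log-likelihood with a dense grid-search
#' maximum over `(p, eps)`.
#'
#' @param seed RNG seed.
#' @param n_seeds number of simulated markers.
#' @param n individuals per marker.
#' @param p_true,eps_true,depth_mean generating values.
#' @return list: `n_recovered` (both parameters within the documented
#'   tolerances), `max_loglik_gap` (grid max minus EM; negative means EM
#'   beat the grid), `median_p_err`, `median_eps_err`.
#' @export
benchmark_em_oracle <- function(seed, n_seeds = 20, n = 200, p_true = 0.3,
                                eps_true = 0.01, depth_mean = 8) {
  grid <- expand.grid(p = seq(0.05, 0.95, by = 0.01),
                      e = seq(1e-4, 0.1, by = 0.005))
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  res <- sapply(seq_len(n_seeds), function(i) {
    with_seed(derive_seed(seed, paste0("em", i)), {
      d <- rbinom(n, 2, p_true)
      dep <- rpois(n, depth_mean)
      alt <- rbinom(n, dep, (d / 2) * (1 - eps_true) +
                      (1 - d / 2) * eps_true)
      ref <- dep - alt
      fit <- em_fit_marker(ref, alt)
      ll <- mapply(function(p, e) {
        lg <- sapply(c(e, 0.5, 1 - e),
                     function(pd) xlogy(alt, pd) + xlogy(ref, 1 - pd))
        sum(log(pmax(exp(lg) %*% c((1 - p)^2, 2 * p * (1 - p), p^2),
                     1e-300)))
      }, grid$p, grid$e)
      c(p_err = abs(fit$allele_freq - p_true),
        eps_err = abs(fit$error_rate - eps_true),
        gap = max(ll) - fit$loglik)
    })
  })
  list(n_recovered = sum(res["p_err", ] < 0.05 & res["eps_err", ] < 0.02),
       max_loglik_gap = max(res["gap", ]),
       median_p_err = median(res["p_err", ]),
       median_eps_err = median(res["eps_err", ]))
}

#' Variance-component recovery for the plant mixed model
#'
#' Simulates trials with known components (family variance 1, every other
#' term 0.25), fits the plant model by REML, and reports how many seeds
#' recover every component within 30%, plus the median relative error over
#' the well-replicated components (family, family interactions, residual).
#'
#' @param seed RNG seed.
#' @param n_seeds datasets.
#' @param m,nb,ny,np families, blocks, years, plants per family-block.
#' @return list: `n_all_within_30`, `median_rel_err_replicated`.
#' @export
benchmark_varcomp_recovery <- function(seed, n_seeds = 20, m = 100,
                                       nb = 4, ny = 2, np = 3) {
  truth <- c(g = 1, b = 0.25, t = 0.25, gb = 0.25, gt = 0.25, bt = 0.25,
             gbt = 0.25, residual = 0.25)
  res <- sapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(seed = derive_seed(seed, paste0("vc", i)),
                      n_parents_per_pop = c(m, 2), n_chromosomes = 1,
                      markers_per_chromosome = 20, sigma_g2 = 1,
                      sigma_b2 = 0.25, sigma_t2 = 0.25, sigma_gb2 = 0.25,
                      sigma_gt2 = 0.25, sigma_bt2 = 0.25,
                      sigma_gbt2 = 0.25, sigma_e2 = 0.25, n_blocks = nb,
                      n_years = ny, plants_per_family_per_block = np,
                      n_causal = 5)
    par <- simulate_parents(cfg)
    ph <- simulate_phenotypes(par$truth, cfg, level = "plant")
    fit <- fit_plant_model(ph, control = list(restarts = 0))
    rel <- abs(fit$varcomp[names(truth)] - truth) / truth
    c(all30 = all(rel < 0.3),
      med_rep = median(rel[c("g", "gb", "gt", "gbt", "residual")]))
  })
  list(n_all_within_30 = sum(res["all30", ]),
       median_rel_err_replicated = median(res["med_rep", ]))
}

#' Bivariate genomic-correlation recovery
#'
#' Simulates pairs of outcomes with genomic correlation `rg_true` over a
#' marker-derived kernel and counts estimates inside `[0.6, 0.95]`.
#'
#' @param seed RNG seed.
#' @param n_seeds datasets.
#' @param m genotypes; `q` markers.
#' @param rg_true generating genomic correlation.
#' @return list: `n_recovered`, `median_rg`.
#' @export
benchmark_rg_recovery <- function(seed, n_seeds = 20, m = 100, q = 150,
                                  rg_true = 0.8) {
  rgs <- sapply(seq_len(n_seeds), function(i) {
    with_seed(derive_seed(seed, paste0("rg", i)), {
      G <- matrix(rbinom(m * q, 2, 0.3), m, q,
                  dimnames = list(sprintf("i%03d", 1:m), NULL))
      K <- grm_named(unclass(base_transform(G)))
      L <- t(chol(K + 1e-6 * diag(m)))
      z1 <- rnorm(m); z2 <- rg_true * z1 + sqrt(1 - rg_true^2) * rnorm(m)
      g1 <- setNames(drop(L %*% z1) + rnorm(m, 0, 0.5), rownames(G))
      g2 <- setNames(drop(L %*% z2) + rnorm(m, 0, 0.5), rownames(G))
      bivariate_gblup(g1, g2, K)$rg
    })
  })
  list(n_recovered = sum(rgs > 0.6 & rgs < 0.95), median_rg = median(rgs))
}

#' Planted-class heritability-partition identification
#'
#' Places all causal variants in one tagging class and counts how often the
#' multi-kernel partition assigns that class the largest contribution.
#'
#' @param seed RNG seed.
#' @param n_seeds datasets.
#' @param m,q genotypes and markers.
#' @param target planted class (`"high"` by default).
#' @return list: `n_identified`.
#' @export
benchmark_partition_planted <- function(seed, n_seeds = 20, m = 90, q = 90,
                                        target = "high") {
  hits <- sapply(seq_len(n_seeds), function(i) {
    with_seed(derive_seed(seed, paste0("pt", i)), {
      G <- matrix(rbinom(m * q, 2, 0.3), m, q,
                  dimnames = list(sprintf("i%03d", 1:m),
                                  sprintf("m%03d", 1:q)))
      Xb <- base_transform(G)
      tg <- setNames(rep(c(1, 2, 4), each = q / 3), colnames(G))
      cls <- split(colnames(G), rep(c("low", "intermediate", "high"),
                                    each = q / 3))
      u <- drop(scale(unclass(Xb)[, cls[[target]]] %*%
                        rnorm(length(cls[[target]]))))
      g <- setNames(u * sqrt(0.6) + rnorm(m, 0, sqrt(0.4)), rownames(G))
      names(which.max(partition_heritability(g, Xb, tg)$contributions)) ==
        target
    })
  })
  list(n_identified = sum(hits))
}

#' Type-I error of the corrected Dunnett comparison
#'
#' Null harness: the same procedure evaluated in two independent replicated
#' cross-validation runs (different partition seeds) on each simulated
#' dataset, so the true difference in accuracy is exactly zero; reports the
#' rejection rate of the corrected paired Dunnett test at `alpha`.
#'
#' @param seed RNG seed.
#' @param n_datasets simulated datasets.
#' @param alpha nominal level.
#' @param m,q genotypes and markers per dataset.
#' @param K,R folds and replicates per run.
#' @return list: `rejection_rate`, `n_datasets`.
#' @export
benchmark_dunnett_type1 <- function(seed, n_datasets = 500, alpha = 0.05,
                                    m = 40, q = 60, K = 5, R = 2) {
  rej <- sapply(seq_len(n_datasets), function(i) {
    s <- derive_seed(seed, paste0("t1_", i))
    with_seed(s, {
      G <- matrix(rbinom(m * q, 2, 0.35), m, q,
                  dimnames = list(sprintf("i%03d", 1:m),
                                  sprintf("m%03d", 1:q)))
      X <- scale(G, scale = FALSE)
      u <- drop(X[, 1:10] %*% rnorm(10))
      g <- drop(scale(u)) * sqrt(0.4) + rnorm(m, 0, sqrt(0.6))
      K_g <- grm_named(X)
      acc_run <- function(run_seed) {
        out <- numeric(0)
        for (r in seq_len(R)) {
          folds <- make_folds(m, K, derive_seed(run_seed, r))
          for (k in seq_len(K)) {
            te <- rownames(G)[folds[[k]]]
            tr <- setdiff(rownames(G), te)
            f <- fit_gblup(g[match(tr, rownames(G))], K = K_g[tr, tr])
            pr <- predict_gblup(f, K_g, te)
            ote <- g[match(te, rownames(G))]
            out <- c(out, if (sd(pr) == 0 || sd(ote) == 0) 0
                     else cor(ote, pr))
          }
        }
        out
      }
      a1 <- acc_run(derive_seed(s, "runA"))
      a2 <- acc_run(derive_seed(s, "runB"))
      dr <- corrected_dunnett(a1, list(b = a2), K = K, R = R)
      dr$p_adjusted < alpha
    })
  })
  list(rejection_rate = mean(rej), n_datasets = n_datasets)
}

#' GWAS null calibration
#'
#' Simulates polygenic-plus-noise outcomes with no single-marker fixed
#' effects and reports how many seeds give a uniform EMMAX p-value
#' distribution (Kolmogorov-Smirnov p above 0.01).
#'
#' @param seed RNG seed.
#' @param n_seeds datasets.
#' @param m,q genotypes and markers.
#' @return list: `n_uniform`, `median_ks_p`.
#' @export
benchmark_gwas_null <- function(seed, n_seeds = 20, m = 80, q = 120) {
  ks <- sapply(seq_len(n_seeds), function(i) {
    with_seed(derive_seed(seed, paste0("gw", i)), {
      G <- matrix(rbinom(m * q, 2, 0.3), m, q,
                  dimnames = list(sprintf("i%03d", 1:m),
                                  sprintf("m%03d", 1:q)))
      K <- grm_named(unclass(base_transform(G)))
      L <- t(chol(K + 1e-6 * diag(m)))
      g <- setNames(drop(L %*% rnorm(m)) * 0.3 + rnorm(m), rownames(G))
      ks.test(gwas_emmax(g, G, K)$p, stats::punif)$p.value
    })
  })
  list(n_uniform = sum(ks > 0.01), median_ks_p = median(ks))
}

#' Directional comparison of Cor-GBLUP and Base-GBLUP
#'
#' Simulates datasets whose causal variants sit in the lowest
#' degree-of-tagging tertile, under the WS4U-like genome defaults
#' (haplotype blocks plus rare two-haplotype bottleneck clusters), runs
#' replicated cross-validation for both procedures with shared folds, and
#' reports how often Cor-GBLUP achieves the higher mean accuracy.
#'
#' @param seed RNG seed.
#' @param n_datasets datasets.
#' @param K,R folds and replicates.
#' @param h2 outcome heritability (a low-heritability, yield-like trait).
#' @param include_ld also score the weights-based LD transformation on the
#'   same folds (reported alongside; the Cor/Base comparison is unchanged).
#' @return list: `win_fraction`, `mean_base`, `mean_cor`, and with
#'   `include_ld` also `ld_win_fraction`, `mean_ld`; plus `n_datasets`.
#' @export
benchmark_headline_cor_vs_base <- function(seed, n_datasets = 20, K = 5,
                                           R = 10, h2 = 0.3,
                                           include_ld = FALSE) {
  res <- sapply(seq_len(n_datasets), function(i) {
    s <- derive_seed(seed, paste0("hl", i))
    cfg <- sim_config(seed = s, n_parents_per_pop = c(110, 30),
                      n_chromosomes = 3, markers_per_chromosome = 100,
                      ld_decay_rate = c(0.7, 0.7),
                      ld_block_mean_length = 10,
                      bottleneck_block_prob = c(0.5, 0),
                      maf_distribution = c("uniform", "uniform"),
                      n_causal = 25, causal_tagging_stratum = "low")
    par <- simulate_parents(cfg)
    dm <- new_dosage_matrix(par$dosages + 0.0, par$marker_info,
                            par$populations)
    g <- simulate_family_outcome(par$truth, h2,
                                 seed = derive_seed(s, "outcome"),
                                 populations = par$populations)
    oc <- data.frame(genotype = names(g), population = par$populations,
                     trait = "DMY", location = "NE",
                     value = as.numeric(g), stringsAsFactors = FALSE)
    ds <- build_gs_dataset(dm, oc)
    sch <- learning_scheme("within", "within", "pop1", "DMY", "NE")
    procs <- c("Base-GBLUP", "Cor-GBLUP", if (include_ld) "LD-GBLUP")
    cv <- cross_validate(procs, ds, sch, K = K, R = R, master_seed = s)
    a <- tapply(cv$accuracy, cv$procedure, mean)
    c(base = a[["Base-GBLUP"]], cor = a[["Cor-GBLUP"]],
      ld = if (include_ld) a[["LD-GBLUP"]] else NA_real_)
  })
  out <- list(win_fraction = mean(res["cor", ] > res["base", ]),
              mean_base = mean(res["base", ]),
              mean_cor = mean(res["cor", ]), n_datasets = n_datasets)
  if (include_ld) {
    out$ld_win_fraction <- mean(res["ld", ] > res["base", ])
    out$mean_ld <- mean(res["ld", ])
  }
  out
}
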