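# Learning schemes, replicated k-fold cross-validation and the
# correlation-adjusted paired Dunnett comparisons used to validate
# prediction procedures against the standard Base - GBLUP.

#' Random k-fold partition
#'
#' @param m number of instances (`>= K`).
#' @param K number of folds.
#' @param seed RNG seed.
#' @return list of `K` disjoint index vectors covering `1:m`, sizes
#'   differing by at most one.
#' @export
make_folds <- function(m, K, seed) {
  if (m < K) stop("m < K")
  with_seed(seed, {
    idx <- sample.int(m)
    unname(split(idx, rep(seq_len(K), length.out = m)))
  })
}

#' Define a learning scheme
#'
#' @param population_scope `"within"` (target population only) or
#'   `"across"` (both populations pooled for training).
#' @param environment_scope `"within"` (target trait-location only) or
#'   `"across"` (same trait in both locations; training rows double,
#'   `n = 2m`).
#' @param target_population population label of the genotypes being
#'   predicted.
#' @param trait,location the target outcome.
#' @return object of class `learning_scheme`.
#' @export
learning_scheme <- function(population_scope = c("within", "across"),
                            environment_scope = c("within", "across"),
                            target_population, trait, location) {
  structure(list(population_scope = match.arg(population_scope),
                 environment_scope = match.arg(environment_scope),
                 target_population = target_population,
                 trait = trait, location = location),
            class = "learning_scheme")
}

#' Bundle marker data and family-BLUP outcomes for prediction experiments
#'
#' @param dm a `dosage_matrix` (all genotyped parents, both populations).
#' @param outcomes data.frame with columns `genotype`, `population`,
#'   `trait`, `location`, `value` (HS-family BLUPs, one row per genotype
#'   and outcome).
#' @return object of class `gs_dataset`; feature sets per population scope
#'   are built lazily and cached.
#' @export
build_gs_dataset <- function(dm, outcomes) {
  stopifnot(inherits(dm, "dosage_matrix"),
            all(c("genotype", "population", "trait", "location", "value")
                %in% names(outcomes)))
  if (!all(outcomes$genotype %in% rownames(dm$values)))
    stop("outcome genotypes missing from the dosage matrix")
  cache <- new.env(parent = emptyenv())
  pops <- dm$populations
  feature_set_for <- function(scope) {
    key <- paste(sort(scope), collapse = "+")
    if (is.null(cache[[key]])) {
      ind <- names(pops)[pops %in% scope]
      cache[[key]] <- build_feature_set(dm, individuals = ind, scope = key)
    }
    cache[[key]]
  }
  structure(list(outcomes = outcomes, populations = pops,
                 feature_set_for = feature_set_for),
            class = "gs_dataset")
}

outcome_values <- function(data, population, trait, location) {
  o <- data$outcomes
  sel <- o$population == population & o$trait == trait &
    o$location == location
  setNames(o$value[sel], o$genotype[sel])
}

#' Assemble training and test sets for a learning scheme
#'
#' Within-population/within-environment training is the target outcome
#' minus the test fold.  Across-population learning appends the other
#' population's rows (training only).  Across-environment learning appends
#' the paired location's rows for the training genotypes only, so held-out
#' families are excluded from both environments; accuracy is always
#' evaluated on the target outcome's test-fold values.
#'
#' @param scheme a `learning_scheme`.
#' @param data a `gs_dataset`.
#' @param test_ids genotype ids held out for testing.
#' @return list: `g_train`, `train_geno` (genotype per training
#'   observation), `test_ids`, `g_test`, `scope` (population labels whose
#'   genotypes the kernel must cover).
#' @export
assemble_training <- function(scheme, data, test_ids) {
  target <- outcome_values(data, scheme$target_population, scheme$trait,
                           scheme$location)
  if (!all(test_ids %in% names(target)))
    stop("test ids missing from the target outcome")
  train_ids <- setdiff(names(target), test_ids)
  g_train <- unname(target[train_ids])
  train_geno <- train_ids
  scope <- scheme$target_population
  if (scheme$population_scope == "across") {
    other_pop <- setdiff(unique(data$outcomes$population),
                         scheme$target_population)
    for (op in other_pop) {
      oth <- outcome_values(data, op, scheme$trait, scheme$location)
      if (any(names(oth) %in% names(target)))
        stop("genotype id collision across populations")
      g_train <- c(g_train, unname(oth))
      train_geno <- c(train_geno, names(oth))
    }
    scope <- unique(data$outcomes$population)
  }
  if (scheme$environment_scope == "across") {
    other_loc <- setdiff(unique(data$outcomes$location), scheme$location)
    if (length(other_loc) != 1L)
      stop("across-environment learning needs exactly one paired location")
    for (pp in unique(c(scheme$target_population,
                        if (scheme$population_scope == "across")
                          setdiff(unique(data$outcomes$population),
                                  scheme$target_population)))) {
      oth <- outcome_values(data, pp, scheme$trait, other_loc)
      keep <- intersect(names(oth), unique(train_geno))
      g_train <- c(g_train, unname(oth[keep]))
      train_geno <- c(train_geno, keep)
    }
  }
  list(g_train = g_train, train_geno = train_geno, test_ids = test_ids,
       g_test = unname(target[test_ids]), scope = scope)
}

#' Replicated k-fold cross-validation of prediction procedures
#'
#' For each replicate, a fresh seeded partition of the target population's
#' genotypes is shared by every procedure (paired design); each procedure
#' is fitted on the training folds and scored by the Pearson correlation
#' between observed and predicted values on the test fold.  Degenerate
#' folds (constant predictions or observations) score 0 and are flagged.
#'
#' @param procedures character vector like `"Cor-GBLUP"`, or list of
#'   `c(transform, model)` pairs.
#' @param data a `gs_dataset`.
#' @param scheme a `learning_scheme`.
#' @param K,R folds and replicates.
#' @param master_seed seed from which per-replicate partitions and
#'   per-fit seeds are derived.
#' @param bayes_chain chain settings forwarded to Bayesian procedures.
#' @return object of class `cv_accuracy`: data.frame (`procedure`,
#'   `replicate`, `fold`, `accuracy`, `degenerate`) with `K`, `R` in
#'   attributes.
#' @export
cross_validate <- function(procedures, data, scheme, K = 5L, R = 10L,
                           master_seed = 1L, bayes_chain = list()) {
  if (is.character(procedures))
    procedures <- strsplit(procedures, "-", fixed = TRUE)
  procedures <- lapply(procedures, function(p)
    c(p[1L], paste(p[-1L], collapse = "-")))
  labels <- vapply(procedures, paste, character(1L), collapse = "-")
  target <- outcome_values(data, scheme$target_population, scheme$trait,
                           scheme$location)
  ids <- names(target)
  rows <- list()
  for (r in seq_len(R)) {
    folds <- make_folds(length(ids), K, derive_seed(master_seed,
                                                    paste0("fold_", r)))
    for (k in seq_len(K)) {
      test_ids <- ids[folds[[k]]]
      tr <- assemble_training(scheme, data, test_ids)
      fs <- data$feature_set_for(tr$scope)
      for (pi in seq_along(procedures)) {
        pr <- procedures[[pi]]
        seed_fit <- derive_seed(master_seed, paste(r, k, labels[pi]))
        proc <- fit_procedure(pr[1L], pr[2L], fs, tr$g_train,
                              tr$train_geno, seed = seed_fit,
                              bayes_chain = bayes_chain)
        pred <- proc$predict(test_ids)
        degen <- sd(pred) == 0 || sd(tr$g_test) == 0
        acc <- if (degen) 0 else cor(tr$g_test, pred[test_ids])
        rows[[length(rows) + 1L]] <-
          data.frame(procedure = labels[pi], replicate = r, fold = k,
                     accuracy = acc, degenerate = degen,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, K = K, R = R, master_seed = master_seed,
            class = c("cv_accuracy", "data.frame"))
}

fisher_z <- function(r) atanh(pmin(pmax(r, -0.9999), 0.9999))

#' Correlation-adjusted paired Dunnett comparison of procedures
#'
#' For each candidate, computes per-fold accuracy differences on the Fisher
#' z scale, the corrected paired t-statistic
#' \eqn{T = \bar\Delta / (SD(\Delta) \sqrt{1/(KR) + 1/(K-1)})}
#' (the variance correction accounts for training-set overlap in
#' cross-validation), and a two-sided p-value adjusted for `c` many-to-one
#' comparisons under the equicorrelated (correlation 1/2) multivariate t
#' with `KR - 1` degrees of freedom, evaluated by seeded Monte Carlo
#' (`c = 1` reduces to the exact corrected paired t-test).
#'
#' @param control accuracy vector of the control procedure (length `K*R`,
#'   fold-paired), or a `cv_accuracy` table containing it.
#' @param candidates named list of accuracy vectors (same pairing), or
#'   candidate procedure names when `control` is a `cv_accuracy` table.
#' @param K,R folds and replicates (taken from the table when given).
#' @param control_name control procedure name when `control` is a table.
#' @param n_mc Monte Carlo draws for the Dunnett adjustment.
#' @param mc_seed Monte Carlo seed.
#' @return object of class `dunnett_result`: data.frame with `candidate`,
#'   `delta_mean`, `delta_sd`, `T`, `p_adjusted`, `degenerate`.
#' @export
corrected_dunnett <- function(control, candidates, K = NULL, R = NULL,
                              control_name = "Base-GBLUP", n_mc = 1e5,
                              mc_seed = 20160210L) {
  if (inherits(control, "cv_accuracy")) {
    tab <- control
    K <- attr(tab, "K"); R <- attr(tab, "R")
    get_acc <- function(nm) {
      s <- tab[tab$procedure == nm, ]
      s <- s[order(s$replicate, s$fold), ]
      if (nrow(s) != K * R) stop(sprintf("procedure '%s' has %d entries, expected K*R = %d",
                                         nm, nrow(s), K * R))
      s$accuracy
    }
    ctrl <- get_acc(control_name)
    cand_names <- if (is.character(candidates)) candidates else names(candidates)
    candidates <- lapply(cand_names, get_acc)
    names(candidates) <- cand_names
  } else {
    ctrl <- control
    if (is.null(K) || is.null(R)) stop("K and R required with raw vectors")
    if (!is.list(candidates)) candidates <- list(candidate = candidates)
  }
  stopifnot(all(vapply(candidates, length, 1L) == length(ctrl)),
            length(ctrl) == K * R)
  cfac <- sqrt(1 / (K * R) + 1 / (K - 1))
  df <- K * R - 1
  cnum <- length(candidates)
  stats <- lapply(candidates, function(acc) {
    delta <- fisher_z(acc) - fisher_z(ctrl)
    dbar <- mean(delta); dsd <- sd(delta)
    if (dsd == 0) {
      if (dbar == 0) return(list(dbar = dbar, dsd = dsd, T = 0, p = 1,
                                 degenerate = TRUE))
      return(list(dbar = dbar, dsd = dsd, T = sign(dbar) * Inf, p = 0,
                  degenerate = TRUE))
    }
    list(dbar = dbar, dsd = dsd, T = dbar / (dsd * cfac), p = NA_real_,
         degenerate = FALSE)
  })
  Ts <- vapply(stats, `[[`, numeric(1L), "T")
  ps <- vapply(stats, `[[`, numeric(1L), "p")
  todo <- which(is.na(ps))
  if (length(todo) > 0) {
    if (cnum == 1L) {
      ps[todo] <- 2 * pt(-abs(Ts[todo]), df = df)
    } else {
      maxT <- with_seed(mc_seed, {
        x0 <- rnorm(n_mc)
        xj <- matrix(rnorm(n_mc * cnum), n_mc, cnum)
        zz <- (x0 + xj) / sqrt(2)          # equicorrelation 1/2
        s <- sqrt(rchisq(n_mc, df) / df)   # shared denominator
        apply(abs(zz / s), 1L, max)
      })
      ps[todo] <- vapply(Ts[todo], function(tt) mean(maxT >= abs(tt)),
                         numeric(1L))
    }
  }
  out <- data.frame(candidate = names(candidates),
                    delta_mean = vapply(stats, `[[`, 1, "dbar"),
                    delta_sd = vapply(stats, `[[`, 1, "dsd"),
                    T = Ts, p_adjusted = ps,
                    degenerate = vapply(stats, `[[`, TRUE, "degenerate"),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, K = K, R = R, n_candidates = cnum, df = df,
            correction_factor = cfac,
            class = c("dunnett_result", "data.frame"))
}

#' Two-step selection and validation of a prediction procedure
#'
#' Step 1 screens every transformation x model combination by mean accuracy
#' in non-replicated k-fold cross-validation.  Step 2 validates the winner
#' against the standard `Base-GBLUP` in replicated cross-validation with
#' corrected Dunnett tests; when the winner differs in both axes, the
#' comparison is staged — first the alternate transformation under GBLUP
#' (multiplicity = number of alternative transformations), then the
#' alternate model under the alternate transformation (multiplicity =
#' number of alternative models) — so that the selection bias from reusing
#' the data is accounted for.
#'
#' @param data a `gs_dataset`.
#' @param scheme a `learning_scheme`.
#' @param transforms,models candidate axes.
#' @param K,R folds and replicates for step 2 (step 1 uses `R = 1`).
#' @param master_seed seed.
#' @param bayes_chain chain settings for Bayesian procedures.
#' @return list: `step1` (mean-accuracy table), `selected`, `short_circuit`
#'   flag, `step2` (cv_accuracy), `comparisons` (list of `dunnett_result`).
#' @export
two_step_selection <- function(data, scheme, transforms = gs_transforms(),
                               models = gs_models(), K = 5L, R = 10L,
                               master_seed = 1L, bayes_chain = list()) {
  combos <- expand.grid(transform = transforms, model = models,
                        stringsAsFactors = FALSE)
  procs <- paste(combos$transform, combos$model, sep = "-")
  cv1 <- cross_validate(procs, data, scheme, K = K, R = 1L,
                        master_seed = derive_seed(master_seed, "step1"),
                        bayes_chain = bayes_chain)
  mean_acc <- tapply(cv1$accuracy, cv1$procedure, mean)[procs]
  selected <- procs[which.max(mean_acc)]
  step1 <- data.frame(procedure = procs,
                      transform = combos$transform, model = combos$model,
                      mean_accuracy = as.numeric(mean_acc),
                      stringsAsFactors = FALSE)
  control <- "Base-GBLUP"
  if (selected == control)
    return(list(step1 = step1, selected = selected, short_circuit = TRUE,
                step2 = NULL, comparisons = NULL))
  sel_tr <- sub("-.*$", "", selected)
  sel_md <- sub("^[^-]+-", "", selected)
  needed <- unique(c(control, selected,
                     if (sel_tr != "Base" && sel_md != "GBLUP")
                       paste0(sel_tr, "-GBLUP")))
  cv2 <- cross_validate(needed, data, scheme, K = K, R = R,
                        master_seed = derive_seed(master_seed, "step2"),
                        bayes_chain = bayes_chain)
  comparisons <- list()
  if (sel_tr != "Base" && sel_md != "GBLUP") {
    comparisons$transformation <- corrected_dunnett(
      cv2, paste0(sel_tr, "-GBLUP"), control_name = control)
    attr(comparisons$transformation, "multiplicity") <-
      length(transforms) - 1L
    comparisons$transformation$p_adjusted <- dunnett_readjust(
      comparisons$transformation, length(transforms) - 1L)
    comparisons$model <- corrected_dunnett(
      cv2, selected, control_name = paste0(sel_tr, "-GBLUP"))
    comparisons$model$p_adjusted <- dunnett_readjust(
      comparisons$model, length(models) - 1L)
  } else {
    mult <- if (sel_tr != "Base") length(transforms) - 1L
            else length(models) - 1L
    comparisons$single <- corrected_dunnett(cv2, selected,
                                            control_name = control)
    comparisons$single$p_adjusted <- dunnett_readjust(comparisons$single,
                                                      mult)
  }
  list(step1 = step1, selected = selected, short_circuit = FALSE,
       step2 = cv2, comparisons = comparisons)
}

# Re-adjust a single observed T for selection bias: the winner was picked
# among `mult` candidates, so its p-value is referred to the max-|T|
# distribution of `mult` equicorrelated statistics.
dunnett_readjust <- function(dres, mult, n_mc = 1e5,
                             mc_seed = 20160210L) {
  if (mult <= 1L) return(dres$p_adjusted)
  df <- attr(dres, "df")
  vapply(dres$T, function(tt) {
    if (!is.finite(tt)) return(0)
    maxT <- with_seed(mc_seed, {
      x0 <- rnorm(n_mc)
      xj <- matrix(rnorm(n_mc * mult), n_mc, mult)
      s <- sqrt(rchisq(n_mc, df) / df)
      apply(abs((x0 + xj) / sqrt(2) / s), 1L, max)
    })
    mean(maxT >= abs(tt))
  }, numeric(1L))
}
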