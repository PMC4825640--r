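make_trial <- function(seed, m = 40, nb = 4, ny = 2, np = 2, sigma = list()) {
  sg <- utils::modifyList(list(g = 1, b = 0.25, t = 0.25, gb = 0.25,
                               gt = 0.25, bt = 0.25, gbt = 0.25, e = 1),
                          sigma)
  set.seed(seed)
  rec <- expand.grid(plant = seq_len(np), family = seq_len(m),
                     block = seq_len(nb), year = seq_len(ny))
  g <- rnorm(m, 0, sqrt(sg$g)); b <- rnorm(nb, 0, sqrt(sg$b))
  t_ <- rnorm(ny, 0, sqrt(sg$t))
  gb <- matrix(rnorm(m * nb, 0, sqrt(sg$gb)), m, nb)
  gt <- matrix(rnorm(m * ny, 0, sqrt(sg$gt)), m, ny)
  bt <- matrix(rnorm(nb * ny, 0, sqrt(sg$bt)), nb, ny)
  gbt <- array(rnorm(m * nb * ny, 0, sqrt(sg$gbt)), c(m, nb, ny))
  val <- 10 + g[rec$family] + b[rec$block] + t_[rec$year] +
    gb[cbind(rec$family, rec$block)] + gt[cbind(rec$family, rec$year)] +
    bt[cbind(rec$block, rec$year)] +
    gbt[cbind(rec$family, rec$block, rec$year)] +
    rnorm(nrow(rec), 0, sqrt(sg$e))
  list(records = data.frame(family = sprintf("F%03d", rec$family),
                            block = rec$block, year = rec$year,
                            value = val, stringsAsFactors = FALSE),
       truth = sg, g = setNames(g, sprintf("F%03d", seq_len(m))))
}

test_that("balanced one-way REML matches the closed-form shrinkage BLUP", {
  set.seed(1)
  m <- 30; n_rep <- 6
  g <- rnorm(m, 0, 1)
  fam <- rep(seq_len(m), each = n_rep)
  y <- 5 + g[fam] + rnorm(m * n_rep, 0, 1.5)
  fit <- reml_mixed(y, random = list(g = factor(fam)), pev_term = "g")
  s2g <- unname(fit$varcomp["g"]); s2e <- unname(fit$varcomp["residual"])
  ybar <- tapply(y, fam, mean)
  shrink <- n_rep * s2g / (n_rep * s2g + s2e)
  oracle <- shrink * (as.numeric(ybar) - mean(ybar))
  expect_equal(unname(fit$blup$g), oracle, tolerance = 1e-6)
  # closed-form reliability in the balanced design (the closed form
  # conditions on the grand mean; the MME-based PEV includes its
  # uncertainty, hence the modest tolerance)
  fb <- structure(list(blups = fit$blup$g, pev = fit$pev,
                       varcomp = fit$varcomp,
                       reliabilities = pmin(pmax(1 - fit$pev / s2g, 0), 1)),
                  class = "family_blups")
  expect_equal(unname(reliability(fb)), rep(shrink, m),
               tolerance = 0.05)
})

test_that("REML engine agrees with lme4 on a crossed design", {
  skip_if_not_installed("lme4")
  tr <- make_trial(7, m = 30, nb = 3, ny = 2, np = 2)
  fit <- fit_plant_model(tr$records)
  d <- tr$records
  lf <- lme4::lmer(value ~ 1 + (1 | family) + (1 | block) + (1 | year) +
                     (1 | family:block) + (1 | family:year) +
                     (1 | block:year) + (1 | family:block:year),
                   data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(lf))
  oracle <- setNames(vc$vcov, vc$grp)
  expect_equal(unname(fit$varcomp["g"]), unname(oracle["family"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$varcomp["residual"]), unname(oracle["Residual"]),
               tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-5)
  re <- lme4::ranef(lf)$family
  expect_equal(unname(fit$blups[rownames(re)]),
               unname(re[[1]] - mean(re[[1]])), tolerance = 1e-4)
})

test_that("variance components are recovered on simulated trials", {
  ok <- sapply(1:3, function(s) {
    tr <- make_trial(s, m = 60, nb = 4, ny = 2, np = 3)
    fit <- fit_plant_model(tr$records, control = list(restarts = 0))
    # well-replicated components only; 2-4 level factors are inherently
    # unstable at any sample size
    rel_err <- abs(fit$varcomp[c("g", "gb", "gt", "gbt", "residual")] -
                     c(1, 0.25, 0.25, 0.25, 1)) /
      c(1, 0.25, 0.25, 0.25, 1)
    all(rel_err < 0.5)
  })
  expect_gte(sum(ok), 2)
})

test_that("degenerate and unidentifiable designs are handled", {
  tr <- make_trial(3, m = 20, nb = 3, ny = 2, np = 1,
                   sigma = list(g = 0, gb = 0, gt = 0, gbt = 0))
  fit <- fit_plant_model(tr$records, control = list(restarts = 0))
  expect_lt(fit$varcomp["g"], 0.05)
  expect_lt(max(abs(fit$blups)), 0.2)

  one_year <- tr$records[tr$records$year == 1, ]
  expect_error(fit_plant_model(one_year), "year")
})

test_that("plot model matches plant model on aggregated balanced data", {
  tr <- make_trial(11, m = 30, nb = 3, ny = 2, np = 3,
                   sigma = list(gbt = 0.01))
  ag <- aggregate(value ~ family + block + year, tr$records, mean)
  f_plot <- fit_plot_model(ag, control = list(restarts = 0))
  f_plant <- fit_plant_model(tr$records, control = list(restarts = 0))
  expect_gt(cor(f_plot$blups[names(f_plant$blups)], f_plant$blups,
                method = "spearman"), 0.99)

  # unbalanced data (empty cells) still converge
  drop_rows <- sample(nrow(ag), 25)
  f_unbal <- fit_plot_model(ag[-drop_rows, ], control = list(restarts = 0))
  expect_true(is.finite(f_unbal$loglik))
})

test_that("BLUPs are centered, shrunk, and reliabilities bounded", {
  for (s in c(2, 9)) {
    tr <- make_trial(s, m = 25, nb = 3, ny = 2, np = 2)
    fit <- fit_plant_model(tr$records, control = list(restarts = 0))
    expect_lt(abs(mean(fit$blups)), 1e-6 * max(sd(fit$blups), 1e-12))
    raw <- tapply(tr$records$value, tr$records$family, mean)
    expect_lte(var(fit$blups), var(raw))
    expect_true(all(fit$reliabilities >= 0 & fit$reliabilities <= 1))
  }
})

test_that("REML optimum beats random parameter vectors", {
  tr <- make_trial(5, m = 25, nb = 3, ny = 2, np = 2)
  rec <- tr$records
  fac <- list(g = factor(rec$family), b = factor(rec$block),
              t = factor(rec$year))
  fit <- reml_mixed(rec$value, random = fac)
  # evaluate the profiled REML objective at random variance ratios through
  # a dense oracle: -2 loglik of y ~ N(mu, V)
  neg2_at <- function(theta) {
    n <- nrow(rec)
    Zs <- lapply(fac, function(f) outer(f, levels(f), "==") * 1)
    V <- diag(n)
    for (i in seq_along(Zs)) V <- V + theta[i] * tcrossprod(Zs[[i]])
    s2e_grid <- seq(0.2, 3, length.out = 15)
    X <- matrix(1, n, 1)
    best <- Inf
    for (s2e in s2e_grid) {
      Vf <- s2e * V
      ch <- chol(Vf)
      Viy <- backsolve(ch, forwardsolve(t(ch), rec$value))
      ViX <- backsolve(ch, forwardsolve(t(ch), X))
      mu <- sum(ViX * rec$value) / sum(ViX * X)
      r <- rec$value - mu
      Vir <- backsolve(ch, forwardsolve(t(ch), r))
      v <- 2 * sum(log(diag(ch))) + log(sum(X * ViX)) + sum(r * Vir) +
        (n - 1) * log(2 * pi)
      best <- min(best, v)
    }
    best
  }
  set.seed(99)
  for (i in 1:20) {
    theta <- exp(runif(3, -2, 2))
    expect_gte(neg2_at(theta), -2 * fit$loglik - 1e-6)
  }
})

test_that("spatial plot term is selected when and only when present", {
  harness <- function(sp2, seeds) sapply(seeds, function(s) {
    cfg <- sim_config(seed = s, n_parents_per_pop = c(40, 2),
                      n_chromosomes = 1, markers_per_chromosome = 30,
                      sigma_plot2 = sp2, ar1_rho_row = 0.8,
                      ar1_rho_col = 0.8, n_blocks = 3, n_years = 2,
                      plants_per_family_per_block = 2, n_causal = 5)
    par <- simulate_parents(cfg)
    ph <- simulate_phenotypes(par$truth, cfg, level = "plant")
    as.logical(select_spatial_by_bic(ph, control = list(restarts = 0)))
  })
  expect_gte(sum(harness(2, 1:5)), 4)   # strong spatial signal detected
  expect_lte(sum(harness(0, 1:5)), 2)   # absent signal mostly rejected
})

test_that("outcome descriptives summarize range, mean, SD and reliability", {
  tr <- make_trial(21, m = 20, nb = 3, ny = 2, np = 2)
  de <- outcome_descriptives(tr$records, level = "plant",
                             control = list(restarts = 0))
  expect_equal(de$range, range(tr$records$value))
  expect_equal(de$mean, mean(tr$records$value))
  expect_equal(de$sd, sd(tr$records$value))
  expect_true(de$reliability_mean > 0 && de$reliability_mean <= 1)
})
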