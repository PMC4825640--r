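test_that("same seed reproduces every simulated artifact bitwise", {
  cfg <- sim_config(seed = 11, n_parents_per_pop = c(20, 15),
                    n_chromosomes = 2, markers_per_chromosome = 25,
                    n_causal = 5)
  a <- simulate_parents(cfg)
  b <- simulate_parents(cfg)
  expect_identical(a, b)
  ra <- simulate_read_counts(a$dosages, 6, 0.01, seed = 3)
  rb <- simulate_read_counts(b$dosages, 6, 0.01, seed = 3)
  expect_identical(ra, rb)
  pa <- simulate_phenotypes(a$truth, cfg, level = "plant")
  pb <- simulate_phenotypes(b$truth, cfg, level = "plant")
  expect_identical(pa, pb)
})

test_that("configuration invalidity is rejected", {
  expect_error(sim_config(ld_decay_rate = c(1, 0.5)), "ld_decay_rate")
  expect_error(sim_config(sigma_g2 = -1), "nonnegative")
  expect_error(sim_config(seq_error = 0.5), "seq_error")
  expect_error(sim_config(markers_per_chromosome = 0), "positive")
  expect_error(sim_config(h2_family = 0.9, sigma_g2 = 1, sigma_e2 = 5),
               "inconsistent")
  # h2_family without explicit sigma_e2 solves the residual variance
  cfg <- sim_config(h2_family = 0.25, sigma_g2 = 1, sigma_b2 = 0.5,
                    sigma_t2 = 0.5, sigma_gb2 = 0, sigma_gt2 = 0,
                    sigma_bt2 = 0, sigma_gbt2 = 0, sigma_plot2 = 0)
  tot <- with(cfg, sigma_g2 + sigma_b2 + sigma_t2 + sigma_e2)
  expect_equal(cfg$sigma_g2 / tot, 0.25, tolerance = 1e-8)
})

test_that("adjacent-marker LD matches the decay regime", {
  # independence regime
  cfg0 <- sim_config(seed = 6, n_parents_per_pop = c(500, 2),
                     n_chromosomes = 1, markers_per_chromosome = 200,
                     ld_decay_rate = c(0, 0),
                     bottleneck_block_prob = c(0, 0), n_causal = 5)
  G0 <- simulate_parents(cfg0)$dosages[1:500, ]
  r0 <- sapply(seq_len(ncol(G0) - 1L), function(j)
    suppressWarnings(cor(G0[, j], G0[, j + 1L])))
  expect_lt(mean(abs(r0), na.rm = TRUE), 0.08)

  # strong-LD regime: median adjacent r^2 within the documented band
  cfg9 <- sim_config(seed = 4, n_parents_per_pop = c(200, 2),
                     n_chromosomes = 1, markers_per_chromosome = 500,
                     ld_decay_rate = c(0.9, 0.2),
                     maf_distribution = c("uniform", "uniform"),
                     ld_block_mean_length = 1e9,  # one uninterrupted block
                     bottleneck_block_prob = c(0, 0), n_causal = 5)
  G9 <- simulate_parents(cfg9)$dosages[1:200, ]
  v <- apply(G9, 2, var)
  r <- sapply(seq_len(ncol(G9) - 1L), function(j)
    if (v[j] > 0 && v[j + 1L] > 0) cor(G9[, j], G9[, j + 1L]) else NA)
  expect_gt(median(r^2, na.rm = TRUE), 0.6)
  expect_lt(median(r^2, na.rm = TRUE), 0.95)
})

test_that("realized MAF spectrum matches the configured distribution", {
  # decay 0 so draws are independent; test the generator's drawn true MAFs
  pass <- sapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_parents_per_pop = c(2, 2),
                      n_chromosomes = 10, markers_per_chromosome = 500,
                      ld_decay_rate = c(0, 0),
                      bottleneck_block_prob = c(0, 0), n_causal = 2)
    tr <- simulate_parents(cfg)$truth
    p_u <- ks.test(tr$maf_draws$pop1,
                   function(x) pbeta(sqrt((x - 0.01) / 0.49), 1, 1))$p.value
    # pop1 is u-shaped: maf = 0.01 + 0.49 u^2, u ~ U(0,1)
    p_un <- ks.test(tr$maf_draws$pop2,
                    function(x) punif(x, 0.01, 0.5))$p.value
    p_u > 0.01 && p_un > 0.01
  })
  expect_gte(sum(pass), 19)
})

test_that("read counts follow the binomial emission model", {
  d2 <- matrix(2L, 1, 1, dimnames = list("a", "m"))
  rc <- simulate_read_counts(d2, 1e4, 0, seed = 1)
  expect_equal(rc$ref[1, 1], 0L)
  d1 <- matrix(1L, 1, 1, dimnames = list("a", "m"))
  rc1 <- simulate_read_counts(d1, 1e4, 0, seed = 2)
  expect_equal(rc1$alt / (rc1$alt + rc1$ref), 0.5, tolerance = 0.02,
               ignore_attr = TRUE)
  d0 <- matrix(0L, 1, 1, dimnames = list("a", "m"))
  rc0 <- simulate_read_counts(d0, 1e4, 0.01, seed = 3)
  expect_equal(rc0$alt / (rc0$alt + rc0$ref), 0.01, tolerance = 0.005,
               ignore_attr = TRUE)
  expect_error(simulate_read_counts(d0, 10, 0.6, seed = 1), "seq_error")
  expect_error(simulate_read_counts(matrix(3L, 1, 1), 10, 0, seed = 1),
               "dosages")
})

test_that("phenotype generator honors the mixed-model structure", {
  cfg0 <- sim_config(seed = 2, n_parents_per_pop = c(10, 2),
                     n_chromosomes = 1, markers_per_chromosome = 10,
                     sigma_g2 = 0, sigma_b2 = 0, sigma_t2 = 0,
                     sigma_gb2 = 0, sigma_gt2 = 0, sigma_bt2 = 0,
                     sigma_gbt2 = 0, sigma_plot2 = 0, sigma_e2 = 0,
                     n_causal = 2)
  par <- simulate_parents(cfg0)
  ph <- simulate_phenotypes(par$truth, cfg0, level = "plant", mu = 7)
  expect_true(all(ph$value == 7))

  # variance of family means ~ sigma_g2 when nuisance terms are tiny
  cfg1 <- sim_config(seed = 3, n_parents_per_pop = c(150, 2),
                     n_chromosomes = 1, markers_per_chromosome = 30,
                     sigma_g2 = 1, sigma_b2 = 0.01, sigma_t2 = 0.01,
                     sigma_gb2 = 0.01, sigma_gt2 = 0.01, sigma_bt2 = 0.01,
                     sigma_gbt2 = 0.01, sigma_e2 = 0.01, n_blocks = 4,
                     n_years = 2, plants_per_family_per_block = 3,
                     n_causal = 10)
  par1 <- simulate_parents(cfg1)
  ph1 <- simulate_phenotypes(par1$truth, cfg1, level = "plant")
  fam_means <- tapply(ph1$value, ph1$family, mean)
  expect_equal(var(fam_means), 1, tolerance = 0.25)

  # heritability plumbing: with nuisance variances 0 and genetic values
  # passed through directly, family means regress on them with slope 1
  cfg2 <- sim_config(seed = 4, n_parents_per_pop = c(40, 2),
                     n_chromosomes = 1, markers_per_chromosome = 20,
                     sigma_b2 = 0, sigma_t2 = 0, sigma_gb2 = 0,
                     sigma_gt2 = 0, sigma_bt2 = 0, sigma_gbt2 = 0,
                     sigma_plot2 = 0, sigma_e2 = 0, n_causal = 5)
  par2 <- simulate_parents(cfg2)
  gv <- par2$truth$breeding_values
  ph2 <- simulate_phenotypes(par2$truth, cfg2, level = "plot",
                             genetic_values = gv)
  fm <- tapply(ph2$value, ph2$family, mean)[names(gv)]
  expect_equal(unname(coef(lm(fm ~ gv))[2]), 1, tolerance = 1e-8)
})

test_that("AR1 x AR1 plot effects have the configured autocorrelation", {
  lag1 <- replicate(100, {
    f <- gsld:::sim_ar1_field(12, 12, 0.8, 0.3)
    cor(as.vector(f[-12, ]), as.vector(f[-1, ]))
  })
  expect_equal(mean(lag1), 0.8, tolerance = 0.1)
})

test_that("ground truth breeding values are exact dosage sums", {
  cfg <- sim_config(seed = 8, n_parents_per_pop = c(25, 20),
                    n_chromosomes = 2, markers_per_chromosome = 20,
                    n_causal = 6)
  par <- simulate_parents(cfg)
  tr <- par$truth
  Xc <- scale(par$dosages[, tr$causal_marker_ids], center = TRUE,
              scale = FALSE)
  expect_equal(unname(tr$breeding_values),
               unname(drop(Xc %*% tr$causal_effects)), tolerance = 1e-12)
})

test_that("bottleneck blocks create perfect-LD clusters with rare alleles", {
  cfg <- sim_config(seed = 13, n_parents_per_pop = c(80, 10),
                    n_chromosomes = 1, markers_per_chromosome = 80,
                    ld_decay_rate = c(0.5, 0.5), ld_block_mean_length = 10,
                    bottleneck_block_prob = c(1, 0),
                    maf_distribution = c("uniform", "uniform"),
                    n_causal = 5)
  G <- simulate_parents(cfg)$dosages[1:80, ]
  G <- G[, apply(G, 2, var) > 0]
  R <- abs(cor(G))
  # perfect-LD pairs must exist in pop1 under forced bottleneck blocks
  expect_gt(mean(R[upper.tri(R)] > 0.999), 0.05)
})
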