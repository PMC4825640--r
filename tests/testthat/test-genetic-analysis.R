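relatedness_fixture <- function(seed, m = 100, q = 150) {
  set.seed(seed)
  G <- matrix(rbinom(m * q, 2, 0.3), m, q,
              dimnames = list(sprintf("i%03d", 1:m), sprintf("m%03d", 1:q)))
  K <- grm(base_transform(G))
  rownames(K) <- colnames(K) <- rownames(G)
  list(G = G, K = K, L = t(chol(K + 1e-6 * diag(m))))
}

test_that("bivariate GBLUP recovers the genomic correlation", {
  fx <- relatedness_fixture(5)
  m <- nrow(fx$K)
  set.seed(5)
  u <- drop(fx$L %*% rnorm(m))
  g1 <- setNames(u + rnorm(m, 0, 0.6), rownames(fx$K))
  same <- bivariate_gblup(g1, g1, fx$K)
  expect_gt(same$rg, 0.99)
  expect_true(all(eigen(same$genetic_cov)$values > -1e-8))

  rg_hat <- sapply(1:3, function(s) {
    set.seed(s)
    z1 <- rnorm(m); z2 <- 0.8 * z1 + sqrt(1 - 0.64) * rnorm(m)
    gg1 <- setNames(drop(fx$L %*% z1) + rnorm(m, 0, 0.5), rownames(fx$K))
    gg2 <- setNames(drop(fx$L %*% z2) + rnorm(m, 0, 0.5), rownames(fx$K))
    bivariate_gblup(gg1, gg2, fx$K)$rg
  })
  expect_gte(sum(rg_hat > 0.6 & rg_hat < 0.95), 2)

  rg_null <- sapply(1:3, function(s) {
    set.seed(s + 100)
    gg1 <- setNames(drop(fx$L %*% rnorm(m)) + rnorm(m, 0, 0.5),
                    rownames(fx$K))
    gg2 <- setNames(drop(fx$L %*% rnorm(m)) + rnorm(m, 0, 0.5),
                    rownames(fx$K))
    bivariate_gblup(gg1, gg2, fx$K)$rg
  })
  expect_gte(sum(abs(rg_null) < 0.3), 2)
})

test_that("EMMAX reduces to per-marker regression with an identity kernel", {
  set.seed(8)
  n <- 50
  M <- matrix(rbinom(n * 40, 2, 0.4), n, 40,
              dimnames = list(paste0("i", 1:n), paste0("m", 1:40)))
  g <- setNames(rnorm(n), rownames(M))
  K_I <- diag(n); dimnames(K_I) <- list(names(g), names(g))
  gw <- gwas_emmax(g, M, K_I, maf_min = 0.05)
  lmp <- sapply(gw$marker_id,
                function(mk) summary(lm(g ~ M[, mk]))$coefficients[2, 4])
  expect_equal(gw$p, unname(lmp), tolerance = 1e-8)
  expect_true(all(gw$maf > 0.05))
})

test_that("EMMAX is calibrated under the null and finds planted QTL", {
  fx <- relatedness_fixture(9, m = 80, q = 120)
  ok_null <- sapply(1:3, function(s) {
    set.seed(s)
    g <- setNames(drop(fx$L %*% rnorm(80)) * 0.3 + rnorm(80),
                  rownames(fx$K))
    ks.test(gwas_emmax(g, fx$G, fx$K)$p, punif)$p.value > 0.01
  })
  expect_gte(sum(ok_null), 2)

  hits <- sapply(1:3, function(s) {
    set.seed(s + 50)
    qtl <- fx$G[, 7]
    g <- setNames(drop(scale(qtl)) * sqrt(0.25) +
                    drop(fx$L %*% rnorm(80)) * sqrt(0.2) +
                    rnorm(80, 0, sqrt(0.55)), rownames(fx$K))
    gw <- gwas_emmax(g, fx$G, fx$K)
    top <- gw$marker_id[which.min(gw$p)]
    top == "m007" || abs(cor(fx$G[, top], qtl)) > 0.8
  })
  expect_gte(sum(hits), 2)
})

test_that("forward BIC selection matches the exhaustive oracle", {
  set.seed(9)
  n <- 60
  Mb <- matrix(rbinom(n * 5, 2, 0.4), n, 5,
               dimnames = list(paste0("i", 1:n), paste0("m", 1:5)))
  Mb <- cbind(Mb, dup = Mb[, 1])
  colnames(Mb)[6] <- "m1dup"
  gt <- setNames(drop(scale(Mb[, 1])) + rnorm(n, 0, 0.7), rownames(Mb))
  K <- relatedness_fixture(10, m = n, q = 60)$K
  rownames(K) <- colnames(K) <- rownames(Mb)
  fb <- forward_bic(gt, Mb, colnames(Mb), K)
  expect_true(fb$selected[1] %in% c("m1", "m1dup"))
  expect_false(all(c("m1", "m1dup") %in% fb$selected))  # collinearity guard
  expect_true(all(diff(fb$bic_path) < 0))
  expect_equal(forward_bic(gt, Mb, character(0), K)$selected, character(0))

  # exhaustive-subset oracle over the five distinct candidates: the greedy
  # final set must attain the best subset BIC (independent dense ML code)
  subset_bic <- function(set) {
    X <- cbind(1, Mb[, set, drop = FALSE])
    obj <- function(loglam) {
      V0 <- K + exp(loglam) * diag(n)
      ch <- chol(V0)
      ViX <- backsolve(ch, forwardsolve(t(ch), X))
      Viy <- backsolve(ch, forwardsolve(t(ch), gt))
      beta <- solve(crossprod(X, ViX), crossprod(X, Viy))
      r <- gt - drop(X %*% beta)
      Vir <- backsolve(ch, forwardsolve(t(ch), r))
      s2 <- sum(r * Vir) / n
      n * log(s2) + 2 * sum(log(diag(ch))) + n * (1 + log(2 * pi))
    }
    op <- optimize(obj, c(-12, 12), tol = 1e-7)
    op$objective + (ncol(X) + 2) * log(n)
  }
  cands <- colnames(Mb)[1:5]
  subsets <- unlist(lapply(0:3, function(k)
    combn(cands, k, simplify = FALSE)), recursive = FALSE)
  bics <- vapply(subsets, subset_bic, numeric(1))
  best_set <- subsets[[which.min(bics)]]
  expect_setequal(sub("dup", "", fb$selected), sub("dup", "", best_set))
})

test_that("likelihood-ratio R2 follows its closed form", {
  expect_equal(r2_lr(10, 10, 50), 0)
  expect_equal(r2_lr(12, 10, 100), 1 - exp(-0.04), tolerance = 1e-12)
  expect_equal(r2_lr(12, 10, 100), 0.0392, tolerance = 1e-3)
  vals <- sapply(c(0.5, 1, 2, 4), function(d) r2_lr(10 + d, 10, 80))
  expect_true(all(diff(vals) > 0))
  expect_error(r2_lr(9, 10, 50), "negative")
})

test_that("heritability partition attributes variance to the causal class", {
  fx <- relatedness_fixture(12, m = 90, q = 90)
  Xb <- base_transform(fx$G)
  # synthetic tagging: thirds of the markers by construction
  tg <- setNames(rep(c(1, 2, 4), each = 30), colnames(fx$G))

  hits <- sapply(1:3, function(s) {
    set.seed(s)
    causal <- colnames(fx$G)[61:90]  # the "high" class
    u <- drop(scale(unclass(Xb)[, causal] %*% rnorm(30)))
    g <- setNames(u * sqrt(0.6) + rnorm(90, 0, sqrt(0.4)), rownames(fx$G))
    pt <- partition_heritability(g, Xb, tg)
    names(which.max(pt$contributions)) == "high"
  })
  expect_gte(sum(hits), 2)

  # null trait: small contributions
  ok_null <- sapply(1:3, function(s) {
    set.seed(s + 20)
    g <- setNames(rnorm(90), rownames(fx$G))
    all(partition_heritability(g, Xb, tg)$contributions < 0.15)
  })
  expect_gte(sum(ok_null), 2)

  # invariance to marker order; shares sum to at most 1
  set.seed(2)
  g <- setNames(drop(scale(unclass(Xb) %*% rnorm(90))) + rnorm(90),
                rownames(fx$G))
  p1 <- partition_heritability(g, Xb, tg)
  perm <- sample(90)
  p2 <- partition_heritability(g, Xb[, perm], tg[perm])
  expect_equal(p1$contributions, p2$contributions, tolerance = 1e-3)
  expect_lte(sum(p1$contributions), 1 + 1e-8)

  # degenerate single class equals the plain GBLUP heritability
  tg1 <- setNames(rep(2, 90), colnames(fx$G))
  pd <- partition_heritability(g, Xb, tg1)
  h2 <- fit_gblup(unname(g), K = grm(Xb))$h2
  expect_equal(unname(pd$contributions["low"]), h2, tolerance = 1e-3)
  expect_equal(unname(pd$contributions[c("intermediate", "high")]),
               c(0, 0))
})
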