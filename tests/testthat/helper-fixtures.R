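# Shared fixtures, all generated in code under fixed seeds.

# small random dosage matrix with chromosome labels (independent markers)
random_dosage_fixture <- function(seed, n = 40, q = 60, n_chrom = 2,
                                  p_range = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(q, p_range[1], p_range[2])
  G <- sapply(p, function(pp) rbinom(n, 2, pp))
  dimnames(G) <- list(sprintf("ind%03d", seq_len(n)),
                      sprintf("mk%03d", seq_len(q)))
  list(G = G, chrom = rep(sprintf("chr%d", seq_len(n_chrom)),
                          length.out = q)[order(rep(seq_len(n_chrom),
                                                    length.out = q))])
}

# well-conditioned fixture: more genotypes than markers per chromosome
conditioned_fixture <- function(seed, n = 50, q = 200, n_chrom = 8) {
  set.seed(seed)
  p <- runif(q, 0.1, 0.5)
  G <- sapply(p, function(pp) rbinom(n, 2, pp))
  dimnames(G) <- list(sprintf("g%03d", seq_len(n)),
                      sprintf("m%03d", seq_len(q)))
  list(G = G, chrom = rep(sprintf("chr%d", seq_len(n_chrom)),
                          each = q / n_chrom))
}

# a gs_dataset with genuine genetic signal for prediction tests
signal_dataset <- function(seed, m1 = 70, m2 = 30, q_chr = 40, n_chrom = 3,
                           h2 = 0.6, locations = "NE") {
  cfg <- sim_config(seed = seed, n_parents_per_pop = c(m1, m2),
                    n_chromosomes = n_chrom, markers_per_chromosome = q_chr,
                    ld_decay_rate = c(0.5, 0.5),
                    maf_distribution = c("uniform", "uniform"),
                    bottleneck_block_prob = c(0, 0),
                    n_causal = 20, causal_tagging_stratum = "random")
  par <- simulate_parents(cfg)
  dm <- new_dosage_matrix(par$dosages + 0.0, par$marker_info,
                          par$populations)
  oc <- do.call(rbind, lapply(seq_along(locations), function(i) {
    g <- simulate_family_outcome(par$truth, h2, seed = seed + 1000 * i,
                                 populations = par$populations)
    data.frame(genotype = names(g), population = par$populations,
               trait = "DMY", location = locations[i],
               value = as.numeric(g), stringsAsFactors = FALSE)
  }))
  list(data = build_gs_dataset(dm, oc), parents = par, config = cfg)
}

# target-outcome values of population 1 from a signal_dataset
outcome_values_fixture <- function(sd, population = "pop1",
                                   location = NULL) {
  oc <- sd$data$outcomes
  if (is.null(location)) location <- oc$location[1]
  sel <- oc$population == population & oc$location == location
  setNames(oc$value[sel], oc$genotype[sel])
}

# brute-force vertex-enumeration oracle for the 1-norm nonnegative LP
# min ||Aw - b||_1, w >= 0 (small q only)
l1_lp_vertex_oracle <- function(A, b) {
  q <- ncol(A)
  m <- nrow(A)
  Af <- cbind(A, diag(m), -diag(m))
  cost <- c(rep(0, q), rep(1, 2 * m))
  best <- Inf
  for (cols in combn(ncol(Af), m, simplify = FALSE)) {
    B <- Af[, cols, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    x <- solve(B, b)
    if (all(x >= -1e-10)) best <- min(best, sum(cost[cols] * x))
  }
  best
}
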