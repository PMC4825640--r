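#' Configuration for the two-population half-sib simulator
#'
#' Collects every parameter of the synthetic-data generator: genome layout,
#' per-population linkage-disequilibrium (LD) decay and minor-allele-frequency
#' (MAF) spectrum, the genetic architecture of the simulated outcome, the
#' variance components of the field-trial model, and the sequencing emission
#' model.  Defaults emulate two polycross populations of maternal parents
#' (137 and 110 genotyped parents) with contrasting within-chromosome LD
#' decay, evaluated in a randomized complete block design over several years.
#'
#' @param seed master seed; every downstream stage derives its own stream
#'   from it.
#' @param n_parents_per_pop integer vector of length 2, genotyped parents per
#'   population.
#' @param n_chromosomes,markers_per_chromosome genome layout.
#' @param ld_decay_rate length-2 vector in `[0, 1)`: expected correlation
#'   between adjacent-marker haplotype alleles within a haplotype block,
#'   per population (geometric decay with marker distance inside blocks).
#' @param ld_block_mean_length expected number of markers per haplotype
#'   block; adjacent-pair correlation drops to zero at block boundaries
#'   (recombination hotspots), which is what makes the degree of tagging
#'   heterogeneous across markers.
#' @param bottleneck_block_prob length-2 vector: per-population probability
#'   that a haplotype block is a "bottleneck" region segregating only two
#'   haplotype variants, so all its markers are in perfect LD (degree of
#'   tagging equal to the block length).  Emulates extended LD from
#'   low-frequency haplotypes with limited recombination, the structure
#'   that couples rarity with extreme tagging in an upland-ecotype pool.
#' @param bottleneck_freq_range frequency range of the bottleneck haplotype
#'   variant (its markers' MAF falls in this range regardless of
#'   `maf_distribution`).
#' @param maf_distribution length-2 character vector, `"ushaped"` (density
#'   rising towards rare alleles, emulating a diverse outbred pool) or
#'   `"uniform"`, per population.
#' @param n_causal number of causal markers.
#' @param causal_tagging_stratum `"low"`, `"intermediate"`, `"high"` or
#'   `"random"`: tertile of the degree-of-tagging distribution (computed on
#'   population 1's simulated dosages) from which causal markers are drawn.
#' @param h2_family optional plant-level heritability
#'   \eqn{\sigma_g^2 / \sigma_{tot}^2}.  When supplied, `sigma_e2` is solved
#'   from the other components; supplying both an inconsistent `h2_family`
#'   and `sigma_e2` is an error.
#' @param sigma_g2,sigma_b2,sigma_t2,sigma_gb2,sigma_gt2,sigma_bt2,sigma_gbt2
#'   variances of family, block, year and interaction effects.
#' @param sigma_plot2 variance of the spatially correlated plot effect
#'   (`0` disables it).
#' @param sigma_e2 residual (within-plot / plant) variance.
#' @param ar1_rho_row,ar1_rho_col first-order autoregressive correlations of
#'   the plot effect along field rows and columns, in `(-1, 1)`.
#' @param n_blocks,n_years,plants_per_family_per_block trial layout.
#' @param read_depth_mean mean of the per-observation Poisson read depth.
#' @param seq_error sequencing/alignment error rate in `[0, 0.5)`.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_parents_per_pop = c(137L, 110L),
                       n_chromosomes = 3L,
                       markers_per_chromosome = 100L,
                       ld_decay_rate = c(0.35, 0.8),
                       ld_block_mean_length = 8,
                       bottleneck_block_prob = c(0.3, 0),
                       bottleneck_freq_range = c(0.05, 0.25),
                       maf_distribution = c("ushaped", "uniform"),
                       n_causal = 20L,
                       causal_tagging_stratum = "random",
                       h2_family = NULL,
                       sigma_g2 = 1, sigma_b2 = 0.25, sigma_t2 = 0.25,
                       sigma_gb2 = 0.1, sigma_gt2 = 0.1, sigma_bt2 = 0.1,
                       sigma_gbt2 = 0.1, sigma_plot2 = 0, sigma_e2 = 2,
                       ar1_rho_row = 0.5, ar1_rho_col = 0.5,
                       n_blocks = 4L, n_years = 2L,
                       plants_per_family_per_block = 3L,
                       read_depth_mean = 8, seq_error = 0.01) {
  vc <- c(sigma_g2 = sigma_g2, sigma_b2 = sigma_b2, sigma_t2 = sigma_t2,
          sigma_gb2 = sigma_gb2, sigma_gt2 = sigma_gt2, sigma_bt2 = sigma_bt2,
          sigma_gbt2 = sigma_gbt2, sigma_plot2 = sigma_plot2,
          sigma_e2 = sigma_e2)
  if (any(vc < 0)) stop("all variance components must be nonnegative")
  if (length(n_parents_per_pop) != 2L || any(n_parents_per_pop < 2L))
    stop("n_parents_per_pop must be two integers >= 2")
  if (n_chromosomes < 1L || markers_per_chromosome < 1L)
    stop("genome layout counts must be positive")
  if (any(ld_decay_rate < 0) || any(ld_decay_rate >= 1))
    stop("ld_decay_rate must be in [0, 1)")
  if (ld_block_mean_length < 1) stop("ld_block_mean_length must be >= 1")
  if (any(bottleneck_block_prob < 0) || any(bottleneck_block_prob > 1))
    stop("bottleneck_block_prob must be in [0, 1]")
  if (bottleneck_freq_range[1L] <= 0 || bottleneck_freq_range[2L] >= 1 ||
      diff(bottleneck_freq_range) < 0)
    stop("invalid bottleneck_freq_range")
  if (!all(maf_distribution %in% c("ushaped", "uniform")))
    stop("maf_distribution must be 'ushaped' or 'uniform'")
  if (!causal_tagging_stratum %in% c("low", "intermediate", "high", "random"))
    stop("invalid causal_tagging_stratum")
  if (abs(ar1_rho_row) >= 1 || abs(ar1_rho_col) >= 1)
    stop("AR1 correlations must be in (-1, 1)")
  if (seq_error < 0 || seq_error >= 0.5) stop("seq_error must be in [0, 0.5)")
  if (!is.null(h2_family)) {
    if (h2_family < 0 || h2_family > 1) stop("h2_family must be in [0, 1]")
    other <- sum(vc[setdiff(names(vc), c("sigma_g2", "sigma_e2"))])
    implied_e <- sigma_g2 / h2_family - sigma_g2 - other
    if (implied_e < -1e-8)
      stop("h2_family inconsistent with the supplied variance components")
    if (!missing(sigma_e2)) {
      tot <- sum(vc)
      if (abs(sigma_g2 / tot - h2_family) > 1e-8)
        stop("h2_family and sigma_e2 both given but inconsistent")
    } else {
      sigma_e2 <- max(implied_e, 0)
    }
  }
  structure(list(
    seed = as.integer(seed),
    n_parents_per_pop = as.integer(n_parents_per_pop),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    ld_decay_rate = ld_decay_rate,
    ld_block_mean_length = ld_block_mean_length,
    bottleneck_block_prob = bottleneck_block_prob,
    bottleneck_freq_range = bottleneck_freq_range,
    maf_distribution = maf_distribution,
    n_causal = as.integer(n_causal),
    causal_tagging_stratum = causal_tagging_stratum,
    sigma_g2 = sigma_g2, sigma_b2 = sigma_b2, sigma_t2 = sigma_t2,
    sigma_gb2 = sigma_gb2, sigma_gt2 = sigma_gt2, sigma_bt2 = sigma_bt2,
    sigma_gbt2 = sigma_gbt2, sigma_plot2 = sigma_plot2, sigma_e2 = sigma_e2,
    ar1_rho_row = ar1_rho_row, ar1_rho_col = ar1_rho_col,
    n_blocks = as.integer(n_blocks), n_years = as.integer(n_years),
    plants_per_family_per_block = as.integer(plants_per_family_per_block),
    read_depth_mean = read_depth_mean, seq_error = seq_error
  ), class = "sim_config")
}

# MAF draws by quantile transform of a spatially smooth uniform, so that the
# marginal spectrum is exactly the configured distribution while adjacent
# markers have similar frequencies (which real LD blocks do, and which keeps
# the target adjacent-haplotype correlation attainable for Bernoulli margins).
maf_quantile <- function(u, distribution) {
  switch(distribution,
         uniform = 0.01 + u * 0.49,
         ushaped = 0.01 + 0.49 * u^2,  # density ~ 1/sqrt(m): rare-heavy
         stop("unknown maf distribution"))
}

# One population's haplotypes for one chromosome: a first-order Markov chain
# on {0,1} with marginal allele frequency p[j] at marker j and per-pair
# target adjacent correlation rho[j-1] (attenuated where Bernoulli margins
# make the target infeasible).  Pair-specific correlations encode haplotype
# blocks: high within a block, ~0 at recombination hotspots.
sim_haplotypes_chrom <- function(n_hap, p, rho) {
  q <- length(p)
  if (length(rho) == 1L) rho <- rep(rho, max(q - 1L, 0L))
  H <- matrix(0L, n_hap, q)
  H[, 1L] <- as.integer(runif(n_hap) < p[1L])
  if (q == 1L) return(H)
  for (j in 2:q) {
    rj <- rho[j - 1L]
    if (is.na(rj)) rj <- 0  # placeholder pairs are refilled by the caller
    if (rj == 0) {
      H[, j] <- as.integer(runif(n_hap) < p[j])
      next
    }
    sd_prev <- sqrt(p[j - 1L] * (1 - p[j - 1L]))
    sd_cur <- sqrt(p[j] * (1 - p[j]))
    slope <- if (sd_prev > 0) rj * sd_cur / sd_prev else 0
    pr <- pmin(pmax(p[j] + slope * (H[, j - 1L] - p[j - 1L]), 0), 1)
    H[, j] <- as.integer(runif(n_hap) < pr)
  }
  H
}

#' Simulate parent genotypes for two populations with contrasting LD decay
#'
#' Draws true allelic dosages (0/1/2) for the genotyped maternal parents of
#' two independent populations.  Within each chromosome, haplotype alleles
#' follow a first-order Markov chain whose adjacent-marker correlation equals
#' the population's `ld_decay_rate`, so the genotype correlation decays
#' geometrically with marker distance; allele frequencies are drawn from the
#' configured MAF spectrum.  Populations are simulated independently (zero
#' cross-population relatedness).  Causal markers are then placed in the
#' requested degree-of-tagging stratum (computed on population 1's dosages)
#' and parent breeding values are the centered dosage-weighted sums of the
#' causal effects.
#'
#' @param config a [sim_config()].
#' @return a list with elements `dosages` (parents x markers integer matrix,
#'   both populations stacked), `marker_info` (data.frame: `marker_id`,
#'   `chrom`, `pos`, `annotated`), `populations` (per-parent labels), and
#'   `truth` (a `ground_truth` list: `causal_marker_ids`, `causal_effects`,
#'   `breeding_values`, `true_dosages`, `allele_freq` per population,
#'   `maf_draws`, `seq_error`).
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_chr <- config$n_chromosomes
  q_chr <- config$markers_per_chromosome
  q <- n_chr * q_chr
  chrom <- rep(sprintf("Chr%02d", seq_len(n_chr)), each = q_chr)
  pos <- with_seed(derive_seed(config$seed, "positions"),
                   unlist(lapply(seq_len(n_chr), function(i)
                     cumsum(1L + rpois(q_chr, 9L)))))
  marker_id <- paste0(chrom, "_", pos)
  marker_info <- data.frame(marker_id = marker_id, chrom = chrom,
                            pos = as.integer(pos), annotated = TRUE,
                            stringsAsFactors = FALSE)

  pops <- c("pop1", "pop2")
  dosage_list <- list()
  freq_list <- list()
  maf_list <- list()
  for (k in 1:2) {
    n <- config$n_parents_per_pop[k]
    rho <- config$ld_decay_rate[k]
    seed_k <- derive_seed(config$seed, paste0("genotypes_", k))
    res <- with_seed(seed_k, {
      p_all <- numeric(q)
      G <- matrix(0L, n, q)
      for (ci in seq_len(n_chr)) {
        idx <- which(chrom == sprintf("Chr%02d", ci))
        # smooth latent AR1 (stationary start) -> uniform -> configured MAF
        # marginal; smooth frequencies keep the target haplotype correlation
        # attainable between neighbours (Bernoulli margins bound the
        # achievable correlation, tightly so for dissimilar frequencies)
        rho_f <- if (rho > 0) rho^(1 / 4) else 0
        z <- Reduce(function(a, b) rho_f * a + sqrt(1 - rho_f^2) * b,
                    as.list(rnorm(length(idx) - 1L)), accumulate = TRUE,
                    init = rnorm(1L))
        m <- maf_quantile(pnorm(z), config$maf_distribution[k])
        flip <- runif(length(idx)) < 0.5
        p <- ifelse(flip, m, 1 - m)
        # haplotype blocks: adjacent-pair correlation is rho inside a block
        # and 0 at hotspot boundaries (geometric block lengths)
        hot <- runif(max(length(idx) - 1L, 0L)) <
          1 / config$ld_block_mean_length
        rho_vec <- ifelse(hot, 0, rho)
        blk <- cumsum(c(1L, as.integer(hot)))
        # bottleneck blocks segregate two haplotype variants only: every
        # marker is a (possibly flipped) copy of the variant indicator, so
        # within-block LD is perfect and MAF equals the variant frequency
        for (b in unique(blk)) {
          bidx <- which(blk == b)
          if (length(bidx) >= 2L &&
              runif(1L) < config$bottleneck_block_prob[k]) {
            fb <- runif(1L, config$bottleneck_freq_range[1L],
                        config$bottleneck_freq_range[2L])
            p[bidx] <- ifelse(runif(length(bidx)) < 0.5, fb, 1 - fb)
            rho_vec[bidx[-length(bidx)]] <- NA  # mark: filled directly
            # sever chain dependence at the block edges
            if (bidx[1L] > 1L) rho_vec[bidx[1L] - 1L] <- 0
            if (bidx[length(bidx)] < length(idx))
              rho_vec[bidx[length(bidx)]] <- 0
          }
        }
        h1 <- sim_haplotypes_chrom(n, p, rho_vec)
        h2 <- sim_haplotypes_chrom(n, p, rho_vec)
        G[, idx] <- h1 + h2
        for (b in unique(blk)) {
          bidx <- which(blk == b)
          if (length(bidx) >= 2L && anyNA(rho_vec[bidx[-length(bidx)]])) {
            v1 <- as.integer(runif(n) < p[bidx[1L]])
            v2 <- as.integer(runif(n) < p[bidx[1L]])
            for (j in bidx) {
              same <- p[j] == p[bidx[1L]]  # flipped markers mirror the variant
              G[, idx[j]] <- if (same) v1 + v2 else 2L - v1 - v2
            }
          }
        }
        p_all[idx] <- p
      }
      list(G = G, p = p_all, maf = pmin(p_all, 1 - p_all))
    })
    rownames(res$G) <- sprintf("%s_P%03d", pops[k], seq_len(n))
    dosage_list[[k]] <- res$G
    freq_list[[k]] <- res$p
    maf_list[[k]] <- res$maf
  }
  dosages <- rbind(dosage_list[[1L]], dosage_list[[2L]])
  colnames(dosages) <- marker_id
  populations <- rep(pops, config$n_parents_per_pop)
  names(populations) <- rownames(dosages)

  truth <- with_seed(derive_seed(config$seed, "architecture"), {
    causal_idx <- pick_causal_markers(dosage_list[[1L]], marker_info,
                                      config$n_causal,
                                      config$causal_tagging_stratum)
    effects <- rnorm(length(causal_idx))
    Xc <- scale(dosages[, causal_idx, drop = FALSE], center = TRUE,
                scale = FALSE)
    bv <- drop(Xc %*% effects)
    list(causal_marker_ids = marker_id[causal_idx],
         causal_effects = effects,
         breeding_values = setNames(bv, rownames(dosages)),
         true_dosages = dosages,
         allele_freq = list(pop1 = freq_list[[1L]], pop2 = freq_list[[2L]]),
         maf_draws = list(pop1 = maf_list[[1L]], pop2 = maf_list[[2L]]),
         seq_error = config$seq_error)
  })
  class(truth) <- "ground_truth"
  list(dosages = dosages, marker_info = marker_info,
       populations = populations, truth = truth)
}

# Choose causal markers from a degree-of-tagging stratum of the simulated
# data (tertiles; "random" ignores tagging).  Monomorphic markers are never
# causal.
pick_causal_markers <- function(G, marker_info, n_causal, stratum) {
  poly <- which(apply(G, 2L, var) > 0)
  if (length(poly) < n_causal) stop("not enough polymorphic markers")
  if (stratum == "random") return(sort(sample(poly, n_causal)))
  cb <- block_correlation_matrix(G[, poly, drop = FALSE],
                                 marker_info$chrom[poly])
  dot <- degree_of_tagging(cb)
  qs <- quantile(dot, c(1 / 3, 2 / 3), type = 1L)
  cls <- cut(dot, c(-Inf, qs, Inf), labels = c("low", "intermediate", "high"))
  pool <- poly[cls == stratum]
  if (length(pool) < n_causal)
    stop("requested tagging stratum has too few markers")
  sort(sample(pool, n_causal))
}

#' Simulate sequencing read counts from true dosages
#'
#' Per individual and marker, total depth is Poisson and the alternate-allele
#' count is Binomial with success probability
#' \eqn{\pi_d = (d/2)(1-\epsilon) + (1-d/2)\epsilon}, where `d` is the true
#' dosage and \eqn{\epsilon} the sequencing/alignment error rate.
#'
#' @param true_dosages integer matrix (individuals x markers) with values in
#'   `{0, 1, 2}`.
#' @param depth_mean positive mean of the Poisson read depth.
#' @param seq_error error rate in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return object of class `read_counts`: list with integer matrices `ref`
#'   and `alt` of the same shape as `true_dosages`.
#' @export
simulate_read_counts <- function(true_dosages, depth_mean, seq_error, seed) {
  if (!all(true_dosages %in% 0:2)) stop("dosages must be integers in {0,1,2}")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (seq_error < 0 || seq_error >= 0.5) stop("seq_error must be in [0, 0.5)")
  with_seed(seed, {
    n <- length(true_dosages)
    depth <- rpois(n, depth_mean)
    pi_d <- (true_dosages / 2) * (1 - seq_error) +
      (1 - true_dosages / 2) * seq_error
    alt <- rbinom(n, depth, as.numeric(pi_d))
    ref <- depth - alt
    out <- list(ref = matrix(as.integer(ref), nrow(true_dosages),
                             dimnames = dimnames(true_dosages)),
                alt = matrix(as.integer(alt), nrow(true_dosages),
                             dimnames = dimnames(true_dosages)))
    class(out) <- "read_counts"
    out
  })
}

# AR1(rho) Cholesky-based draw of an n_row x n_col separable random field
# with unit marginal variance.
sim_ar1_field <- function(n_row, n_col, rho_row, rho_col) {
  ar1_chol <- function(n, rho) {
    S <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
    chol(S)
  }
  Z <- matrix(rnorm(n_row * n_col), n_row, n_col)
  t(ar1_chol(n_row, rho_row)) %*% Z %*% ar1_chol(n_col, rho_col)
}

#' Simulate field-trial phenotypes for half-sib families
#'
#' Generates plant-level records under the full multi-year RCBD model
#' \eqn{y_{ijkl} = \mu + g_i + b_j + t_k + (gb)_{ij} + (gt)_{ik} + (bt)_{jk}
#' + (gbt)_{ijk} + \epsilon_{ijkl}} or plot-level records under the reduced
#' model without the three-way interaction term's plant replication (the
#' pooled-error model \eqn{y_{ijk} = \mu + g_i + b_j + t_k + (gb)_{ij} +
#' (gt)_{ik} + (bt)_{jk} + e_{ijk}}).  The family genetic effect is the
#' parent breeding value (the transmitted half of it; only the scale
#' matters) standardized so that its variance equals `sigma_g2`; all other
#' random terms are i.i.d. normal at their configured variances.  When
#' `sigma_plot2 > 0` a plot effect with separable AR1 row x AR1 column
#' covariance is added (plant level only; the plot model's pooled error
#' absorbs it).
#'
#' @param truth a `ground_truth` from [simulate_parents()] (or any list with
#'   a named `breeding_values` vector).
#' @param config a [sim_config()].
#' @param level `"plant"` or `"plot"`.
#' @param mu grand mean.
#' @param genetic_values optional named per-parent genetic values overriding
#'   the standardized breeding values (plumbing for correlated outcomes).
#' @param seed RNG seed (defaults to a stream derived from `config$seed`).
#' @return data.frame of records with columns `family`, `block`, `year`,
#'   `plant` (plant level), `row`, `col`, `value`, `level`.
#' @export
simulate_phenotypes <- function(truth, config, level = c("plant", "plot"),
                                mu = 0, genetic_values = NULL, seed = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(config, "sim_config"))
  bv <- truth$breeding_values
  fam <- names(bv)
  m <- length(fam)
  if (is.null(seed)) seed <- derive_seed(config$seed, paste0("pheno_", level))
  g <- if (!is.null(genetic_values)) {
    genetic_values[fam]
  } else if (config$sigma_g2 == 0 || sd(bv) == 0) {
    setNames(rep(0, m), fam)
  } else {
    setNames((bv - mean(bv)) / sd(bv) * sqrt(config$sigma_g2), fam)
  }
  nb <- config$n_blocks; ny <- config$n_years
  with_seed(seed, {
    b <- rnorm(nb, 0, sqrt(config$sigma_b2))
    t_ <- rnorm(ny, 0, sqrt(config$sigma_t2))
    gb <- matrix(rnorm(m * nb, 0, sqrt(config$sigma_gb2)), m, nb)
    gt <- matrix(rnorm(m * ny, 0, sqrt(config$sigma_gt2)), m, ny)
    bt <- matrix(rnorm(nb * ny, 0, sqrt(config$sigma_bt2)), nb, ny)

    # plot grid: one plot per family x block, laid row-major on a near-square
    # field
    n_plot <- m * nb
    n_row <- ceiling(sqrt(n_plot))
    n_col <- ceiling(n_plot / n_row)
    if (n_row * n_col < n_plot) stop("grid too small for plot count")
    plot_of <- function(i, j) (j - 1L) * m + i  # family i, block j
    prow <- ((seq_len(n_plot) - 1L) %/% n_col) + 1L
    pcol <- ((seq_len(n_plot) - 1L) %% n_col) + 1L
    plot_eff <- if (config$sigma_plot2 > 0 && level == "plant") {
      fld <- sim_ar1_field(n_row, n_col, config$ar1_rho_row,
                           config$ar1_rho_col) * sqrt(config$sigma_plot2)
      fld[cbind(prow, pcol)]
    } else rep(0, n_plot)

    if (level == "plant") {
      np <- config$plants_per_family_per_block
      gbt <- array(rnorm(m * nb * ny, 0, sqrt(config$sigma_gbt2)),
                   c(m, nb, ny))
      rec <- expand.grid(plant = seq_len(np), family = seq_len(m),
                         block = seq_len(nb), year = seq_len(ny),
                         KEEP.OUT.ATTRS = FALSE)
      pid <- plot_of(rec$family, rec$block)
      eps <- rnorm(nrow(rec), 0, sqrt(config$sigma_e2))
      val <- mu + g[rec$family] + b[rec$block] + t_[rec$year] +
        gb[cbind(rec$family, rec$block)] + gt[cbind(rec$family, rec$year)] +
        bt[cbind(rec$block, rec$year)] +
        gbt[cbind(rec$family, rec$block, rec$year)] + plot_eff[pid] + eps
      data.frame(family = fam[rec$family], block = rec$block,
                 year = 2011L + rec$year,
                 plant = paste0("pl", rec$plant), row = prow[pid],
                 col = pcol[pid], value = as.numeric(val), level = "plant",
                 stringsAsFactors = FALSE)
    } else {
      rec <- expand.grid(family = seq_len(m), block = seq_len(nb),
                         year = seq_len(ny), KEEP.OUT.ATTRS = FALSE)
      pid <- plot_of(rec$family, rec$block)
      e <- rnorm(nrow(rec), 0, sqrt(config$sigma_e2))
      val <- mu + g[rec$family] + b[rec$block] + t_[rec$year] +
        gb[cbind(rec$family, rec$block)] + gt[cbind(rec$family, rec$year)] +
        bt[cbind(rec$block, rec$year)] + e
      data.frame(family = fam[rec$family], block = rec$block,
                 year = 2011L + rec$year, plant = NA_character_,
                 row = prow[pid], col = pcol[pid], value = as.numeric(val),
                 level = "plot", stringsAsFactors = FALSE)
    }
  })
}

#' Simulate a family-mean outcome directly from breeding values
#'
#' Convenience plumbing for prediction experiments: returns per-family
#' outcome values `g + noise` with the genetic share of variance equal to
#' `h2`, standing in for half-sib family BLUPs without running the full
#' phenotype pipeline.  When population labels are supplied, breeding
#' values are standardized within each population — family BLUPs are
#' computed within populations, so between-population frequency shifts
#' never appear in them.
#'
#' @param truth a `ground_truth` (needs `breeding_values`).
#' @param h2 proportion of outcome variance that is genetic, in `[0, 1]`.
#' @param seed RNG seed.
#' @param populations optional named population labels over the parents.
#' @return named numeric vector (one value per parent).
#' @export
simulate_family_outcome <- function(truth, h2, seed, populations = NULL) {
  bv <- truth$breeding_values
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  std <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) * sqrt(h2)
                     else x * 0
  gv <- if (is.null(populations)) std(bv) else {
    out <- bv * 0
    for (pp in unique(populations[names(bv)]))
      out[populations[names(bv)] == pp] <-
        std(bv[populations[names(bv)] == pp])
    out
  }
  with_seed(seed, gv + rnorm(length(bv), 0, sqrt(1 - h2)))
}
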