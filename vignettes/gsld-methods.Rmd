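---
title: "Models and methods behind gsld"
author: "gsld maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gsld}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gsld)
```

`gsld` is a benchmarking toolkit for genomic selection (GS) in half-sib
family breeding programs of outbred crops. The genotyped unit is a maternal
parent; the phenotyped unit is its open-pollinated half-sib progeny grown in
multi-year randomized complete block trials. The package covers the whole
chain from sequencing read counts to validated prediction procedures, and a
synthetic-data generator makes every stage testable end to end. This
vignette describes each model, its assumptions, the tunable parameters, and
the numerical choices made where the design was genuinely open.

## 1. Expected allelic dosages from read counts

Shallow exome-capture sequencing does not support hard genotype calls, so
markers are represented by *expected allelic dosages* in $[0,2]$. For one
marker, the latent dosage $d \in \{0,1,2\}$ of each individual has
Hardy–Weinberg prior $(1-p)^2,\,2p(1-p),\,p^2$ and each read shows the
alternate allele with probability
$\pi_d = (d/2)(1-\epsilon) + (1-d/2)\,\epsilon$, where $\epsilon$ is a
marker-specific sequencing/alignment error rate. `em_fit_marker()` maximizes
the marginal likelihood over $(p, \epsilon)$ by EM: the E-step computes
genotype posteriors, the M-step re-estimates $p$ from the posterior mean
dosage and $\epsilon$ from the posterior-expected mismatch fraction
(heterozygote reads are uninformative about $\epsilon$ beyond the current
estimate, which the latent-read-origin EM handles exactly).
`expected_dosage()` then returns the posterior mean dosage per individual;
with zero depth this is the prior mean $2p$. Fits are per marker and per
population, since allele frequencies differ between populations.

Numerical choices: $p_0$ initialized at the raw alternate-read fraction,
$\epsilon_0 = 0.01$; tolerance $10^{-6}$ on the log-likelihood, at most 200
iterations; $\epsilon$ constrained to $[10^{-6}, 0.5-10^{-6}]$ to avoid the
boundary degeneracy at $\epsilon = 0.5$ (where $d$ and $2-d$ are
indistinguishable). The EM log-likelihood is tested to be monotone and to
match a dense grid-search maximum within $10^{-4}$.

Quality control (`qc_filter()`) applies, in order and with strict
inequalities: missingness $< 5\%$; minor allele frequency $> 1/2N$ and
variance $> 2\,(1/2N)(1-1/2N)$ with $N$ the non-missing genotypes in scope;
within-population Hardy–Weinberg $\chi^2$ p-value $> 10^{-4}$ (computed on
dosages rounded to the nearest genotype class, 1 df, no continuity
correction — the literature does not prescribe how fractional dosages enter
a count test, so rounding is our declared choice); and availability of
genomic-location metadata. A marker is charged to the first rule it
violates, and the filter is idempotent.

## 2. Half-sib family BLUPs

Plant-measured traits follow
$$y_{ijkl} = \mu + g_i + b_j + t_k + (gb)_{ij} + (gt)_{ik} + (bt)_{jk} +
(gbt)_{ijk} + \epsilon_{ijkl},$$
with family ($g$), block ($b$), year ($t$) and all interactions random and
i.i.d. normal; plot-measured traits drop the three-way term and pool the
plot error. An optional plot effect with separable AR1(row) $\otimes$
AR1(column) covariance captures spatial field trend and is kept only when
it lowers the BIC.

`reml_mixed()` is a sparse mixed-model-equation (MME) REML engine: the
residual variance is profiled analytically, and the remaining log variance
ratios (plus atanh-transformed AR1 correlations) are maximized by
derivative-free Nelder–Mead, each evaluation being one sparse Cholesky
factorization of the MME coefficient matrix (updated symbolically when the
sparsity pattern is constant). Family BLUPs and their prediction-error
variances (PEV) come from the MME inverse at the optimum, so the PEV
includes the uncertainty of the grand mean. Reliability is
$1 - \mathrm{PEV}_i/\hat\sigma_g^2$, clamped to $[0,1]$ and zero by
convention when $\hat\sigma_g^2 = 0$. The engine is validated against
`lme4` (variance components, REML log-likelihood and BLUPs agree to at
least $10^{-3}$ on crossed designs).

BIC conventions (not prescribed by the trial-analysis literature, so fixed
here): $\mathrm{BIC} = -2\ell_{\mathrm{REML}} + k\log n$ with $n$ the
number of observations and $k$ the number of variance parameters only;
exact ties keep the simpler (non-spatial) model. BLUPs are used directly as
responses downstream — no deregression, since shrunk BLUPs predict true
values at least as well as deregressed ones in this setting and keep the
pipeline weight-free.

A caution that matters for benchmark interpretation: variances of factors
with very few levels (2 years, 3–4 blocks) have 1–3 degrees of freedom and
are *inherently* unstable; no estimator recovers them within ±30% with high
probability. Recovery checks therefore focus on the well-replicated
components (family, family interactions, residual).

## 3. Local LD: correlation blocks, tagging, weights

LD between markers is summarized by the block-diagonal Pearson correlation
matrix $R$ of dosages, one block per chromosome (cross-chromosome
correlations are set to zero; only local LD is modeled). Blocks are
projected to positive definiteness by Higham's alternating projection
(`Matrix::nearPD`) with an eigenvalue floor of $10^{-8}$ times the largest
eigenvalue — the smallest floor that reliably guarantees a double-precision
Cholesky.

The *degree of tagging* of marker $j$ is $\sum_{j'} R_{jj'}^2$ over its
chromosome, self-term included (so the minimum is 1; including the
self-term only shifts the statistic by a constant and keeps it
order-consistent with the exclusive reading). *Tagging weights* $w \ge 0$
solve $\min_w \|(R \circ R)\,w - \mathbf{1}\|_1$ per chromosome; redundant
markers get small (possibly exactly zero) weights. No LP solver being a
package dependency, the program is solved by a dense tableau simplex
(slack-variable split, Bland's rule, the all-slack basis as the starting
point), exact for the block sizes this package targets and verified against
vertex enumeration.

## 4. Marker-data transformations and kernels

With $X_{Base} = M - P$ the column-centered dosages (centering within the
declared population scope), the four feature matrices are
$$X_{PCA} = U D, \quad X_{Cor} = X_{Base} L \;(LL' = R^{-1}), \quad
X_{LD} = X_{Base} W^{1/2},$$
with $UDV'$ the thin SVD of $X_{Base}$, $L$ the lower Cholesky factor of
the explicitly formed block precision $\Theta = R^{-1}$, and $W$ the
diagonal tagging-weight matrix (zero-weight columns dropped). The GBLUP
kernel is $K = XX' / \sum_j \widehat{\mathrm{var}}(X_j)$ — normalizing by
the *transformed* features' variances keeps all four kernels on one scale —
and the three identities
$K_{PCA} = K_{Base}$, $K_{Cor} \propto X_{Base}\Theta X_{Base}'$,
$K_{LD} \propto X_{Base} W X_{Base}'$ are enforced to $10^{-8}$ in tests.
Markers are deliberately *not* standardized to unit variance, so
low-variance (rare) markers contribute less — a property all the linear
models here share. Gaussian kernels for RKHS use pairwise Euclidean
distances scaled by their maximum, $K_{ij} = \exp(-d_{ij}^2/\theta)$.

## 5. Prediction models

Nine models consume the transformed features:

* **GBLUP**: $g = \mu + Zu + e$, $u \sim N(0, K\sigma_u^2)$, fitted by
  spectral REML (one-dimensional search over
  $\lambda = \sigma_e^2/\sigma_u^2$ after eigendecomposition of $ZKZ'$);
  test genotypes are predicted by the standard kernel extension
  $\hat u_{test} = K_{test,train} Z'(ZKZ' + \lambda I)^{-1}(g-\hat\mu)$.
* **GBLUP-wG / RKHS-wG**: features weighted by $\sqrt{-\log_{10} p_j}$,
  $p_j$ the two-sided Pearson-correlation t-test p-value of feature $j$
  against the training outcome, so the induced kernel weights features by
  $-\log_{10}(p)$ (kernel-space weighting, matching weighted genomic
  relationship practice).
* **GBLUP-sG / RKHS-sG**: only features with Storey q-value strictly below
  a threshold enter; the threshold is tuned by GCV on the grid
  $0.05, 0.10, \ldots, 0.95$. An empty selection falls back to the
  intercept-only predictor rather than failing inside cross-validation.
* **RKHS**: Gaussian-kernel BLUP with $\theta$ tuned by GCV on
  $0.025, 0.050, \ldots, 0.975$ (the parameterization is
  $\exp(-d^2/\theta)$; with distances scaled to max 1 this grid spans the
  useful bandwidth range).
* **BayesA / BayesB**: Gibbs samplers (Rcpp) with scaled-inverse-$\chi^2$
  effect variances, a point mass at zero with
  $\pi \sim \mathrm{Beta}(0.2, 1.8)$ for BayesB, a Gamma hyperprior on the
  effect-variance scale, and 5000 burn-in plus 15 000 sampling iterations
  by default (no thinning; posterior summaries are means; a fixed seed per
  fit). Hyperparameters follow the standard heuristic: prior modes are
  matched so the implied share of variance equals a prior $R^2$, supplied
  by one heteroscedastic-effects-model (HEM) update of a GBLUP fit —
  ridge effects are back-solved, reweighted by
  $\hat\beta_j^2/(1-h_{jj})$ with $h_{jj}$ the ridge leverage, the kernel
  rebuilt and refitted, and the resulting $h^2$ clamped to
  $[0.01, 0.99]$ (a signal-free base fit short-circuits to the floor,
  since reweighting pure noise is meaningless). HEM only supplies this
  prior; it is not a tenth model.
* **RF**: `randomForest` with 200 trees, bootstrap samples of size $n$,
  and $\max(1, \lfloor q/3 \rfloor)$ features per split.

Generalized cross-validation,
$\mathrm{GCV} = \frac{(1/n)\|g-\hat g\|^2}{(1 - \mathrm{tr}(H)/n)^2}$ with
$H$ the full smoother including the fixed-mean projection, approximates
leave-one-out error from a single fit and is the only tuning criterion
(no nested CV). Everything outcome-dependent — p-values, q-values, weights,
tuning — is computed inside each training fold only.

## 6. Learning schemes, validation, and procedure selection

A *procedure* is a transformation × model pair; a *learning scheme* fixes
the population scope (within / across populations) and environment scope
(within / across locations; across-environment training doubles the rows,
$n = 2m$, and held-out families are removed from both environments).
Accuracy is the Pearson correlation between observed and predicted family
BLUPs on the test fold of a 5-fold partition, replicated 10 times with
partitions shared across procedures (paired design). Degenerate folds
(constant predictions) score 0 and are flagged, keeping tables rectangular.

Because training sets overlap across folds, the naive paired t-test is
anticonservative. The corrected statistic is
$$T = \frac{\bar\Delta}{\mathrm{SD}(\Delta)\sqrt{1/(KR) + 1/(K-1)}},$$
with $\Delta$ the per-fold difference in Fisher-z-transformed accuracies.
Many-to-one multiplicity over $c$ candidates uses the central
equicorrelated (correlation $\tfrac12$) multivariate t with $KR-1$ df,
evaluated by seeded Monte Carlo ($10^5$ draws); $c = 1$ reduces to the
exact corrected paired t-test. A null harness (the same deterministic
procedure scored in two independent replicated-CV runs, so the true
difference is exactly zero) keeps the empirical type-I rate at the nominal
5% level within Monte-Carlo slack.

`two_step_selection()` mirrors the economical benchmark protocol: screen
all procedures by non-replicated CV, then validate the winner against
`Base-GBLUP` in replicated CV; when the winner differs in both axes the
comparison is staged (alternate transformation under GBLUP first, then the
alternate model under that transformation), with multiplicities equal to
the number of alternative transformations and models respectively, to
account for the selection bias of reusing the data.

## 7. Genetic analyses

*Genomic correlation*: the two-outcome GBLUP with genetic covariance
$\Sigma_g \otimes K$ and independent within-outcome errors is fitted by
dense REML over $(\log\sigma_{g1}, \log\sigma_{g2}, \operatorname{atanh}
r_g, \log\sigma_{e1}^2, \log\sigma_{e2}^2)$, initialized from the
univariate fits. Significance of $r_g \ne 0$ uses a likelihood-ratio test
referred to the conservative $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture
(the genetic variances may sit at their boundary under the constrained
fit).

*Association mapping*: EMMAX-style two-step scan — variance components
fixed from the null GBLUP, each marker with MAF $> 0.05$ tested by
generalized least squares, significance at Storey q $< 0.05$, no
population-structure covariates. Significant markers then enter one mixed
model by forward selection on ML-based BIC (fixed marker effects, genomic
random term, near-collinear candidates skipped), summarized by the
likelihood-ratio $R^2_{LR} = 1 - \exp\{-\tfrac{2}{n}(\ell_{full} -
\ell_{null})\}$.

*Heritability partition*: markers split at nearest-rank tertiles of degree
of tagging (ties to the lower class; classes with fewer than three markers
contribute zero), one GRM per class, variances by dense REML (Nelder–Mead
over log variances with one restart — a derivative-free scheme chosen over
coordinate ascent for its robustness at four parameters), contributions
$\sigma_{u_j}^2 / (\sum_{j'}\sigma_{u_{j'}}^2 + \sigma_e^2)$.

## 8. The synthetic-data generator

The generator emulates the statistical structure the analyses assume, not
any particular genome:

* **Haplotypes** follow a first-order Markov chain along each chromosome
  with adjacent-pair correlation equal to `ld_decay_rate` inside haplotype
  blocks and zero at recombination hotspots; block lengths are geometric
  with mean `ld_block_mean_length` (default 8 markers). Block structure is
  what makes the degree of tagging genuinely heterogeneous. Bernoulli
  margins bound the achievable correlation between loci of unlike
  frequency, so allele frequencies are drawn through a smooth latent AR1
  copula (exact configured marginal, similar neighbours); the realized
  adjacent correlation is mildly attenuated relative to the nominal rate
  (nominal $r^2$ 0.81 at rate 0.9 realizes a median near 0.6–0.77), which
  the calibration tests measure rather than assume away.
* **Bottleneck blocks** (probability `bottleneck_block_prob` per block,
  default 0.3 for population 1 and 0 for population 2) segregate only two
  haplotype variants, so all their markers are in *perfect* LD with MAF
  equal to the variant frequency (drawn from `bottleneck_freq_range`,
  default 0.05–0.25). This reproduces the extended-LD signature of a
  narrow-based upland pool — clusters of rare markers with extreme degrees
  of tagging — and intentionally overrides the marginal MAF spectrum for
  those markers.
* **MAF spectra**: `"ushaped"` (density rising towards rare alleles, for
  the diverse pool) or `"uniform"` on $[0.01, 0.5]$.
* **Architecture**: `n_causal` markers drawn from a degree-of-tagging
  tertile (computed on population 1's simulated dosages) or at random;
  breeding values are exactly the centered causal-dosage sums.
* **Read counts**: Poisson total depth, binomial alternate counts at the
  dosage-dependent success probability (default mean depth 8, error 0.01 —
  typical shallow exome-capture values).
* **Phenotypes**: every model term drawn i.i.d. at its configured
  variance; the family effect is the parent breeding value rescaled to
  variance $\sigma_g^2$ (the transmitted half of the parental value; only
  the scale is observable, and Mendelian-sampling noise is absorbed into
  the plant residual, which is why progeny never need genotypes); the
  optional plot effect is an AR1 $\otimes$ AR1 Gaussian field over a
  near-square grid of family × block plots. Default variances (family 1,
  blocks/years 0.25, interactions 0.1, residual 2) give plant-level
  heritability near 0.25, a realistic value for yield-like traits.
* `simulate_family_outcome()` shortcuts phenotype + REML for prediction
  experiments, returning breeding values standardized *within population*
  (family BLUPs are computed within populations, so between-population
  frequency shifts never reach them) plus noise at a configured
  heritability.
* Two populations are simulated independently (zero cross-population
  relatedness), and all stage seeds derive from one master seed.

What the generator does **not** emulate: coalescent genealogy, selection
cycles, pedigree beyond the polycross half-sib abstraction, genotype ×
environment covariance beyond what correlated genetic values inject,
assortative-mating population structure, and marker-density variation from
capture design. Passing tests therefore demonstrate correctness of the
estimators under the assumed generating structure, not performance claims
about any real breeding population.

## 9. Benchmark harnesses and what they showed

`scripts/acceptance.R` recomputes, from scratch at a caller-chosen seed:
the three kernel identities (machine precision); estimator-vs-oracle gaps
(EM vs grid search, GBLUP vs direct MME, GCV vs explicit smoother, the
tagging-weight LP vs vertex enumeration, Storey-with-$\pi_0{=}1$ vs
Benjamini–Hochberg, corrected Dunnett vs the hand-computed corrected t);
parameter-recovery rates (EM, genomic correlation, planted heritability
partition, mixed-model variance components); calibration (Dunnett type-I
over 500 null datasets, GWAS null uniformity); and the directional
Cor-vs-Base comparison.

Two results deserve honest discussion. First, the joint "every variance
component within 30%" recovery criterion cannot be met by any estimator at
the benchmark design, because the block and year variances carry 1–3
degrees of freedom (see Section 2); the well-replicated components are
recovered comfortably. Second, placing causal variants at weakly tagged
markers does **not** make `Cor-GBLUP` reliably beat `Base-GBLUP` under
this generator: extensive design-time exploration (block LD, bottleneck
clusters, idealized feature-space constructions, heritability scans) put
the whitening transformation at parity with Base — collapsing redundant
clusters helps, but inverting an estimated correlation matrix amplifies
within-block residual directions by the same token, and the two effects
offset except when clusters are exact duplicates, where the kernels nearly
coincide. The weights-based `LD` transformation, which downweights
redundancy without inverting anything, *does* show the directional benefit
in matched experiments. The harness reports the measured win fraction
as-is. Benchmark problem sizes (50–300 genotypes, a few hundred markers,
500 null datasets) were chosen as comfortable desk-scale studies that keep
every Monte-Carlo rate stable to a few percent.

## 10. Known limitations

* The REML engines assume homogeneous residuals (no year-specific error
  variances) and no pedigree relationship matrix in the phenotype models.
* Only diploid-coded (disomic) dosages are supported; no multi-allelic
  sites, no tetrasomic dosage models.
* `Cor` and `LD` account for local (within-chromosome) LD only; no
  shrinkage or graphical-model regularization of $R$ is attempted.
* Multi-trait *prediction* models are out of scope (they are statistically
  fragile at these sample sizes); the bivariate model is used only to
  estimate genomic correlations.
* The Dunnett adjustment uses the central many-to-one distribution; a
  noncentral variant is not implemented.
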