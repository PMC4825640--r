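#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the Bayesian linear regressions g = mu + X b + e with
// per-feature effect variances: BayesA puts a scaled-inverse-chi-square
// prior on every sigma2_bj; BayesB adds a point mass at zero with mixing
// probability pi ~ Beta(pi_a, pi_b).  The effect-variance scale S_b2
// carries a Gamma(r_b, rate s_b) hyperprior; the residual variance a
// scaled-inverse-chi-square(df_e, S_e2).  Uses R's RNG so set.seed()
// controls the chain.

static double rscaled_inv_chisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".bayes_gibbs")]]
List bayes_gibbs(NumericVector g, NumericMatrix X, bool variant_b,
                 double df_b, double r_b, double s_b, double df_e,
                 double S_e2, double pi_a, double pi_b,
                 int burn_in, int n_iter, int thin) {
  const int n = g.size(), q = X.ncol();
  const int total = burn_in + n_iter;
  std::vector<double> xtx(q);
  for (int j = 0; j < q; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = mean(g);
  std::vector<double> b(q, 0.0), s2b(q);
  double S_b2 = r_b / s_b;  // prior mean of the Gamma hyperprior
  for (int j = 0; j < q; ++j) s2b[j] = rscaled_inv_chisq(df_b, S_b2);
  std::vector<int> delta(q, 1);
  double pi = pi_a / (pi_a + pi_b);
  double sigma_e2 = S_e2;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = g[i] - mu;

  std::vector<double> b_sum(q, 0.0), incl_sum(q, 0.0);
  double mu_sum = 0.0, se2_sum = 0.0, sb2_sum = 0.0, pi_sum = 0.0;
  int n_kept = 0;

  for (int it = 0; it < total; ++it) {
    // mu | rest  ~  N(mu + mean(e), sigma_e2 / n)
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double shift = ebar + R::norm_rand() * std::sqrt(sigma_e2 / n);
    mu += shift;
    for (int i = 0; i < n; ++i) e[i] -= shift;

    // effects
    for (int j = 0; j < q; ++j) {
      if (xtx[j] <= 0.0) { b[j] = 0.0; continue; }
      // residual with b_j removed
      double xe = 0.0;
      if (b[j] != 0.0) {
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * b[j];
      }
      for (int i = 0; i < n; ++i) xe += X(i, j) * e[i];
      bool include = true;
      if (variant_b) {
        // integrate b_j out of the inclusion odds
        double v1 = xtx[j] * s2b[j] + sigma_e2;
        double log_or = std::log(1.0 - pi) - std::log(pi)
          - 0.5 * std::log(v1 / sigma_e2)
          + 0.5 * xe * xe * s2b[j] / (sigma_e2 * v1);
        double p_in = 1.0 / (1.0 + std::exp(-log_or));
        include = (R::unif_rand() < p_in);
      }
      if (include) {
        double cj = xtx[j] + sigma_e2 / s2b[j];
        double mean_j = xe / cj;
        b[j] = mean_j + R::norm_rand() * std::sqrt(sigma_e2 / cj);
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * b[j];
        delta[j] = 1;
      } else {
        b[j] = 0.0;
        delta[j] = 0;
      }
    }

    // per-feature effect variances
    double sum_inv = 0.0;
    for (int j = 0; j < q; ++j) {
      if (!variant_b || delta[j] == 1) {
        s2b[j] = rscaled_inv_chisq(df_b + 1.0,
                                   (df_b * S_b2 + b[j] * b[j]) / (df_b + 1.0));
      } else {
        s2b[j] = rscaled_inv_chisq(df_b, S_b2);  // from the prior
      }
      sum_inv += 1.0 / s2b[j];
    }

    // S_b2 | s2b  ~ Gamma(r_b + q df_b / 2, rate s_b + (df_b/2) sum 1/s2b)
    S_b2 = R::rgamma(r_b + 0.5 * q * df_b, 1.0 / (s_b + 0.5 * df_b * sum_inv));

    // pi (probability of exclusion) for BayesB
    if (variant_b) {
      int n_in = 0;
      for (int j = 0; j < q; ++j) n_in += delta[j];
      pi = R::rbeta(pi_a + (q - n_in), pi_b + n_in);
    }

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e2 = rscaled_inv_chisq(df_e + n, (df_e * S_e2 + sse) / (df_e + n));

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      mu_sum += mu;
      se2_sum += sigma_e2;
      sb2_sum += S_b2;
      pi_sum += pi;
      for (int j = 0; j < q; ++j) {
        b_sum[j] += b[j];
        incl_sum[j] += delta[j];
      }
    }
  }

  NumericVector b_mean(q), incl(q);
  for (int j = 0; j < q; ++j) {
    b_mean[j] = b_sum[j] / n_kept;
    incl[j] = incl_sum[j] / n_kept;
  }
  return List::create(_["mu"] = mu_sum / n_kept,
                      _["b"] = b_mean,
                      _["sigma_e2"] = se2_sum / n_kept,
                      _["S_b2"] = sb2_sum / n_kept,
                      _["pi"] = pi_sum / n_kept,
                      _["inclusion"] = incl,
                      _["n_kept"] = n_kept);
}
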