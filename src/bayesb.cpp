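#include <Rcpp.h>
using namespace Rcpp;

// Scaled inverse chi-square draw: nu * S / chisq(nu)
static inline double rsinvchisq(double nu, double S) {
  return nu * S / R::rchisq(nu);
}

// Bayes-B single-trait Gibbs sampler.
//
// Model: y = W b + sum_j x_j a_j delta_j + e, with
//   b           flat prior (contemporary-group fixed effects)
//   delta_j     ~ Bernoulli(1 - pi)
//   a_j|s2_j    ~ N(0, s2_j)
//   s2_j        ~ scaled-inv-chisq(nu, scale)
//   var(e)      ~ scaled-inv-chisq(nu_e, scale_e)
//
// X must be column-centered; grp is a 0-based group index per individual.
// delta_j and a_j are updated jointly: delta_j from its full conditional
// with a_j integrated out, then a_j | delta_j = 1 from its normal full
// conditional. Uses R's RNG, so results are reproducible via set.seed().
//
// [[Rcpp::export]]
List bayesb_mcmc(NumericMatrix X, NumericVector y, IntegerVector grp,
                 int ngrp, double pi0, double nu, double scale,
                 double nu_e, double scale_e,
                 int burn_in, int chain_length, int thin) {
  const int n = X.nrow(), m = X.ncol();
  const int n_iter = burn_in + chain_length;
  const int n_store = chain_length / thin;

  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    const double *xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  std::vector<double> a(m, 0.0), s2(m, scale);
  std::vector<int> delta(m, 0);
  std::vector<double> b(ngrp, 0.0);
  std::vector<int> grp_n(ngrp, 0);
  for (int i = 0; i < n; ++i) grp_n[grp[i]]++;

  // initialize fixed effects at group means, residuals at deviations
  std::vector<double> e(n);
  {
    std::vector<double> gsum(ngrp, 0.0);
    for (int i = 0; i < n; ++i) gsum[grp[i]] += y[i];
    for (int g = 0; g < ngrp; ++g) b[g] = gsum[g] / grp_n[g];
    for (int i = 0; i < n; ++i) e[i] = y[i] - b[grp[i]];
  }
  double vare = 0.0;
  for (int i = 0; i < n; ++i) vare += e[i] * e[i];
  vare = std::max(vare / n, 1e-8);

  NumericVector a_mean(m), incl(m), b_mean(ngrp);
  NumericMatrix samples(m, n_store);
  NumericVector vare_samples(n_store);
  int stored = 0;

  const double log_prior_odds =
    (pi0 <= 0.0) ? R_PosInf : std::log(1.0 - pi0) - std::log(pi0);

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- contemporary-group effects (flat prior) ---
    std::vector<double> gsum(ngrp, 0.0);
    for (int i = 0; i < n; ++i) gsum[grp[i]] += e[i] + b[grp[i]];
    for (int g = 0; g < ngrp; ++g) {
      double b_new = gsum[g] / grp_n[g] + R::norm_rand() * std::sqrt(vare / grp_n[g]);
      gsum[g] = b_new - b[g];  // reuse as delta for residual update
      b[g] = b_new;
    }
    for (int i = 0; i < n; ++i) e[i] -= gsum[grp[i]];

    // --- SNP effects ---
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) continue;  // monomorphic locus carries no signal
      const double *xj = &X(0, j);
      double rhs = xtx[j] * a[j];
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      const double v0 = xtx[j] * vare;
      const double v1 = v0 + xtx[j] * xtx[j] * s2[j];
      const double log_bf = -0.5 * (std::log(v1) - std::log(v0))
                            - 0.5 * rhs * rhs * (1.0 / v1 - 1.0 / v0);
      double p1;
      if (log_prior_odds == R_PosInf) p1 = 1.0;
      else p1 = 1.0 / (1.0 + std::exp(-(log_prior_odds + log_bf)));

      const double a_old = a[j];
      double a_new = 0.0;
      if (unif_rand() < p1) {
        delta[j] = 1;
        const double prec = xtx[j] + vare / s2[j];
        a_new = rhs / prec + R::norm_rand() * std::sqrt(vare / prec);
      } else {
        delta[j] = 0;
      }
      if (a_new != a_old) {
        const double d = a_new - a_old;
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * d;
        a[j] = a_new;
      }
      // locus variance: full conditional when in the model, prior draw otherwise
      if (delta[j]) s2[j] = rsinvchisq(nu + 1.0, (nu * scale + a[j] * a[j]) / (nu + 1.0));
      else          s2[j] = rsinvchisq(nu, scale);
    }

    // --- residual variance ---
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    vare = rsinvchisq(nu_e + n, (sse + nu_e * scale_e) / (nu_e + n));

    if (iter >= burn_in) {
      for (int j = 0; j < m; ++j) {
        a_mean[j] += a[j];
        incl[j] += delta[j];
      }
      for (int g = 0; g < ngrp; ++g) b_mean[g] += b[g];
      int post = iter - burn_in;
      if (post % thin == 0 && stored < n_store) {
        for (int j = 0; j < m; ++j) samples(j, stored) = a[j];
        vare_samples[stored] = vare;
        ++stored;
      }
    }
  }

  for (int j = 0; j < m; ++j) {
    a_mean[j] /= chain_length;
    incl[j] /= chain_length;
  }
  for (int g = 0; g < ngrp; ++g) b_mean[g] /= chain_length;

  return List::create(_["effect_mean"] = a_mean,
                      _["inclusion_freq"] = incl,
                      _["group_mean"] = b_mean,
                      _["samples"] = samples,
                      _["vare_samples"] = vare_samples);
}
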