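// BayesC-pi Gibbs sampler with additive and optional dominance marker
// effects and site-heterogeneous residual variances.  Uses R's RNG so a
// set.seed() call on the R side makes runs bit-reproducible.
#include <Rcpp.h>
using namespace Rcpp;

static double sample_scaled_inv_chisq(double df, double scale_sum) {
  // scale_sum = df0*S0 + sum of squares; df = df0 + n
  return scale_sum / R::rchisq(df);
}

// One spike-and-slab block update: markers in Z (n x m, centred), effects
// alpha, inclusion indicators delta, slab variance var_eff, inclusion
// probability pi.  The indicator and effect are updated jointly from the
// marginalized likelihood ratio.  e is the running residual.
static int update_marker_block(const NumericMatrix& Z, NumericVector& alpha,
                               IntegerVector& delta, NumericVector& e,
                               const NumericVector& w, double var_eff,
                               double pi) {
  const int n = Z.nrow(), m = Z.ncol();
  int n_in = 0;
  const double logit_pi = std::log(pi) - std::log1p(-pi);
  for (int j = 0; j < m; ++j) {
    const double* zj = &Z(0, j);
    if (delta[j] == 1) {
      const double aj = alpha[j];
      for (int i = 0; i < n; ++i) e[i] += zj[i] * aj;
    }
    double C = 1.0 / var_eff, rhs = 0.0;
    for (int i = 0; i < n; ++i) {
      const double wz = w[i] * zj[i];
      C += wz * zj[i];
      rhs += wz * e[i];
    }
    const double lr = logit_pi + 0.5 * rhs * rhs / C -
      0.5 * std::log(var_eff * C);
    const double p_in = 1.0 / (1.0 + std::exp(-lr));
    if (R::unif_rand() < p_in) {
      const double aj = rhs / C + R::norm_rand() / std::sqrt(C);
      alpha[j] = aj;
      delta[j] = 1;
      for (int i = 0; i < n; ++i) e[i] -= zj[i] * aj;
      ++n_in;
    } else {
      alpha[j] = 0.0;
      delta[j] = 0;
    }
  }
  return n_in;
}

// [[Rcpp::export(name = ".bayescpi_gibbs")]]
List bayescpi_gibbs(NumericVector y, NumericMatrix X, NumericMatrix Z1,
                    NumericMatrix Z2, IntegerVector site, int n_site,
                    int n_iter, int burn_in, int thin,
                    double df0, double S0_a, double S0_d,
                    double p0, double pi0,
                    double df_e, double Se,
                    double fix_pi, double fix_var) {
  const int n = y.size(), p = X.ncol(), m = Z1.ncol();
  const bool has_dom = Z2.ncol() > 0;
  const int md = Z2.ncol();
  RNGScope scope;

  NumericVector beta(p), alpha(m), dom(md);
  IntegerVector delta_a(m), delta_d(md);
  NumericVector ve(n_site, Se);
  double var_a = S0_a, var_d = S0_d;
  double pi_a = pi0, pi_d = pi0;
  const bool pi_fixed = fix_pi > 0.0;
  const bool var_fixed = fix_var > 0.0;
  if (pi_fixed) { pi_a = std::min(fix_pi, 1.0 - 1e-9); pi_d = pi_a; }
  if (var_fixed) { var_a = fix_var; var_d = fix_var; }
  NumericVector e = clone(y);

  NumericVector w(n);
  IntegerVector n_by_site(n_site);
  for (int i = 0; i < n; ++i) n_by_site[site[i]]++;

  // accumulators
  NumericVector sum_alpha(m), sum_dom(md), sum_beta(p);
  NumericVector freq_a(m), freq_d(md), sum_ve(n_site);
  double sum_pia = 0, sum_pid = 0, sum_va = 0, sum_vd = 0;
  int n_keep = (n_iter - burn_in) / thin;
  int n_mon = 2 + n_site + (has_dom ? 2 : 0);
  NumericMatrix trace(n_keep, n_mon);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int i = 0; i < n; ++i) w[i] = 1.0 / ve[site[i]];
    // fixed effects, flat prior
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      const double bj_old = beta[j];
      double C = 0.0, rhs = 0.0;
      for (int i = 0; i < n; ++i) {
        e[i] += xj[i] * bj_old;
        const double wx = w[i] * xj[i];
        C += wx * xj[i];
        rhs += wx * e[i];
      }
      const double bj = rhs / C + R::norm_rand() / std::sqrt(C);
      beta[j] = bj;
      for (int i = 0; i < n; ++i) e[i] -= xj[i] * bj;
    }
    // marker effects
    int in_a = update_marker_block(Z1, alpha, delta_a, e, w, var_a, pi_a);
    int in_d = 0;
    if (has_dom) {
      in_d = update_marker_block(Z2, dom, delta_d, e, w, var_d, pi_d);
    }
    // slab variances (scaled inverse chi-square)
    if (!var_fixed) {
      double ssq_a = df0 * S0_a;
      for (int j = 0; j < m; ++j) if (delta_a[j]) ssq_a += alpha[j] * alpha[j];
      var_a = sample_scaled_inv_chisq(df0 + in_a, ssq_a);
      if (has_dom) {
        double ssq_d = df0 * S0_d;
        for (int j = 0; j < md; ++j) if (delta_d[j]) ssq_d += dom[j] * dom[j];
        var_d = sample_scaled_inv_chisq(df0 + in_d, ssq_d);
      }
    }
    // inclusion proportions, Beta(p0*pi0, p0*(1-pi0)) prior
    if (!pi_fixed) {
      pi_a = R::rbeta(p0 * pi0 + in_a, p0 * (1.0 - pi0) + m - in_a);
      pi_a = std::min(std::max(pi_a, 1e-6), 1.0 - 1e-6);
      if (has_dom) {
        pi_d = R::rbeta(p0 * pi0 + in_d, p0 * (1.0 - pi0) + md - in_d);
        pi_d = std::min(std::max(pi_d, 1e-6), 1.0 - 1e-6);
      }
    }
    // per-site residual variances
    {
      std::vector<double> ssq(n_site, 0.0);
      for (int i = 0; i < n; ++i) ssq[site[i]] += e[i] * e[i];
      for (int s = 0; s < n_site; ++s) {
        ve[s] = sample_scaled_inv_chisq(df_e + n_by_site[s],
                                        df_e * Se + ssq[s]);
      }
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < m; ++j) {
        sum_alpha[j] += alpha[j];
        freq_a[j] += delta_a[j];
      }
      for (int j = 0; j < md; ++j) {
        sum_dom[j] += dom[j];
        freq_d[j] += delta_d[j];
      }
      for (int j = 0; j < p; ++j) sum_beta[j] += beta[j];
      for (int s = 0; s < n_site; ++s) sum_ve[s] += ve[s];
      sum_pia += pi_a; sum_pid += pi_d;
      sum_va += var_a; sum_vd += var_d;
      int c = 0;
      trace(kept, c++) = pi_a;
      trace(kept, c++) = var_a;
      if (has_dom) { trace(kept, c++) = pi_d; trace(kept, c++) = var_d; }
      for (int s = 0; s < n_site; ++s) trace(kept, c++) = ve[s];
      ++kept;
    }
  }
  const double inv = 1.0 / std::max(kept, 1);
  return List::create(
    _["a_hat"] = sum_alpha * inv,
    _["d_hat"] = sum_dom * inv,
    _["beta_hat"] = sum_beta * inv,
    _["inclusion_a"] = freq_a * inv,
    _["inclusion_d"] = freq_d * inv,
    _["pi_hat_a"] = sum_pia * inv,
    _["pi_hat_d"] = has_dom ? sum_pid * inv : NA_REAL,
    _["var_a_hat"] = sum_va * inv,
    _["var_d_hat"] = has_dom ? sum_vd * inv : NA_REAL,
    _["ve_hat"] = sum_ve * inv,
    _["trace"] = trace,
    _["n_samples"] = kept);
}
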