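// Gibbs sampler for the Bayes-C-pi marker model
//   y = 1 mu + ZA (delta_a * a) + ZD (delta_d * d) + e
// with per-class inclusion indicators delta_g ~ Bernoulli(1 - pi_g),
// uniform(0,1) prior on pi_g (beta full conditional), scaled-inverse-
// chi-square priors on the effect and residual variances.
// Uses R's RNG so seeded chains are bitwise reproducible from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// one effect class sweep: updates eff, delta, residual e in place;
// returns number of included markers
static int sweep_class(const arma::mat &Z, const arma::vec &zz,
                       arma::vec &eff, arma::ivec &delta, arma::vec &e,
                       double s2_eff, double s2_e, double pi_g) {
  const int m = Z.n_cols;
  int k = 0;
  double log_prior_odds = (pi_g <= 0.0) ? R_PosInf
                        : (pi_g >= 1.0) ? R_NegInf
                        : std::log1p(-pi_g) - std::log(pi_g);
  const double lambda = s2_e / s2_eff;
  for (int j = 0; j < m; ++j) {
    if (zz[j] <= 0.0) { eff[j] = 0.0; delta[j] = 0; continue; }
    double w = delta[j] ? eff[j] : 0.0;
    // rhs = Z_j' (e + Z_j w)
    double rhs = arma::dot(Z.col(j), e) + zz[j] * w;
    double C = zz[j] + lambda;
    int incl;
    if (pi_g <= 0.0) incl = 1;
    else if (pi_g >= 1.0) incl = 0;
    else {
      double log_bf = 0.5 * (std::log(lambda) - std::log(C)) +
                      rhs * rhs / (2.0 * s2_e * C);
      double lo = log_prior_odds + log_bf;
      double p1 = 1.0 / (1.0 + std::exp(-lo));
      incl = (R::unif_rand() < p1) ? 1 : 0;
    }
    double a_new = 0.0;
    if (incl) {
      a_new = rhs / C + R::norm_rand() * std::sqrt(s2_e / C);
      ++k;
    }
    // residual update: e := e + Z_j (w - a_new)
    double diff = w - a_new;
    if (diff != 0.0) e += Z.col(j) * diff;
    eff[j] = a_new;
    delta[j] = incl;
  }
  return k;
}

// [[Rcpp::export(name = ".bayescpi_gibbs")]]
List bayescpi_gibbs(const arma::vec &y, const arma::mat &ZA,
                    const arma::mat &ZD, bool use_dom,
                    int n_iter, int burn_in, int thin,
                    double fix_pi_a, double fix_pi_d,
                    double nu, double S_a, double S_d, double S_e,
                    double nu_e) {
  RNGScope scope;
  const int n = y.n_elem, m = ZA.n_cols;
  arma::vec zzA(m), zzD(m, arma::fill::zeros);
  for (int j = 0; j < m; ++j) zzA[j] = arma::dot(ZA.col(j), ZA.col(j));
  if (use_dom)
    for (int j = 0; j < m; ++j) zzD[j] = arma::dot(ZD.col(j), ZD.col(j));

  double mu = arma::mean(y);
  arma::vec a(m, arma::fill::zeros), d(m, arma::fill::zeros);
  arma::ivec da(m, arma::fill::ones), dd(m, arma::fill::ones);
  double pi_a = (fix_pi_a >= 0.0) ? fix_pi_a : 0.5;
  double pi_d = (fix_pi_d >= 0.0) ? fix_pi_d : 0.5;
  double s2_a = S_a, s2_d = S_d, s2_e = S_e;
  arma::vec e = y - mu;

  arma::vec sum_a(m, arma::fill::zeros), sum_d(m, arma::fill::zeros);
  arma::vec sum_da(m, arma::fill::zeros), sum_dd(m, arma::fill::zeros);
  double sum_mu = 0, sum_pia = 0, sum_pid = 0;
  double sum_s2a = 0, sum_s2d = 0, sum_s2e = 0;
  int n_kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    double r_mean = arma::mean(e) + mu;
    double mu_new = r_mean + R::norm_rand() * std::sqrt(s2_e / n);
    e += mu - mu_new;
    mu = mu_new;

    int ka = sweep_class(ZA, zzA, a, da, e, s2_a, s2_e, pi_a);
    int kd = 0;
    if (use_dom) kd = sweep_class(ZD, zzD, d, dd, e, s2_d, s2_e, pi_d);

    if (fix_pi_a < 0.0) pi_a = R::rbeta(m - ka + 1.0, ka + 1.0);
    if (use_dom && fix_pi_d < 0.0) pi_d = R::rbeta(m - kd + 1.0, kd + 1.0);

    double ssa = arma::dot(a, a);
    s2_a = rinvchisq(nu + ka, (nu * S_a + ssa) / (nu + ka));
    if (use_dom) {
      double ssd = arma::dot(d, d);
      s2_d = rinvchisq(nu + kd, (nu * S_d + ssd) / (nu + kd));
    }
    double sse = arma::dot(e, e);
    if (!std::isfinite(sse))
      stop("non-finite residual sum of squares at iteration %d", it);
    s2_e = rinvchisq(nu_e + n, (nu_e * S_e + sse) / (nu_e + n));

    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      sum_mu += mu;
      sum_pia += pi_a; sum_pid += pi_d;
      sum_s2a += s2_a; sum_s2d += s2_d; sum_s2e += s2_e;
      for (int j = 0; j < m; ++j) {
        sum_a[j] += a[j];
        sum_da[j] += da[j];
        if (use_dom) { sum_d[j] += d[j]; sum_dd[j] += dd[j]; }
      }
    }
  }
  if (n_kept == 0) stop("no posterior samples kept");
  double inv = 1.0 / n_kept;
  return List::create(
      _["mu"] = sum_mu * inv,
      _["additive"] = NumericVector(wrap(sum_a * inv)),
      _["dominance"] = NumericVector(wrap(sum_d * inv)),
      _["incl_additive"] = NumericVector(wrap(sum_da * inv)),
      _["incl_dominance"] = NumericVector(wrap(sum_dd * inv)),
      _["pi_a"] = sum_pia * inv, _["pi_d"] = sum_pid * inv,
      _["sigma2_a"] = sum_s2a * inv, _["sigma2_d"] = sum_s2d * inv,
      _["sigma2_e"] = sum_s2e * inv, _["n_samples"] = n_kept);
}
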