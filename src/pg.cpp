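#include <Rcpp.h>
using namespace Rcpp;

// Devroye-type sampler for Polya-Gamma PG(1, z) (Polson, Scott & Windle 2013).
// Uses R's RNG so draws are reproducible under set.seed().

static const double TRUNC = 0.64;

// piecewise coefficients a_n(x) of the Jacobi-theta alternating series
static double a_coef(int n, double x) {
  double d = n + 0.5;
  if (x > TRUNC) {
    return M_PI * d * std::exp(-d * d * M_PI * M_PI * x / 2.0);
  }
  return M_PI * d * std::pow(2.0 / (M_PI * x), 1.5) * std::exp(-2.0 * d * d / x);
}

// CDF at t of inverse-Gaussian(mu = 1/z, lambda = 1); z = 0 is the Levy limit
static double pigauss(double t, double z) {
  double s = 1.0 / std::sqrt(t);
  if (z <= 0.0) return 2.0 * R::pnorm(-s, 0.0, 1.0, 1, 0);
  double a = R::pnorm(s * (t * z - 1.0), 0.0, 1.0, 1, 0);
  // exp(2z) * pnorm(...) computed in logs to dodge overflow
  double lb = 2.0 * z + R::pnorm(-s * (t * z + 1.0), 0.0, 1.0, 1, 1);
  return a + std::exp(lb);
}

// inverse-Gaussian(1/z, 1) truncated to (0, t)
static double rtigauss(double z, double t) {
  double x;
  if (1.0 / z > t) { // heavy truncation: rejection from truncated Levy
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-z * z * x / 2.0)) return x;
    }
  }
  double mu = 1.0 / z;
  for (;;) {
    double y = R::norm_rand();
    y = y * y;
    x = mu + 0.5 * mu * mu * y -
        0.5 * mu * std::sqrt(4.0 * mu * y + mu * mu * y * y);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x <= t) return x;
  }
}

static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double x;
    if (R::unif_rand() < p / (p + q)) {
      x = TRUNC + R::exp_rand() / K; // exponential tail above t
    } else {
      x = rtigauss(z, TRUNC);
    }
    // alternating-series accept/reject
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

// Bernoulli log-likelihood sum(log sigmoid(ysign * (eta_base + delta * g)))
// in one fused pass; used by the slice sampler over random-effect scales.
// [[Rcpp::export(name = ".bern_loglik_delta")]]
double bern_loglik_delta(NumericVector eta_base, NumericVector g,
                         double delta, NumericVector ysign) {
  R_xlen_t n = eta_base.size();
  double s = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double t = ysign[i] * (eta_base[i] + delta * g[i]);
    s += (t > 0) ? -std::log1p(std::exp(-t)) : t - std::log1p(std::exp(t));
  }
  return s;
}

//' @title Polya-Gamma PG(1, z) draws
//' @description One draw per element of `z`, using R's RNG stream.
//' @param z numeric vector of tilting parameters.
//' @return numeric vector of PG(1, z) variates.
//' @keywords internal
// [[Rcpp::export(name = ".rpg1_vec")]]
NumericVector rpg1_vec(NumericVector z) {
  R_xlen_t n = z.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}
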