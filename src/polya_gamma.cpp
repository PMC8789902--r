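// Exact Polya-Gamma PG(1, z) sampling by the alternating-series rejection
// method of Devroye, as used for logistic data augmentation.  Draws consume
// R's RNG stream so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;  // series crossover point for J*(1, z)

// Coefficients a_n(x) of the alternating series for the J*(1) density,
// using the left (small-x) or right (large-x) expansion.
static double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > TRUNC) {
    return M_PI * np5 * std::exp(-0.5 * np5 * np5 * M_PI * M_PI * x);
  }
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * np5 *
         std::exp(-2.0 * np5 * np5 / x);
}

// P(pick the truncated-exponential right tail) for the two-piece proposal.
static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);

  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);

  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse-Gaussian(1/z, 1) truncated to (0, TRUNC).
static double rtigauss(double z) {
  double t = TRUNC;
  double x = t + 1.0;
  if (1.0 / z > t) {
    // heavy truncation: rejection from a truncated chi-square proposal
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1 = exp_rand(), e2 = exp_rand();
      while (e1 * e1 > 2.0 * e2 / t) {
        e1 = exp_rand();
        e2 = exp_rand();
      }
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = norm_rand();
      y *= y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

static double sample_pg1(double zin) {
  double z = 0.5 * std::fabs(zin);
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;

  for (;;) {
    double x;
    if (unif_rand() < mass_texpon(z)) {
      x = TRUNC + exp_rand() / fz;  // truncated exponential on (t, Inf)
    } else {
      x = rtigauss(z);  // truncated inverse-Gaussian on (0, t)
    }
    // squeeze accept/reject on the alternating series
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

//' Draw Polya-Gamma PG(1, z) variates
//'
//' One exact draw per element of `z`, consuming R's RNG stream.
//'
//' @param z numeric vector of tilting parameters (the logistic linear
//'   predictors); `PG(1, 0)` is the untilted case.
//' @return numeric vector of the same length as `z`.
//' @export
// [[Rcpp::export]]
NumericVector rpolyagamma(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) out[i] = sample_pg1(z[i]);
  return out;
}
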