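#include <Rcpp.h>
using namespace Rcpp;

// Two-state introgression HMM (state 0 = modern human, 1 = archaic) over a
// shared site grid.  Transitions follow the pulse-admixture model with
// per-interval genetic distance d (Morgans):
//   P(0->1) = alpha (1 - exp(-T d)),  P(1->0) = (1 - alpha)(1 - exp(-T d)).
// Observations are the four per-site marker states (1..4).  All routines
// use scaled forward-backward, so likelihoods are returned in log space.

static inline void trans(double alpha, double T, double d,
                         double &a00, double &a01, double &a10, double &a11) {
  double q = 1.0 - std::exp(-T * d);
  a01 = alpha * q;
  a10 = (1.0 - alpha) * q;
  a00 = 1.0 - a01;
  a11 = 1.0 - a10;
}

// Pooled E-step over all test haplotypes.
// obs: nsites x nhap integer matrix (values 1..4); d: nsites-1 distances.
// Returns pooled expected emission counts (2x4), pooled expected transition
// posteriors per interval (nsites-1 x 4, columns 00,01,10,11), the summed
// archaic posterior per haplotype-site total, and the pooled log-likelihood.
// [[Rcpp::export(name = ".hmm_estep")]]
List hmm_estep(IntegerMatrix obs, NumericVector d, NumericMatrix e,
               double alpha, double T) {
  const int n = obs.nrow(), H = obs.ncol();
  if (e.nrow() != 2 || e.ncol() != 4) stop("emission matrix must be 2x4");
  if (n < 1) stop("no sites");
  if (d.size() != n - 1) stop("distance vector length mismatch");

  NumericMatrix counts(2, 4);
  NumericMatrix xi(std::max(n - 1, 0), 4);
  double gamma1_sum = 0.0, loglik = 0.0;

  std::vector<double> a00(n - 1), a01(n - 1), a10(n - 1), a11(n - 1);
  for (int i = 0; i < n - 1; ++i)
    trans(alpha, T, d[i], a00[i], a01[i], a10[i], a11[i]);

  std::vector<double> f0(n), f1(n), b0(n), b1(n), sc(n);

  for (int h = 0; h < H; ++h) {
    // forward with scaling
    int o = obs(0, h) - 1;
    f0[0] = (1.0 - alpha) * e(0, o);
    f1[0] = alpha * e(1, o);
    sc[0] = f0[0] + f1[0];
    f0[0] /= sc[0]; f1[0] /= sc[0];
    for (int i = 1; i < n; ++i) {
      o = obs(i, h) - 1;
      double p0 = (f0[i-1] * a00[i-1] + f1[i-1] * a10[i-1]) * e(0, o);
      double p1 = (f0[i-1] * a01[i-1] + f1[i-1] * a11[i-1]) * e(1, o);
      sc[i] = p0 + p1;
      if (sc[i] <= 0) stop("numerical underflow in forward pass");
      f0[i] = p0 / sc[i]; f1[i] = p1 / sc[i];
    }
    for (int i = 0; i < n; ++i) loglik += std::log(sc[i]);
    // backward with the same scale factors
    b0[n-1] = 1.0; b1[n-1] = 1.0;
    for (int i = n - 2; i >= 0; --i) {
      o = obs(i + 1, h) - 1;
      double e0 = e(0, o), e1 = e(1, o);
      b0[i] = (a00[i] * e0 * b0[i+1] + a01[i] * e1 * b1[i+1]) / sc[i+1];
      b1[i] = (a10[i] * e0 * b0[i+1] + a11[i] * e1 * b1[i+1]) / sc[i+1];
    }
    // posteriors and pooled sufficient statistics
    for (int i = 0; i < n; ++i) {
      double g0 = f0[i] * b0[i], g1 = f1[i] * b1[i];
      double s = g0 + g1;
      g0 /= s; g1 /= s;
      o = obs(i, h) - 1;
      counts(0, o) += g0;
      counts(1, o) += g1;
      gamma1_sum += g1;
    }
    for (int i = 0; i < n - 1; ++i) {
      o = obs(i + 1, h) - 1;
      double e0 = e(0, o), e1 = e(1, o);
      double x00 = f0[i] * a00[i] * e0 * b0[i+1] / sc[i+1];
      double x01 = f0[i] * a01[i] * e1 * b1[i+1] / sc[i+1];
      double x10 = f1[i] * a10[i] * e0 * b0[i+1] / sc[i+1];
      double x11 = f1[i] * a11[i] * e1 * b1[i+1] / sc[i+1];
      double s = x00 + x01 + x10 + x11;
      xi(i, 0) += x00 / s; xi(i, 1) += x01 / s;
      xi(i, 2) += x10 / s; xi(i, 3) += x11 / s;
    }
  }
  return List::create(_["loglik"] = loglik, _["counts"] = counts,
                      _["xi"] = xi, _["gamma1_sum"] = gamma1_sum,
                      _["n_total"] = (double)n * H);
}

// Posterior decoding for one haplotype: returns nsites x 2 matrix of
// state posteriors and the log-likelihood.
// [[Rcpp::export(name = ".hmm_posterior")]]
List hmm_posterior(IntegerVector obs, NumericVector d, NumericMatrix e,
                   double alpha, double T) {
  const int n = obs.size();
  std::vector<double> a00(n - 1), a01(n - 1), a10(n - 1), a11(n - 1);
  for (int i = 0; i < n - 1; ++i)
    trans(alpha, T, d[i], a00[i], a01[i], a10[i], a11[i]);
  std::vector<double> f0(n), f1(n), b0(n), b1(n), sc(n);
  int o = obs[0] - 1;
  f0[0] = (1.0 - alpha) * e(0, o);
  f1[0] = alpha * e(1, o);
  sc[0] = f0[0] + f1[0]; f0[0] /= sc[0]; f1[0] /= sc[0];
  for (int i = 1; i < n; ++i) {
    o = obs[i] - 1;
    double p0 = (f0[i-1] * a00[i-1] + f1[i-1] * a10[i-1]) * e(0, o);
    double p1 = (f0[i-1] * a01[i-1] + f1[i-1] * a11[i-1]) * e(1, o);
    sc[i] = p0 + p1;
    f0[i] = p0 / sc[i]; f1[i] = p1 / sc[i];
  }
  double loglik = 0.0;
  for (int i = 0; i < n; ++i) loglik += std::log(sc[i]);
  b0[n-1] = 1.0; b1[n-1] = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    o = obs[i + 1] - 1;
    b0[i] = (a00[i] * e(0, o) * b0[i+1] + a01[i] * e(1, o) * b1[i+1]) / sc[i+1];
    b1[i] = (a10[i] * e(0, o) * b0[i+1] + a11[i] * e(1, o) * b1[i+1]) / sc[i+1];
  }
  NumericMatrix g(n, 2);
  for (int i = 0; i < n; ++i) {
    double g0 = f0[i] * b0[i], g1 = f1[i] * b1[i], s = g0 + g1;
    g(i, 0) = g0 / s; g(i, 1) = g1 / s;
  }
  return List::create(_["gamma"] = g, _["loglik"] = loglik);
}

// Viterbi path for one haplotype (0 = modern human, 1 = archaic).
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(IntegerVector obs, NumericVector d,
                          NumericMatrix e, double alpha, double T) {
  const int n = obs.size();
  std::vector<double> v0(n), v1(n);
  std::vector<signed char> p0(n), p1(n);
  int o = obs[0] - 1;
  v0[0] = std::log(1.0 - alpha) + std::log(e(0, o));
  v1[0] = std::log(alpha) + std::log(e(1, o));
  for (int i = 1; i < n; ++i) {
    double a00, a01, a10, a11;
    trans(alpha, T, d[i-1], a00, a01, a10, a11);
    o = obs[i] - 1;
    double s00 = v0[i-1] + std::log(a00), s10 = v1[i-1] + std::log(a10);
    double s01 = v0[i-1] + std::log(a01), s11 = v1[i-1] + std::log(a11);
    if (s00 >= s10) { v0[i] = s00; p0[i] = 0; } else { v0[i] = s10; p0[i] = 1; }
    if (s11 >= s01) { v1[i] = s11; p1[i] = 1; } else { v1[i] = s01; p1[i] = 0; }
    v0[i] += std::log(e(0, o));
    v1[i] += std::log(e(1, o));
  }
  IntegerVector path(n);
  path[n-1] = v1[n-1] > v0[n-1] ? 1 : 0;
  for (int i = n - 1; i >= 1; --i)
    path[i-1] = path[i] == 0 ? p0[i] : p1[i];
  return path;
}
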