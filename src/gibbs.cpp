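#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Draw from the standard normal truncated to (a, b).
// Central intervals use inverse-CDF sampling; far tails (|bound| > 4) use
// Robert's shifted-exponential rejection, which stays exact beyond 8 sd
// where naive inverse-CDF underflows.
static double rtnorm_std(double a, double b) {
  if (a >= b) stop("lower bound must be strictly below upper bound");
  if (!std::isfinite(a) && !std::isfinite(b)) return norm_rand();

  if (a > 4.0) {  // right tail
    double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (int it = 0; it < 100000; ++it) {
      double u = unif_rand();
      if (u <= 0.0) continue;
      double z = a - std::log(u) / alpha;
      if (z > b) continue;
      double d = z - alpha;
      if (unif_rand() <= std::exp(-0.5 * d * d)) return z;
    }
    return a;  // unreachable in practice
  }
  if (b < -4.0) return -rtnorm_std(-b, -a);

  double pa = std::isfinite(a) ? R::pnorm(a, 0.0, 1.0, 1, 0) : 0.0;
  double pb = std::isfinite(b) ? R::pnorm(b, 0.0, 1.0, 1, 0) : 1.0;
  double w = pb - pa;
  if (w <= 1e-15) {  // numerically degenerate interval: midpoint
    double lo = std::isfinite(a) ? a : b - 1.0;
    double hi = std::isfinite(b) ? b : a + 1.0;
    return 0.5 * (lo + hi);
  }
  double z = R::qnorm(pa + unif_rand() * w, 0.0, 1.0, 1, 0);
  if (z < a) z = a;
  if (z > b) z = b;
  return z;
}

// [[Rcpp::export(name = ".rtnorm_cpp")]]
NumericVector rtnorm_cpp(int n, NumericVector mean, NumericVector sd,
                         NumericVector lower, NumericVector upper) {
  NumericVector out(n);
  int nm = mean.size(), ns = sd.size(), nl = lower.size(), nu = upper.size();
  for (int i = 0; i < n; ++i) {
    double m = mean[i % nm], s = sd[i % ns];
    double a = (lower[i % nl] - m) / s, b = (upper[i % nu] - m) / s;
    out[i] = m + s * rtnorm_std(a, b);
  }
  return out;
}

// Gibbs sampler for a truncated multivariate normal.
//
// mu:     marginal mean vector (length d)
// w:      d x d regression weights, w(i, j) = -Q(i, j)/Q(i, i) for the
//         precision matrix Q, w(i, i) = 0; the full conditional mean of
//         coordinate i is mu_i + sum_j w(i, j) (x_j - mu_j)
// csd:    conditional standard deviations 1/sqrt(Q(i, i))
// lower/upper: truncation bounds per coordinate (+-Inf allowed)
// track:  0-based index of the coordinate whose posterior mean is monitored
//
// Runs burn_in sweeps, then batches of batch_size sweeps; stops when the
// batch-means standard error of the tracked coordinate drops to sem_tol or
// max_batches is reached.  Returns retained samples of all coordinates only
// when keep_samples is true.
// [[Rcpp::export(name = ".gibbs_tmvn_cpp")]]
List gibbs_tmvn_cpp(NumericVector mu, NumericMatrix w, NumericVector csd,
                    NumericVector lower, NumericVector upper,
                    int burn_in, int batch_size, int max_batches,
                    double sem_tol, int track, bool keep_samples) {
  int d = mu.size();
  std::vector<double> x(d);
  for (int i = 0; i < d; ++i) {
    double lo = lower[i], hi = upper[i];
    double start = mu[i];
    if (std::isfinite(lo) && std::isfinite(hi)) start = 0.5 * (lo + hi);
    else if (std::isfinite(lo) && start < lo) start = lo + 0.5;
    else if (std::isfinite(hi) && start > hi) start = hi - 0.5;
    x[i] = start;
  }

  auto sweep = [&](void) {
    for (int i = 0; i < d; ++i) {
      double cm = mu[i];
      for (int j = 0; j < d; ++j)
        if (j != i) cm += w(i, j) * (x[j] - mu[j]);
      if (csd[i] > 0.0) {
        double a = (lower[i] - cm) / csd[i], b = (upper[i] - cm) / csd[i];
        x[i] = cm + csd[i] * rtnorm_std(a, b);
      } else {  // degenerate coordinate: clamp conditional mean into bounds
        if (cm < lower[i]) cm = lower[i];
        if (cm > upper[i]) cm = upper[i];
        x[i] = cm;
      }
    }
  };

  for (int it = 0; it < burn_in; ++it) sweep();

  std::vector<double> batch_means;
  batch_means.reserve(max_batches);
  NumericMatrix samples;
  if (keep_samples) samples = NumericMatrix(batch_size * max_batches, d);

  double grand_sum = 0.0;
  long n_total = 0;
  bool converged = false;
  // the batch-means SE estimate is unreliable with few batches (few df);
  // require a minimum number of batches and two consecutive passes before
  // declaring convergence
  const int min_batches = 5;
  bool passed_last = false;

  for (int b = 0; b < max_batches; ++b) {
    double bsum = 0.0;
    for (int it = 0; it < batch_size; ++it) {
      sweep();
      bsum += x[track];
      if (keep_samples) {
        int row = b * batch_size + it;
        for (int j = 0; j < d; ++j) samples(row, j) = x[j];
      }
    }
    grand_sum += bsum;
    n_total += batch_size;
    batch_means.push_back(bsum / batch_size);

    if ((int)batch_means.size() >= 2) {
      double m = grand_sum / n_total, ss = 0.0;
      for (double bm : batch_means) ss += (bm - m) * (bm - m);
      double se = std::sqrt(ss / (batch_means.size() - 1.0) /
                            batch_means.size());
      bool pass = se <= sem_tol;
      if (pass && passed_last && (int)batch_means.size() >= min_batches) {
        converged = true;
        if (keep_samples)
          samples = samples(Range(0, n_total - 1), Range(0, d - 1));
        return List::create(_["mean"] = m, _["se"] = se,
                            _["n_samples"] = (double)n_total,
                            _["converged"] = true,
                            _["batch_means"] = wrap(batch_means),
                            _["samples"] = keep_samples ? (SEXP)samples
                                                        : R_NilValue);
      }
      passed_last = pass;
    }
  }

  double m = grand_sum / n_total, ss = 0.0;
  for (double bm : batch_means) ss += (bm - m) * (bm - m);
  double se = batch_means.size() > 1
                  ? std::sqrt(ss / (batch_means.size() - 1.0) /
                              batch_means.size())
                  : NA_REAL;
  return List::create(_["mean"] = m, _["se"] = se,
                      _["n_samples"] = (double)n_total,
                      _["converged"] = converged,
                      _["batch_means"] = wrap(batch_means),
                      _["samples"] = keep_samples ? (SEXP)samples
                                                  : R_NilValue);
}
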