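#include <Rcpp.h>
using namespace Rcpp;

static inline double mink2(double dx, double dy, double r) {
  dx = std::fabs(dx); dy = std::fabs(dy);
  if (r == 2.0) return std::sqrt(dx * dx + dy * dy);
  if (r == 1.0) return dx + dy;
  return std::pow(std::pow(dx, r) + std::pow(dy, r), 1.0 / r);
}

// mean over points of the distance to the nearest other point
// [[Rcpp::export(name = ".nn_mean_cpp")]]
double nn_mean_cpp(NumericMatrix X, double r) {
  int n = X.nrow();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = mink2(X(i, 0) - X(j, 0), X(i, 1) - X(j, 1), r);
      if (d < best) best = d;
    }
    acc += best;
  }
  return acc / n;
}

// mean nearest-neighbour distance averaged over n_random uniform
// configurations of n_points drawn in the box [lo, hi] x [lo, hi] per axis;
// uses R's RNG so results follow set.seed()
// [[Rcpp::export(name = ".null_nn_mean_cpp")]]
double null_nn_mean_cpp(int n_points, int n_random,
                        NumericVector lo, NumericVector hi, double r) {
  std::vector<double> x(n_points), y(n_points);
  double acc = 0.0;
  for (int k = 0; k < n_random; ++k) {
    for (int i = 0; i < n_points; ++i) {
      x[i] = R::runif(lo[0], hi[0]);
      y[i] = R::runif(lo[1], hi[1]);
    }
    double m = 0.0;
    for (int i = 0; i < n_points; ++i) {
      double best = R_PosInf;
      for (int j = 0; j < n_points; ++j) {
        if (j == i) continue;
        double d = mink2(x[i] - x[j], y[i] - y[j], r);
        if (d < best) best = d;
      }
      m += best;
    }
    acc += m / n_points;
  }
  return acc / n_random;
}

// per-trial log-probability of the observed odd-one-out choice:
// P(odd = w1) proportional to exp(-delta * d(w2, w3)), Minkowski-r distances
// [[Rcpp::export(name = ".triad_loglik_cpp")]]
NumericVector triad_loglik_cpp(NumericMatrix X, IntegerMatrix idx,
                               IntegerVector odd, NumericVector delta,
                               double r) {
  int n = idx.nrow();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    int a = idx(t, 0) - 1, b = idx(t, 1) - 1, c = idx(t, 2) - 1;
    double u1 = -delta[t] * mink2(X(b, 0) - X(c, 0), X(b, 1) - X(c, 1), r);
    double u2 = -delta[t] * mink2(X(a, 0) - X(c, 0), X(a, 1) - X(c, 1), r);
    double u3 = -delta[t] * mink2(X(a, 0) - X(b, 0), X(a, 1) - X(b, 1), r);
    double m = std::max(u1, std::max(u2, u3));
    double lse = m + std::log(std::exp(u1 - m) + std::exp(u2 - m) +
                              std::exp(u3 - m));
    double uo = (odd[t] == 1) ? u1 : (odd[t] == 2 ? u2 : u3);
    out[t] = uo - lse;
  }
  return out;
}
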