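#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise Euclidean distances between rows of X, optionally excluding
// temporally close pairs (|i - j| <= theiler, indices in original time order
// given by idx). Returns the surviving distances in arbitrary order.
// [[Rcpp::export]]
NumericVector pair_distances_cpp(const NumericMatrix& X,
                                 const IntegerVector& idx,
                                 int theiler) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> out;
  out.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (theiler > 0 && std::abs(idx[i] - idx[j]) <= theiler) continue;
      double s = 0.0;
      for (int k = 0; k < m; ++k) {
        const double d = X(i, k) - X(j, k);
        s += d * d;
      }
      out.push_back(std::sqrt(s));
    }
  }
  return wrap(out);
}

static double phi_apen(const double* x, int n, int m, double r) {
  const int nm = n - m + 1;
  double acc = 0.0;
  for (int i = 0; i < nm; ++i) {
    int cnt = 0;
    for (int j = 0; j < nm; ++j) {
      double dmax = 0.0;
      for (int k = 0; k < m; ++k) {
        const double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dmax) dmax = d;
        if (dmax > r) break;
      }
      if (dmax <= r) ++cnt;  // self-match included (j == i)
    }
    acc += std::log((double)cnt / nm);
  }
  return acc / nm;
}

// Approximate entropy ApEn(m, r) with Chebyshev distance and self-matches.
// [[Rcpp::export]]
double apen_cpp(const NumericVector& x, int m, double r) {
  const int n = x.size();
  if (n < m + 2) return NA_REAL;
  return phi_apen(x.begin(), n, m, r) - phi_apen(x.begin(), n, m + 1, r);
}

// Cao's method: delay matrix E has max_m + 1 columns (components x(i + k*tau),
// k = 0..max_m). For each m = 1..max_m returns
//   E(m)  = mean over i of ||y_{m+1}(i) - y_{m+1}(nn_m(i))|| / ||y_m(i) - y_m(nn_m(i))||
//   E*(m) = mean over i of |x(i + m*tau) - x(nn_m(i) + m*tau)|
// with nearest neighbours in Chebyshev norm, zero-distance pairs skipped.
// [[Rcpp::export]]
List cao_cpp(const NumericMatrix& E, int max_m) {
  const int n = E.nrow();
  NumericVector Em(max_m, NA_REAL), Estar(max_m, NA_REAL);
  for (int m = 1; m <= max_m; ++m) {
    double accE = 0.0, accS = 0.0;
    int cntE = 0, cntS = 0;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int nn = -1;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dmax = 0.0;
        for (int k = 0; k < m; ++k) {
          const double d = std::fabs(E(i, k) - E(j, k));
          if (d > dmax) dmax = d;
          if (dmax >= best) break;
        }
        if (dmax < best && dmax > 0.0) { best = dmax; nn = j; }
      }
      if (nn < 0) continue;
      double dmax1 = best;
      {
        const double d = std::fabs(E(i, m) - E(nn, m));
        if (d > dmax1) dmax1 = d;
      }
      accE += dmax1 / best; ++cntE;
      accS += std::fabs(E(i, m) - E(nn, m)); ++cntS;
    }
    if (cntE > 0) Em[m - 1] = accE / cntE;
    if (cntS > 0) Estar[m - 1] = accS / cntS;
  }
  return List::create(_["E"] = Em, _["Estar"] = Estar);
}
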