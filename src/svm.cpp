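// Linear soft-margin C-SVC trained by sequential minimal optimization,
// specialized for the small leave-one-participant-out problems of the
// decoding module (tens of patterns, tens of features). Dual problem:
//   min 1/2 a' Q a - e' a,  0 <= a <= C,  y' a = 0,  Q_ij = y_i y_j x_i'x_j
// Working-set selection is the maximal violating pair; stopping tolerance
// matches the libsvm default so predictions agree with reference fits.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SvmModel {
  std::vector<double> alpha;
  double b;
};

// X: n x p (row-major flattened by caller as std::vector of rows)
SvmModel smo_train(const std::vector<std::vector<double>>& X,
                   const std::vector<double>& y, double C,
                   double eps = 1e-3, int max_iter = 200000) {
  const int n = (int)X.size();
  // Gram matrix
  std::vector<std::vector<double>> K(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      const std::vector<double>& xi = X[i];
      const std::vector<double>& xj = X[j];
      for (size_t k = 0; k < xi.size(); ++k) s += xi[k] * xj[k];
      K[i][j] = K[j][i] = s;
    }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  double m_up = 0.0, m_low = 0.0;
  for (int iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double Gmax = -1e300, Gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && v > Gmax) { Gmax = v; i = t; }
      if (in_low && v < Gmin) { Gmin = v; j = t; }
    }
    m_up = Gmax; m_low = Gmin;
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    double eta = K[i][i] + K[j][j] - 2.0 * K[i][j];
    if (eta <= 0) eta = 1e-12;
    double d = (Gmax - Gmin) / eta;
    double cap_i = (y[i] > 0) ? C - alpha[i] : alpha[i];
    double cap_j = (y[j] > 0) ? alpha[j] : C - alpha[j];
    if (d > cap_i) d = cap_i;
    if (d > cap_j) d = cap_j;
    if (d <= 0) break;

    double dai = y[i] * d, daj = -y[j] * d;
    alpha[i] += dai;
    alpha[j] += daj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K[t][i] * dai + y[j] * K[t][j] * daj);
  }

  // bias: average KKT condition over free support vectors, else midpoint
  double b = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      b += -y[t] * G[t];
      ++n_free;
    }
  }
  if (n_free > 0) b /= n_free;
  else b = (m_up + m_low) / 2.0;

  SvmModel m;
  m.alpha = alpha;
  m.b = b;
  return m;
}

double decision_value(const std::vector<std::vector<double>>& X,
                      const std::vector<double>& y, const SvmModel& m,
                      const std::vector<double>& x) {
  double s = m.b;
  for (size_t t = 0; t < X.size(); ++t) {
    if (m.alpha[t] <= 0) continue;
    double k = 0.0;
    for (size_t q = 0; q < x.size(); ++q) k += X[t][q] * x[q];
    s += m.alpha[t] * y[t] * k;
  }
  return s;
}

std::vector<std::vector<double>> as_rows(const NumericMatrix& X,
                                         const std::vector<int>& idx) {
  std::vector<std::vector<double>> out(idx.size(),
                                       std::vector<double>(X.ncol()));
  for (size_t r = 0; r < idx.size(); ++r)
    for (int c = 0; c < X.ncol(); ++c) out[r][c] = X(idx[r], c);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".svm_train_cpp")]]
List svm_train_cpp(NumericMatrix X, NumericVector y, double cost) {
  std::vector<int> all(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) all[i] = i;
  std::vector<std::vector<double>> rows = as_rows(X, all);
  std::vector<double> yy(y.begin(), y.end());
  SvmModel m = smo_train(rows, yy, cost);
  return List::create(_["alpha"] = NumericVector(m.alpha.begin(),
                                                 m.alpha.end()),
                      _["b"] = m.b);
}

// [[Rcpp::export(name = ".svm_decision_cpp")]]
NumericVector svm_decision_cpp(NumericMatrix Xtrain, NumericVector y,
                               NumericVector alpha, double b,
                               NumericMatrix Xtest) {
  std::vector<int> all(Xtrain.nrow());
  for (int i = 0; i < Xtrain.nrow(); ++i) all[i] = i;
  std::vector<std::vector<double>> rows = as_rows(Xtrain, all);
  SvmModel m;
  m.alpha.assign(alpha.begin(), alpha.end());
  m.b = b;
  std::vector<double> yy(y.begin(), y.end());
  NumericVector out(Xtest.nrow());
  for (int i = 0; i < Xtest.nrow(); ++i) {
    std::vector<double> x(Xtest.ncol());
    for (int c = 0; c < Xtest.ncol(); ++c) x[c] = Xtest(i, c);
    out[i] = decision_value(rows, yy, m, x);
  }
  return out;
}

// Full leave-one-participant-out pass: for each held-out participant,
// train on all other rows and return decision values for the held-out
// rows. participant: 0-based group index per row of X.
// [[Rcpp::export(name = ".lopo_decision_cpp")]]
NumericVector lopo_decision_cpp(NumericMatrix X, NumericVector y,
                                IntegerVector participant, double cost) {
  int n = X.nrow();
  int n_part = 0;
  for (int i = 0; i < n; ++i)
    if (participant[i] + 1 > n_part) n_part = participant[i] + 1;
  NumericVector out(n);
  for (int p = 0; p < n_part; ++p) {
    std::vector<int> train_idx, test_idx;
    for (int i = 0; i < n; ++i) {
      if (participant[i] == p) test_idx.push_back(i);
      else train_idx.push_back(i);
    }
    if (test_idx.empty()) continue;
    std::vector<std::vector<double>> rows = as_rows(X, train_idx);
    std::vector<double> yy(train_idx.size());
    for (size_t t = 0; t < train_idx.size(); ++t) yy[t] = y[train_idx[t]];
    SvmModel m = smo_train(rows, yy, cost);
    for (size_t t = 0; t < test_idx.size(); ++t) {
      std::vector<double> x(X.ncol());
      for (int c = 0; c < X.ncol(); ++c) x[c] = X(test_idx[t], c);
      out[test_idx[t]] = decision_value(rows, yy, m, x);
    }
  }
  return out;
}
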