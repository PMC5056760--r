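#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// C-SVC dual solved by SMO with second-order working-set selection
// (the libsvm strategy). The full RBF kernel matrix is cached: training
// sets here are at most a few thousand rows.
//
//   min_a 0.5 a' Q a - e' a   s.t. 0 <= a_i <= C, y' a = 0,
//   Q_ij = y_i y_j K(x_i, x_j),  K = exp(-gamma ||u - v||^2)

static inline double rbf(const NumericMatrix &X, int i, int j, double gamma) {
  double s = 0.0;
  int p = X.ncol();
  for (int k = 0; k < p; ++k) {
    double d = X(i, k) - X(j, k);
    s += d * d;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List cpp_svm_train(NumericMatrix X, IntegerVector y, double C, double gamma,
                   double eps, int max_iter) {
  const int n = X.nrow();
  if (n < 2) stop("need at least 2 training rows");
  const double TAU = 1e-12;
  const double INF = std::numeric_limits<double>::infinity();

  // cache signed kernel Q and diagonal
  std::vector<double> Q((size_t) n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double q = y[i] * y[j] * rbf(X, i, j, gamma);
      Q[(size_t) i * n + j] = q;
      Q[(size_t) j * n + i] = q;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  while (iter < max_iter) {
    // working-set selection: i maximizes -y_t G_t over I_up
    int i = -1;
    double Gmax = -INF, Gmin = INF;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      if (up && -y[t] * G[t] > Gmax) { Gmax = -y[t] * G[t]; i = t; }
    }
    if (i < 0) break;
    // j minimizes the second-order gain over I_low with -y_t G_t < Gmax
    int j = -1;
    double obj_min = INF;
    const double *Qi = &Q[(size_t) i * n];
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!low) continue;
      double gt = -y[t] * G[t];
      if (gt < Gmin) Gmin = gt;
      double b = Gmax - gt;
      if (b > 0) {
        double a = Qi[i] + Q[(size_t) t * n + t] - 2.0 * y[i] * y[t] * Qi[t];
        if (a <= 0) a = TAU;
        double obj = -(b * b) / a;
        if (obj < obj_min) { obj_min = obj; j = t; }
      }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    const double *Qj = &Q[(size_t) j * n];
    double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = Qi[i] + Qj[j] + 2.0 * Qi[j];
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Qi[i] + Qj[j] - 2.0 * Qi[j];
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t)
      G[t] += Qi[t] * dai + Qj[t] * daj;
    ++iter;
  }
  if (iter >= max_iter)
    Rf_warning("SMO reached max_iter (%d) before convergence", max_iter);

  // rho (decision offset): average -y_t G_t over free vectors
  double ub = INF, lb = -INF, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C - 1e-12) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      sum_free += yG; ++n_free;
    }
  }
  double rho = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;

  // keep support vectors only
  std::vector<int> sv;
  for (int t = 0; t < n; ++t) if (alpha[t] > 1e-12) sv.push_back(t);
  int nsv = (int) sv.size();
  NumericMatrix SV(nsv, X.ncol());
  NumericVector coef(nsv);
  for (int s = 0; s < nsv; ++s) {
    int t = sv[s];
    coef[s] = alpha[t] * y[t];
    for (int k = 0; k < X.ncol(); ++k) SV(s, k) = X(t, k);
  }
  return List::create(_["sv"] = SV, _["coef"] = coef, _["rho"] = rho,
                      _["iterations"] = iter, _["n_sv"] = nsv);
}

// decision values f(x) = sum_s coef_s K(sv_s, x) - rho
// [[Rcpp::export]]
NumericVector cpp_svm_decision(NumericMatrix SV, NumericVector coef,
                               double rho, double gamma, NumericMatrix newX) {
  const int m = newX.nrow(), nsv = SV.nrow(), p = SV.ncol();
  if (newX.ncol() != p) stop("feature dimension mismatch");
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double f = -rho;
    for (int s = 0; s < nsv; ++s) {
      double d2 = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = SV(s, k) - newX(i, k);
        d2 += d * d;
      }
      f += coef[s] * std::exp(-gamma * d2);
    }
    out[i] = f;
  }
  return out;
}
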