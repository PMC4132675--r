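#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Soft-margin linear C-SVC solved in the dual by SMO with maximal-violating-pair
// working-set selection (the LIBSVM formulation):
//   min_a 0.5 * a' Q a - e' a,  0 <= a_i <= C,  sum_i y_i a_i = 0,
// with Q_ij = y_i y_j K_ij and K the linear kernel. Small problems only
// (tens to a few hundred trials); the Gram matrix is held densely.

struct SmoFit {
  std::vector<double> alpha;
  double bias;
  double dual_obj;
  int iterations;
};

static SmoFit smo_solve(const std::vector<double>& K, const std::vector<double>& y,
                        int n, double C, double tol, int max_iter) {
  std::vector<double> alpha(n, 0.0);
  // grad_i = d/da_i (0.5 a'Qa - e'a) = sum_j y_i y_j K_ij a_j - 1
  std::vector<double> grad(n, -1.0);
  int it = 0;
  for (; it < max_iter; ++it) {
    // working pair: i maximises -y_i grad_i over I_up, j minimises over I_low
    int i = -1, j = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * grad[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    // analytic step along the feasible direction d_i = y_i, d_j = -y_j,
    // clipped so both coordinates stay in the box
    double quad = K[i * n + i] + K[j * n + j] - 2.0 * K[i * n + j];
    if (quad <= 0) quad = 1e-12;
    double lambda = (gmax - gmin) / quad;
    double ub_i = y[i] > 0 ? C - alpha[i] : alpha[i];
    double ub_j = y[j] > 0 ? alpha[j] : C - alpha[j];
    if (lambda > ub_i) lambda = ub_i;
    if (lambda > ub_j) lambda = ub_j;
    if (lambda <= 0) break;

    double di = y[i] * lambda, dj = -y[j] * lambda;
    alpha[i] += di;
    alpha[j] += dj;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * K[i * n + t] * di + y[j] * K[j * n + t] * dj);
  }

  // bias from free support vectors, else midpoint of the KKT bounds
  double bsum = 0.0; int nfree = 0;
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  for (int t = 0; t < n; ++t) {
    double yg = -y[t] * grad[t]; // = y_t - f(x_t) + b contribution; see KKT
    bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { bsum += yg; ++nfree; }
    if (up && yg < ub) ub = yg;
    if (low && yg > lb) lb = yg;
  }
  double bias = nfree > 0 ? bsum / nfree : (ub + lb) / 2.0;

  // dual objective 0.5 a'Qa - e'a, using grad_i = (Qa)_i - 1
  double dual = 0.0;
  for (int t = 0; t < n; ++t) dual += 0.5 * alpha[t] * (grad[t] + 1.0) - alpha[t];

  SmoFit fit;
  fit.alpha = alpha;
  fit.bias = bias;
  fit.dual_obj = dual;
  fit.iterations = it;
  return fit;
}

// [[Rcpp::export]]
List smo_train_cpp(NumericMatrix X, NumericVector y, double C,
                   double tol = 1e-6, int max_iter = 100000) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += X(i, k) * X(j, k);
      K[i * (size_t)n + j] = s;
      K[j * (size_t)n + i] = s;
    }
  std::vector<double> yv(y.begin(), y.end());
  SmoFit fit = smo_solve(K, yv, n, C, tol, max_iter);

  NumericVector w(p);
  for (int t = 0; t < n; ++t) {
    double c = fit.alpha[t] * yv[t];
    if (c != 0.0) for (int k = 0; k < p; ++k) w[k] += c * X(t, k);
  }
  return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["weights"] = w,
                      _["bias"] = fit.bias,
                      _["dual_objective"] = fit.dual_obj,
                      _["iterations"] = fit.iterations);
}

// Decision values for trials given all one-vs-rest margins; ECOC Hamming
// decoding with tie-break by summed signed margin, then lowest class index.
static int ecoc_decode(const std::vector<double>& margin, const IntegerMatrix& code) {
  int K = code.nrow(), L = code.ncol();
  int best = 0;
  double best_h = std::numeric_limits<double>::infinity();
  double best_m = -std::numeric_limits<double>::infinity();
  for (int k = 0; k < K; ++k) {
    double h = 0.0, m = 0.0;
    for (int l = 0; l < L; ++l) {
      int s = margin[l] >= 0 ? 1 : -1;
      if (s != code(k, l)) h += 1.0;
      m += code(k, l) * margin[l];
    }
    if (h < best_h - 1e-12 || (std::fabs(h - best_h) <= 1e-12 && m > best_m + 1e-12)) {
      best = k; best_h = h; best_m = m;
    }
  }
  return best;
}

// Score every candidate searchlight neighbourhood by inner-cross-validated
// ECOC-SVM accuracy on the training data only.
//
// X: trials x voxels (training fold, already standardised)
// cls: 1..K class per trial
// code: K x L ECOC code matrix (+1/-1)
// nbs: list of integer vectors (1-based voxel indices per neighbourhood)
// fold: 1..F inner-fold id per trial
// [[Rcpp::export]]
NumericVector score_neighbourhoods_cpp(NumericMatrix X, IntegerVector cls,
                                       IntegerMatrix code, List nbs,
                                       IntegerVector fold, double C,
                                       double tol = 1e-6, int max_iter = 100000) {
  int n = X.nrow();
  int ncls = code.nrow(), L = code.ncol();
  int F = 0;
  for (int t = 0; t < n; ++t) if (fold[t] > F) F = fold[t];
  int nnb = nbs.size();
  NumericVector out(nnb);

  for (int b = 0; b < nnb; ++b) {
    IntegerVector vox = nbs[b];
    int p = vox.size();
    // Gram over all training trials restricted to this neighbourhood
    std::vector<double> G((size_t)n * n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i; j < n; ++j) {
        double s = 0.0;
        for (int k = 0; k < p; ++k) s += X(i, vox[k] - 1) * X(j, vox[k] - 1);
        G[i * (size_t)n + j] = s;
        G[j * (size_t)n + i] = s;
      }

    int correct = 0;
    for (int f = 1; f <= F; ++f) {
      std::vector<int> tr, te;
      for (int t = 0; t < n; ++t) (fold[t] == f ? te : tr).push_back(t);
      if (te.empty() || tr.empty()) continue;
      int ntr = tr.size(), nte = te.size();
      std::vector<double> Ktr((size_t)ntr * ntr);
      for (int i = 0; i < ntr; ++i)
        for (int j = 0; j < ntr; ++j)
          Ktr[i * (size_t)ntr + j] = G[tr[i] * (size_t)n + tr[j]];

      // margins per held-out trial per binary problem
      std::vector<double> marg((size_t)nte * L, 0.0);
      for (int l = 0; l < L; ++l) {
        std::vector<double> yb(ntr);
        bool pos = false, neg = false;
        for (int i = 0; i < ntr; ++i) {
          yb[i] = code(cls[tr[i]] - 1, l);
          if (yb[i] > 0) pos = true; else neg = true;
        }
        if (!pos || !neg) { // degenerate split: margin 0, decode by tie-break
          continue;
        }
        SmoFit fit = smo_solve(Ktr, yb, ntr, C, tol, max_iter);
        for (int u = 0; u < nte; ++u) {
          double s = fit.bias;
          for (int i = 0; i < ntr; ++i)
            if (fit.alpha[i] != 0.0)
              s += fit.alpha[i] * yb[i] * G[tr[i] * (size_t)n + te[u]];
          marg[u * (size_t)L + l] = s;
        }
      }
      for (int u = 0; u < nte; ++u) {
        std::vector<double> m(marg.begin() + u * (size_t)L,
                              marg.begin() + (u + 1) * (size_t)L);
        if (ecoc_decode(m, code) == cls[te[u]] - 1) ++correct;
      }
    }
    out[b] = (double)correct / (double)n;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector ecoc_decode_cpp(NumericMatrix margins, IntegerMatrix code) {
  int n = margins.nrow(), L = margins.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<double> m(L);
    for (int l = 0; l < L; ++l) m[l] = margins(i, l);
    out[i] = ecoc_decode(m, code) + 1;
  }
  return out;
}
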