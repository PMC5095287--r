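#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for two-class C-SVC on a precomputed kernel.
// Dual: min 0.5 a'Qa - e'a, Q_ij = y_i y_j K_ij, 0 <= a_i <= C, sum a_i y_i = 0.
// Working-set selection is the maximal violating pair (first-order rule); adequate
// for the small per-fold problems (n <= a few hundred) this package solves.
namespace {

struct SmoFit {
  std::vector<double> alpha;
  double b;
  double obj;
  int iter;
};

// K: nsub x nsub kernel of the training subset (contiguous), y: +/-1 per row.
SmoFit smo_solve(const std::vector<double>& K, const std::vector<double>& y,
                 int n, double C, double eps, int max_iter) {
  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  int it = 0;
  double m = 0.0, M = 0.0;
  for (; it < max_iter; ++it) {
    // second-order working-set selection (maximal violating pair for i,
    // best decrease for j), as in libsvm
    int i = -1, j = -1;
    m = -HUGE_VAL; M = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      if (up && v > m) { m = v; i = t; }
    }
    if (i < 0) break;
    const double* Ki_sel = &K[(size_t)n * i];
    const double Kii_sel = Ki_sel[i];
    double best_obj = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (!low) continue;
      if (v < M) M = v;
      const double bt = m - v;
      if (bt > 0) {
        double at = Kii_sel + K[t + (size_t)n * t] - 2.0 * y[i] * y[t] * Ki_sel[t];
        if (at <= 0) at = 1e-12;
        const double obj_t = -(bt * bt) / at;
        if (obj_t < best_obj) { best_obj = obj_t; j = t; }
      }
    }
    if (j < 0 || m - M < eps) break;

    const double Kii = K[i + (size_t)n * i], Kjj = K[j + (size_t)n * j],
                 Kij = K[i + (size_t)n * j];
    const double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = Kii + Kjj + 2.0 * Kij;
      if (quad <= 0) quad = 1e-12;
      const double delta = (-grad[i] - grad[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = 1e-12;
      const double delta = (grad[i] - grad[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    const double di = y[i] * (alpha[i] - ai_old), dj = y[j] * (alpha[j] - aj_old);
    if (di != 0.0 || dj != 0.0) {
      const double* Ki = &K[(size_t)n * i];
      const double* Kj = &K[(size_t)n * j];
      for (int t = 0; t < n; ++t)
        grad[t] += y[t] * (di * Ki[t] + dj * Kj[t]);
    }
  }
  // intercept: average y_i - u_i over free support vectors, else midpoint of bounds
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { bsum += -y[t] * grad[t]; ++nfree; }
  double b = nfree > 0 ? bsum / nfree : 0.5 * (m + M);
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (grad[t] - 1.0);
  obj *= 0.5;
  SmoFit out; out.alpha = std::move(alpha); out.b = b; out.obj = obj; out.iter = it;
  return out;
}

inline void gather_kernel(const NumericMatrix& K, const std::vector<int>& idx,
                          std::vector<double>& out) {
  const int n = idx.size();
  out.resize((size_t)n * n);
  for (int j = 0; j < n; ++j) {
    const double* col = &K(0, idx[j]);
    for (int i = 0; i < n; ++i) out[i + (size_t)n * j] = col[idx[i]];
  }
}

} // namespace

// [[Rcpp::export]]
List smo_fit_cpp(NumericMatrix K, IntegerVector idx0, NumericVector y,
                 double cost, double eps, int max_iter) {
  std::vector<int> idx(idx0.begin(), idx0.end());
  const int n = idx.size();
  std::vector<double> Ksub, ysub(n);
  gather_kernel(K, idx, Ksub);
  for (int i = 0; i < n; ++i) ysub[i] = y[idx[i]];
  SmoFit f = smo_solve(Ksub, ysub, n, cost, eps, max_iter);
  return List::create(_["alpha"] = NumericVector(f.alpha.begin(), f.alpha.end()),
                      _["b"] = f.b, _["obj"] = f.obj, _["iter"] = f.iter);
}

// [[Rcpp::export]]
NumericVector smo_decision_cpp(NumericMatrix K, IntegerVector train0,
                               IntegerVector test0, NumericVector alpha,
                               NumericVector ytrain, double b) {
  const int n = train0.size(), m = test0.size();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    const double* col = &K(0, test0[t]);
    double s = b;
    for (int i = 0; i < n; ++i)
      if (alpha[i] != 0.0) s += alpha[i] * ytrain[i] * col[train0[i]];
    out[t] = s;
  }
  return out;
}

// Full nested cross-validation over (window x gamma x cost).
// Ks: list of n x n kernels, element (g-1)*n_window + w for gamma g, window w.
// outer_assign: 1..k_outer per trial. inner_assign: per outer fold an n x repeats
// integer matrix with 1..k_inner on the outer-training rows and 0 on test rows.
// Returns pooled outer-test predictions per window, per-fold inner-CV accuracy
// tables and the selected (gamma, cost) combination per fold and window.
// [[Rcpp::export]]
List nested_cv_cpp(List Ks, NumericVector y, IntegerVector outer_assign,
                   List inner_assign, NumericVector costs, int n_gamma,
                   int n_window, double eps, int max_iter) {
  const int n = y.size();
  const int n_cost = costs.size();
  const int n_combo = n_gamma * n_cost;
  const int k_outer = inner_assign.size();

  IntegerMatrix pred(n, n_window);
  IntegerMatrix best_combo(k_outer, n_window);
  NumericVector inner_by_fold(Dimension(n_combo, n_window, k_outer));

  std::vector<double> Ksub, Kfit;
  std::vector<double> ysub, yfit;
  std::vector<int> train_idx, fit_idx, val_idx;

  for (int k = 0; k < k_outer; ++k) {
    IntegerMatrix ia = inner_assign[k];
    const int repeats = ia.ncol();
    train_idx.clear();
    std::vector<int> test_idx;
    for (int t = 0; t < n; ++t) {
      if (outer_assign[t] == k + 1) test_idx.push_back(t);
      else train_idx.push_back(t);
    }
    const int ntr = train_idx.size();

    // inner-CV hit counts per (combo, window)
    std::vector<long> hits((size_t)n_combo * n_window, 0);
    long total_preds = 0;

    for (int g = 0; g < n_gamma; ++g) {
      for (int w = 0; w < n_window; ++w) {
        NumericMatrix K = Ks[g * n_window + w];
        for (int r = 0; r < repeats; ++r) {
          int k_inner = 0;
          for (int t = 0; t < n; ++t)
            if (ia(t, r) > k_inner) k_inner = ia(t, r);
          for (int f = 1; f <= k_inner; ++f) {
            fit_idx.clear(); val_idx.clear();
            for (int t = 0; t < ntr; ++t) {
              const int lab = ia(train_idx[t], r);
              if (lab == f) val_idx.push_back(train_idx[t]);
              else if (lab > 0) fit_idx.push_back(train_idx[t]);
            }
            const int nf = fit_idx.size(), nv = val_idx.size();
            if (nf < 2 || nv == 0) continue;
            gather_kernel(K, fit_idx, Kfit);
            yfit.resize(nf);
            for (int i = 0; i < nf; ++i) yfit[i] = y[fit_idx[i]];
            for (int c = 0; c < n_cost; ++c) {
              SmoFit fit = smo_solve(Kfit, yfit, nf, costs[c], eps, max_iter);
              int hit = 0;
              for (int v = 0; v < nv; ++v) {
                const double* col = &K(0, val_idx[v]);
                double s = fit.b;
                for (int i = 0; i < nf; ++i)
                  if (fit.alpha[i] != 0.0)
                    s += fit.alpha[i] * yfit[i] * col[fit_idx[i]];
                if ((s >= 0 ? 1.0 : -1.0) == y[val_idx[v]]) ++hit;
              }
              hits[(size_t)(g * n_cost + c) + (size_t)n_combo * w] += hit;
              if (g == 0 && c == 0) total_preds += nv;
            }
          }
        }
      }
    }
    // total predictions is identical for every combo/window; recompute denominator
    const long denom = total_preds / n_window;
    for (int w = 0; w < n_window; ++w)
      for (int cc = 0; cc < n_combo; ++cc)
        inner_by_fold[cc + n_combo * (w + n_window * k)] =
          denom > 0 ? (double)hits[(size_t)cc + (size_t)n_combo * w] / denom : NA_REAL;

    // refit on the full outer-training set with the per-window winner
    ysub.resize(ntr);
    for (int i = 0; i < ntr; ++i) ysub[i] = y[train_idx[i]];
    for (int w = 0; w < n_window; ++w) {
      int best = 0; double bestacc = -1.0;
      for (int cc = 0; cc < n_combo; ++cc) {
        const double a = inner_by_fold[cc + n_combo * (w + n_window * k)];
        if (a > bestacc + 1e-12) { bestacc = a; best = cc; }
      }
      best_combo(k, w) = best + 1;
      const int g = best / n_cost, c = best % n_cost;
      NumericMatrix K = Ks[g * n_window + w];
      gather_kernel(K, train_idx, Ksub);
      SmoFit fit = smo_solve(Ksub, ysub, ntr, costs[c], eps, max_iter);
      for (size_t v = 0; v < test_idx.size(); ++v) {
        const double* col = &K(0, test_idx[v]);
        double s = fit.b;
        for (int i = 0; i < ntr; ++i)
          if (fit.alpha[i] != 0.0) s += fit.alpha[i] * ysub[i] * col[train_idx[i]];
        pred(test_idx[v], w) = s >= 0 ? 1 : -1;
      }
    }
  }
  return List::create(_["pred"] = pred, _["inner_by_fold"] = inner_by_fold,
                      _["best_combo"] = best_combo);
}
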