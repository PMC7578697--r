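// Linear soft-margin SVM via sequential minimal optimisation (SMO) with
// maximal-violating-pair working-set selection, plus tight cross-validation
// loops used by the exhaustive channel-subset search.
//
// The dual problem solved (per-sample box constraint C, equality constraint
// sum(alpha_i * y_i) = 0) is the standard hinge-loss SVM dual; with a linear
// kernel the primal weight vector w = sum(alpha_i * y_i * x_i) is maintained
// incrementally so every iteration is O(n * d).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double SMO_TAU = 1e-12;

// x: row-major (n x d), y in {-1, +1}; alpha, w, f are caller workspaces.
// f[i] caches w . x_i. Returns number of iterations used; *b_out gets the
// intercept recovered from the KKT conditions.
static int smo_solve(const double* x, int n, int d, const double* y,
                     double C, double tol, int max_iter,
                     double* alpha, double* w, double* f, double* b_out) {
  for (int j = 0; j < d; ++j) w[j] = 0.0;
  for (int i = 0; i < n; ++i) { alpha[i] = 0.0; f[i] = 0.0; }

  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // maximal violating pair over -y_i * G_i, G_i = y_i * f_i - 1
    double m = -HUGE_VAL, M = HUGE_VAL;
    int iu = -1, jl = -1;
    for (int i = 0; i < n; ++i) {
      const double v = -y[i] * (y[i] * f[i] - 1.0);
      const bool up  = (y[i] > 0.0) ? (alpha[i] < C) : (alpha[i] > 0.0);
      const bool low = (y[i] > 0.0) ? (alpha[i] > 0.0) : (alpha[i] < C);
      if (up && v > m)  { m = v; iu = i; }
      if (low && v < M) { M = v; jl = i; }
    }
    if (iu < 0 || jl < 0 || m - M < tol) break;

    const int i = iu, j = jl;
    const double* xi = x + (size_t)i * d;
    const double* xj = x + (size_t)j * d;
    double kii = 0.0, kjj = 0.0, kij = 0.0;
    for (int t = 0; t < d; ++t) {
      kii += xi[t] * xi[t];
      kjj += xj[t] * xj[t];
      kij += xi[t] * xj[t];
    }
    const double gi = y[i] * f[i] - 1.0;
    const double gj = y[j] * f[j] - 1.0;
    const double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      double quad = kii + kjj - 2.0 * kij;
      if (quad <= 0.0) quad = SMO_TAU;
      const double delta = (-gi - gj) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0.0) {
        if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = -diff; }
      }
      if (diff > 0.0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = kii + kjj - 2.0 * kij;
      if (quad <= 0.0) quad = SMO_TAU;
      const double delta = (gi - gj) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = sum; }
      }
    }

    const double dai = (alpha[i] - ai_old) * y[i];
    const double daj = (alpha[j] - aj_old) * y[j];
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < d; ++t) w[t] += dai * xi[t] + daj * xj[t];
      for (int r = 0; r < n; ++r) {
        const double* xr = x + (size_t)r * d;
        double df = 0.0;
        for (int t = 0; t < d; ++t) df += (dai * xi[t] + daj * xj[t]) * xr[t];
        f[r] += df;
      }
    }
  }

  // intercept: average KKT residual over free support vectors; if none,
  // midpoint of the feasible interval implied by the bound alphas.
  double bsum = 0.0; int nfree = 0;
  for (int i = 0; i < n; ++i) {
    if (alpha[i] > SMO_TAU && alpha[i] < C - SMO_TAU) {
      bsum += y[i] - f[i];
      ++nfree;
    }
  }
  double b;
  if (nfree > 0) {
    b = bsum / nfree;
  } else {
    double lo = -HUGE_VAL, hi = HUGE_VAL;
    for (int i = 0; i < n; ++i) {
      const double v = y[i] - f[i];
      const bool at_zero = alpha[i] <= SMO_TAU;
      // y=+1, alpha=0  => b >= 1 - f ; y=-1, alpha=0 => b <= -1 - f
      // y=+1, alpha=C  => b <= 1 - f ; y=-1, alpha=C => b >= -1 - f
      if ((y[i] > 0.0) == at_zero) { if (v > lo) lo = v; }
      else                         { if (v < hi) hi = v; }
    }
    if (std::isfinite(lo) && std::isfinite(hi)) b = 0.5 * (lo + hi);
    else if (std::isfinite(lo)) b = lo;
    else if (std::isfinite(hi)) b = hi;
    else b = 0.0;
  }
  *b_out = b;
  return it;
}

// [[Rcpp::export(name = ".smo_fit_cpp")]]
List smo_fit_cpp(NumericMatrix X, NumericVector y, double C,
                 double tol, int max_iter) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> xr((size_t)n * d), al(n), w(d), f(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j)
      xr[(size_t)i * d + j] = X(i, j);
  double b = 0.0;
  const int it = smo_solve(xr.data(), n, d, &y[0], C, tol, max_iter,
                           al.data(), w.data(), f.data(), &b);
  // primal objective 0.5*|w|^2 + C * sum(hinge)
  double obj = 0.0;
  for (int j = 0; j < d; ++j) obj += 0.5 * w[j] * w[j];
  for (int i = 0; i < n; ++i) {
    const double h = 1.0 - y[i] * (f[i] + b);
    if (h > 0.0) obj += C * h;
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = b,
                      _["alpha"] = NumericVector(al.begin(), al.end()),
                      _["iterations"] = it,
                      _["objective"] = obj);
}

// Gram-matrix SMO with second-order working-set selection (the fold
// engine of the exhaustive search). q holds the label-signed Gram matrix
// Q_ij = y_i y_j x_i.x_j of the training points; G is the dual gradient
// (Q alpha - 1). Returns the intercept b.
static double smo_gram(const double* q, const double* y, int n,
                       double C, double tol, int max_iter,
                       double* alpha, double* G) {
  // alpha may carry a warm start (e.g. the full-data solution restricted
  // to the training rows); clip to the box, repair the equality
  // constraint sum(alpha * y) = 0, and rebuild the gradient. A zero
  // alpha reduces to the cold start G = -1.
  double s = 0.0;
  bool any = false;
  for (int i = 0; i < n; ++i) {
    if (alpha[i] < 0.0) alpha[i] = 0.0;
    if (alpha[i] > C) alpha[i] = C;
    if (alpha[i] > 0.0) any = true;
    s += alpha[i] * y[i];
  }
  if (any && s != 0.0) {
    const double surplus = (s > 0.0) ? 1.0 : -1.0;
    for (int i = 0; i < n && s * surplus > 0.0; ++i) {
      if (y[i] == surplus && alpha[i] > 0.0) {
        const double d0 = (alpha[i] < s * surplus) ? alpha[i] : s * surplus;
        alpha[i] -= d0;
        s -= d0 * surplus;
      }
    }
  }
  for (int i = 0; i < n; ++i) G[i] = -1.0;
  if (any) {
    for (int j = 0; j < n; ++j) {
      if (alpha[j] <= 0.0) continue;
      const double aj = alpha[j];
      const double* qj = q + (size_t)j * n;
      for (int i = 0; i < n; ++i) G[i] += aj * qj[i];
    }
  }

  // shrinking working set: bound points that cannot currently violate the
  // KKT pair conditions are set aside; gradients of inactive points are
  // reconstructed before the final (full-set) convergence check.
  std::vector<int> act(n);
  std::vector<double> qd(n);
  for (int i = 0; i < n; ++i) act[i] = i;
  for (int i = 0; i < n; ++i) qd[i] = q[(size_t)i * n + i];
  int na = n;
  const int shrink_every = (n < 200) ? n : 200;
  int counter = shrink_every;

  for (int it = 0; it < max_iter; ++it) {
    const bool full = (na == n);
    // first-order pick of i over I_up (active set)
    double m = -HUGE_VAL;
    int i = -1;
    for (int a = 0; a < na; ++a) {
      const int r = full ? a : act[a];
      const bool up = (y[r] > 0.0) ? (alpha[r] < C) : (alpha[r] > 0.0);
      if (!up) continue;
      const double v = -y[r] * G[r];
      if (v > m) { m = v; i = r; }
    }
    // second-order pick of j over violating members of I_low; the gain
    // b^2/a is compared by cross-multiplication to avoid per-candidate
    // divisions.
    double M = HUGE_VAL, best_num = -1.0, best_den = 1.0;
    int j = -1;
    const double* qi = (i >= 0) ? q + (size_t)i * n : NULL;
    const double qii = (i >= 0) ? qi[i] : 0.0;
    const double yi = (i >= 0) ? y[i] : 0.0;
    for (int a = 0; a < na; ++a) {
      const int r = full ? a : act[a];
      const bool low = (y[r] > 0.0) ? (alpha[r] > 0.0) : (alpha[r] < C);
      if (!low) continue;
      const double v = -y[r] * G[r];
      if (v < M) M = v;
      if (i >= 0 && v < m) {
        const double bdf = m - v;
        double a2 = qii + qd[r] - 2.0 * yi * y[r] * qi[r];
        if (a2 <= 0.0) a2 = SMO_TAU;
        const double num = bdf * bdf;
        if (num * best_den > best_num * a2) {
          best_num = num; best_den = a2; j = r;
        }
      }
    }
    if (i < 0 || j < 0 || m - M < tol) {
      if (na == n) break;
      // reconstruct gradients of inactive points and recheck globally
      for (int r = 0; r < n; ++r) {
        bool active = false;
        for (int a = 0; a < na; ++a) if (act[a] == r) { active = true; break; }
        if (active) continue;
        double g = -1.0;
        const double* qr = q + (size_t)r * n;
        for (int s = 0; s < n; ++s)
          if (alpha[s] > 0.0) g += alpha[s] * qr[s];
        G[r] = g;
      }
      for (int r = 0; r < n; ++r) act[r] = r;
      na = n;
      counter = shrink_every;
      continue;
    }
    if (--counter == 0) {
      counter = shrink_every;
      // drop bound points that cannot pair-violate at the current (m, M)
      int keep = 0;
      for (int a = 0; a < na; ++a) {
        const int r = act[a];
        const bool up = (y[r] > 0.0) ? (alpha[r] < C) : (alpha[r] > 0.0);
        const bool low = (y[r] > 0.0) ? (alpha[r] > 0.0) : (alpha[r] < C);
        const double v = -y[r] * G[r];
        bool drop = false;
        if (up && !low) drop = (v <= M);
        else if (low && !up) drop = (v >= m);
        if (!drop) act[keep++] = r;
      }
      na = keep;
    }

    const double kii = qii, kjj = qd[j];
    const double kij = y[i] * y[j] * qi[j];
    const double gi = G[i], gj = G[j];
    const double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = kii + kjj - 2.0 * kij;
      if (quad <= 0.0) quad = SMO_TAU;
      const double delta = (-gi - gj) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0.0) { if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = diff; } }
      else            { if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = -diff; } }
      if (diff > 0.0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else            { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double quad = kii + kjj - 2.0 * kij;
      if (quad <= 0.0) quad = SMO_TAU;
      const double delta = (gi - gj) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = sum; } }
    }
    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    const double* qj = q + (size_t)j * n;
    if (na == n) {
      for (int r = 0; r < n; ++r) G[r] += dai * qi[r] + daj * qj[r];
    } else {
      for (int a = 0; a < na; ++a) {
        const int r = act[a];
        G[r] += dai * qi[r] + daj * qj[r];
      }
    }
  }
  // intercept from the KKT interval midpoint (equals -y_i G_i on free SVs)
  double m = -HUGE_VAL, M = HUGE_VAL;
  for (int r = 0; r < n; ++r) {
    const double v = -y[r] * G[r];
    const bool up = (y[r] > 0.0) ? (alpha[r] < C) : (alpha[r] > 0.0);
    const bool low = (y[r] > 0.0) ? (alpha[r] > 0.0) : (alpha[r] < C);
    if (up && v > m) m = v;
    if (low && v < M) M = v;
  }
  if (std::isfinite(m) && std::isfinite(M)) return 0.5 * (m + M);
  if (std::isfinite(m)) return m;
  if (std::isfinite(M)) return M;
  return 0.0;
}

// Confusion counts for one train/test split of the subset-restricted data.
// qfull: label-signed Gram of all n samples for the current subset.
// warm_mode: 0 = cold start, 1 = alpha_warm indexed by full-data row,
// 2 = alpha_warm already compacted to this fold's training rows.
static void fold_confusion(const double* xs, const double* yv, int n, int ds,
                           const double* qfull, const double* alpha_warm,
                           int warm_mode,
                           const int* fold_id, int test_fold,
                           double C, double tol, int max_iter,
                           int* tr_idx, double* qf, double* ytr,
                           double* alpha, double* G, double* w,
                           int* cm /* TP FN FP TN */) {
  int ntr = 0;
  for (int i = 0; i < n; ++i)
    if (fold_id[i] != test_fold) tr_idx[ntr++] = i;
  for (int a = 0; a < ntr; ++a) {
    const double* qrow = qfull + (size_t)tr_idx[a] * n;
    double* dst = qf + (size_t)a * ntr;
    for (int b2 = 0; b2 < ntr; ++b2) dst[b2] = qrow[tr_idx[b2]];
    ytr[a] = yv[tr_idx[a]];
    alpha[a] = (warm_mode == 1) ? alpha_warm[tr_idx[a]] :
               (warm_mode == 2) ? alpha_warm[a] : 0.0;
  }
  const double b = smo_gram(qf, ytr, ntr, C, tol, max_iter, alpha, G);
  for (int t = 0; t < ds; ++t) w[t] = 0.0;
  for (int a = 0; a < ntr; ++a) {
    if (alpha[a] <= SMO_TAU) continue;
    const double coef = alpha[a] * ytr[a];
    const double* xa = xs + (size_t)tr_idx[a] * ds;
    for (int t = 0; t < ds; ++t) w[t] += coef * xa[t];
  }
  cm[0] = cm[1] = cm[2] = cm[3] = 0;
  for (int i = 0; i < n; ++i) {
    if (fold_id[i] != test_fold) continue;
    const double* xi = xs + (size_t)i * ds;
    double dec = b;
    for (int t = 0; t < ds; ++t) dec += w[t] * xi[t];
    const int pred = (dec >= 0.0) ? 1 : -1;  // tie -> positive class
    if (yv[i] > 0.0) { if (pred > 0) ++cm[0]; else ++cm[1]; }
    else             { if (pred > 0) ++cm[2]; else ++cm[3]; }
  }
}

// label-signed Gram of the subset-restricted data
static void build_gram(const double* xs, const double* y, int n, int ds,
                       double* q) {
  for (int i = 0; i < n; ++i) {
    const double* xi = xs + (size_t)i * ds;
    for (int j = 0; j <= i; ++j) {
      const double* xj = xs + (size_t)j * ds;
      double dot = 0.0;
      for (int t = 0; t < ds; ++t) dot += xi[t] * xj[t];
      const double v = y[i] * y[j] * dot;
      q[(size_t)i * n + j] = v;
      q[(size_t)j * n + i] = v;
    }
  }
}

static inline double mcc_from_cm(const int* cm) {
  const double tp = cm[0], fn = cm[1], fp = cm[2], tn = cm[3];
  const double den = (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn);
  if (den <= 0.0) return 0.0;  // any zero factor: MCC defined as 0
  return (tp * tn - fp * fn) / std::sqrt(den);
}

static inline double bacc_from_cm(const int* cm) {
  const double tp = cm[0], fn = cm[1], fp = cm[2], tn = cm[3];
  const double sens = (tp + fn > 0) ? tp / (tp + fn) : NA_REAL;
  const double spec = (tn + fp > 0) ? tn / (tn + fp) : NA_REAL;
  return 0.5 * (sens + spec);
}

// Per-fold confusion cells for one channel subset.
// folds: n x repeats matrix of fold ids in 1..k.
// [[Rcpp::export(name = ".cv_confusion_cpp")]]
IntegerMatrix cv_confusion_cpp(NumericMatrix X, NumericVector y,
                               IntegerMatrix folds, IntegerVector subset,
                               double C, double tol, int max_iter) {
  const int n = X.nrow(), R = folds.ncol(), ds = subset.size();
  int k = 0;
  for (int r = 0; r < R; ++r)
    for (int i = 0; i < n; ++i)
      if (folds(i, r) > k) k = folds(i, r);

  std::vector<double> xs((size_t)n * ds), qfull((size_t)n * n),
      qf((size_t)n * n), ytr(n), alpha(n), G(n), w(ds), alpha_full(n);
  std::vector<int> tr_idx(n);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < ds; ++t)
      xs[(size_t)i * ds + t] = X(i, subset[t] - 1);
  build_gram(xs.data(), &y[0], n, ds, qfull.data());
  for (int i = 0; i < n; ++i) alpha_full[i] = 0.0;
  smo_gram(qfull.data(), &y[0], n, C, tol, max_iter, alpha_full.data(),
           G.data());

  IntegerMatrix out(R * k, 6);
  std::vector<int> fid(n);
  int row = 0, cm[4];
  for (int r = 0; r < R; ++r) {
    for (int i = 0; i < n; ++i) fid[i] = folds(i, r);
    for (int fd = 1; fd <= k; ++fd, ++row) {
      fold_confusion(xs.data(), &y[0], n, ds, qfull.data(),
                     alpha_full.data(), 1, fid.data(),
                     fd, C, tol, max_iter, tr_idx.data(), qf.data(),
                     ytr.data(), alpha.data(), G.data(), w.data(), cm);
      out(row, 0) = r + 1; out(row, 1) = fd;
      out(row, 2) = cm[0]; out(row, 3) = cm[1];
      out(row, 4) = cm[2]; out(row, 5) = cm[3];
    }
  }
  colnames(out) = CharacterVector::create("repeat", "fold", "TP", "FN",
                                          "FP", "TN");
  return out;
}

// Mean MCC / bACC over all folds for every subset, sharing one fold layout.
// [[Rcpp::export(name = ".cv_search_cpp")]]
NumericMatrix cv_search_cpp(NumericMatrix X, NumericVector y,
                            IntegerMatrix folds, List subsets,
                            double C, double tol, int max_iter) {
  const int n = X.nrow(), R = folds.ncol(), nsub = subsets.size();
  int k = 0;
  for (int r = 0; r < R; ++r)
    for (int i = 0; i < n; ++i)
      if (folds(i, r) > k) k = folds(i, r);
  const int nfolds = R * k;

  // pre-extract fold ids (column-contiguous)
  std::vector<int> fid((size_t)n * R);
  for (int r = 0; r < R; ++r)
    for (int i = 0; i < n; ++i)
      fid[(size_t)r * n + i] = folds(i, r);

  int dmax = 0;
  for (int s = 0; s < nsub; ++s) {
    const int ds = Rf_length(subsets[s]);
    if (ds > dmax) dmax = ds;
  }
  std::vector<double> xs((size_t)n * dmax), qfull((size_t)n * n),
      qf((size_t)n * n), ytr(n), alpha(n), G(n), w(dmax);
  std::vector<int> tr_idx(n);

  // Subsets are expected in prefix (preorder) order: each subset's parent
  // (the subset minus its largest channel) precedes it. A stack of
  // per-fold dual solutions lets every fold solve warm-start from the
  // same fold of the parent subset; since all subsets share one fold
  // layout, the training rows align exactly.
  std::vector<std::vector<int> > stk_sub;
  std::vector<std::vector<double> > stk_alpha;  // nfolds x n, fold-major

  NumericMatrix out(nsub, 2);
  int cm[4];
  for (int s = 0; s < nsub; ++s) {
    if ((s & 255) == 0) Rcpp::checkUserInterrupt();
    IntegerVector sub = subsets[s];
    const int ds = sub.size();
    std::vector<int> key(sub.begin(), sub.end());
    std::vector<int> parent(key.begin(), key.end() - 1);
    while (!stk_sub.empty() && stk_sub.back() != parent) {
      stk_sub.pop_back();
      stk_alpha.pop_back();
    }
    const bool have_parent = !stk_sub.empty();
    const double* par_alpha = have_parent ? stk_alpha.back().data() : NULL;

    for (int i = 0; i < n; ++i)
      for (int t = 0; t < ds; ++t)
        xs[(size_t)i * ds + t] = X(i, sub[t] - 1);
    build_gram(xs.data(), &y[0], n, ds, qfull.data());

    std::vector<double> cur_alpha((size_t)nfolds * n, 0.0);
    double mcc_sum = 0.0, bacc_sum = 0.0;
    int fc = 0;
    for (int r = 0; r < R; ++r) {
      const int* fr = fid.data() + (size_t)r * n;
      for (int fd = 1; fd <= k; ++fd, ++fc) {
        fold_confusion(xs.data(), &y[0], n, ds, qfull.data(),
                       have_parent ? par_alpha + (size_t)fc * n : NULL,
                       have_parent ? 2 : 0, fr, fd, C,
                       tol, max_iter, tr_idx.data(), qf.data(),
                       ytr.data(), alpha.data(), G.data(), w.data(), cm);
        mcc_sum += mcc_from_cm(cm);
        bacc_sum += bacc_from_cm(cm);
        std::memcpy(&cur_alpha[(size_t)fc * n], alpha.data(),
                    sizeof(double) * n);
      }
    }
    out(s, 0) = mcc_sum / nfolds;
    out(s, 1) = bacc_sum / nfolds;
    stk_sub.push_back(key);
    stk_alpha.push_back(std::move(cur_alpha));
  }
  colnames(out) = CharacterVector::create("mean_mcc", "mean_bacc");
  return out;
}
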