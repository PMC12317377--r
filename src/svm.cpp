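#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear C-SVC solved by SMO on the dual:
//   min 1/2 a'Qa - e'a,  0 <= a_i <= C,  y'a = 0,  Q_ij = y_i y_j x_i'x_j.
// Working pair selection is the maximal-violating-pair rule; for the
// fold-sized problems this package trains (<= a few dozen points) the loop
// converges in a handful of sweeps. Decision value f(x) = sum a_i y_i x_i'x + b;
// the class listed first (lowest index) takes label +1 and wins ties at f = 0
// strictly positive, matching the LIBSVM convention the tests cross-check.

static const double TAU = 1e-12;

struct BinarySVM {
  std::vector<double> alpha_y; // alpha_i * y_i
  double b;
};

static BinarySVM solve_binary(const std::vector<const double*>& X, int nfeat,
                              const std::vector<int>& y, double C,
                              double eps = 1e-3, int max_iter = 10000) {
  const int n = (int)X.size();
  // Gram matrix (tiny n, dense is fine)
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < nfeat; ++k) s += X[i][k] * X[j][k];
      K[(size_t)i * n + j] = K[(size_t)j * n + i] = s;
    }
  std::vector<double> alpha(n, 0.0), grad(n, -1.0); // grad of dual objective
  for (int it = 0; it < max_iter; ++it) {
    // maximal violating pair (i from I_up, j from I_low)
    int i = -1, j = -1;
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      if ((y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0)) {
        double v = -y[t] * grad[t];
        if (v > gmax) { gmax = v; i = t; }
      }
      if ((y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C)) {
        double v = -y[t] * grad[t];
        if (v < gmin) { gmin = v; j = t; }
      }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;
    // curvature along the feasible direction (u_i = y_i, u_j = -y_j):
    // the label signs cancel against Q = (yy') ∘ K
    double quad = K[(size_t)i * n + i] + K[(size_t)j * n + j]
                  - 2.0 * K[(size_t)i * n + j];
    if (quad <= 0) quad = TAU;
    double delta = (gmax - gmin) / quad;
    // clip to box along the constraint y_i a_i + y_j a_j = const
    double ai = alpha[i], aj = alpha[j];
    double di = y[i] * delta, dj = -y[j] * delta;
    double nai = ai + di, naj = aj + dj;
    double scale = 1.0;
    if (nai > C)  scale = std::min(scale, (C - ai) / di);
    if (nai < 0)  scale = std::min(scale, (0 - ai) / di);
    if (naj > C)  scale = std::min(scale, (C - aj) / dj);
    if (naj < 0)  scale = std::min(scale, (0 - aj) / dj);
    di *= scale; dj *= scale;
    alpha[i] += di; alpha[j] += dj;
    // snap to the box: alphas a rounding error away from a bound would
    // otherwise stay in the working set with a zero step and stall the loop
    if (alpha[i] < 1e-10) alpha[i] = 0.0;
    if (alpha[i] > C - 1e-10) alpha[i] = C;
    if (alpha[j] < 1e-10) alpha[j] = 0.0;
    if (alpha[j] > C - 1e-10) alpha[j] = C;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * di * K[(size_t)i * n + t] +
                         y[j] * dj * K[(size_t)j * n + t]);
  }
  // b from free SVs; fall back to midpoint of the active bounds
  double bsum = 0.0; int nfree = 0;
  double ub = HUGE_VAL, lb = -HUGE_VAL;
  for (int t = 0; t < n; ++t) {
    double yg = y[t] * grad[t]; // y_t * grad = f(x_t) - y_t ... (up to b)
    if (alpha[t] > TAU && alpha[t] < C - TAU) { bsum += -yg; ++nfree; }
    else {
      if ((y[t] == 1 && alpha[t] <= TAU) || (y[t] == -1 && alpha[t] >= C - TAU))
        ub = std::min(ub, -yg);
      else
        lb = std::max(lb, -yg);
    }
  }
  BinarySVM m;
  m.b = nfree > 0 ? bsum / nfree : (ub + lb) / 2.0;
  m.alpha_y.resize(n);
  for (int t = 0; t < n; ++t) m.alpha_y[t] = alpha[t] * y[t];
  return m;
}

static double decision_value(const BinarySVM& m,
                             const std::vector<const double*>& Xtr, int nfeat,
                             const double* x) {
  double f = m.b;
  for (size_t i = 0; i < m.alpha_y.size(); ++i) {
    if (m.alpha_y[i] == 0.0) continue;
    double s = 0.0;
    for (int k = 0; k < nfeat; ++k) s += Xtr[i][k] * x[k];
    f += m.alpha_y[i] * s;
  }
  return f;
}

// One-vs-one multiclass train + predict. Classes are the sorted unique values
// of y (1-based integer codes); vote ties go to the lowest class code.
// Returns integer class codes for the rows of Xtest.
// [[Rcpp::export]]
IntegerVector svc_train_predict(NumericMatrix Xtrain, IntegerVector ytrain,
                                NumericMatrix Xtest, double cost) {
  const int n = Xtrain.nrow(), p = Xtrain.ncol(), m = Xtest.nrow();
  // row pointers (copy rows into contiguous buffers)
  std::vector<std::vector<double>> trbuf(n, std::vector<double>(p));
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < p; ++k) trbuf[i][k] = Xtrain(i, k);
  std::vector<std::vector<double>> tebuf(m, std::vector<double>(p));
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < p; ++k) tebuf[i][k] = Xtest(i, k);

  std::vector<int> classes;
  for (int i = 0; i < n; ++i) {
    bool seen = false;
    for (int c : classes) if (c == ytrain[i]) { seen = true; break; }
    if (!seen) classes.push_back(ytrain[i]);
  }
  std::sort(classes.begin(), classes.end());
  const int nc = (int)classes.size();
  if (nc < 2) stop("training data must contain at least two classes");

  std::vector<std::vector<int>> votes(m, std::vector<int>(nc, 0));
  for (int a = 0; a < nc; ++a) {
    for (int bcl = a + 1; bcl < nc; ++bcl) {
      std::vector<const double*> Xs; std::vector<int> ys;
      for (int i = 0; i < n; ++i) {
        if (ytrain[i] == classes[a]) { Xs.push_back(trbuf[i].data()); ys.push_back(1); }
        else if (ytrain[i] == classes[bcl]) { Xs.push_back(trbuf[i].data()); ys.push_back(-1); }
      }
      BinarySVM mod = solve_binary(Xs, p, ys, cost);
      for (int i = 0; i < m; ++i) {
        double f = decision_value(mod, Xs, p, tebuf[i].data());
        if (f > 0) votes[i][a]++; else votes[i][bcl]++;
      }
    }
  }
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) {
    int best = 0;
    for (int c = 1; c < nc; ++c)
      if (votes[i][c] > votes[i][best]) best = c; // strict: ties keep lowest
    out[i] = classes[best];
  }
  return out;
}

// Permutation-null accuracies permuting event (trial) labels before
// condition averaging. Each iteration: average the event betas into one
// pattern per (run, condition) under the permuted labels, min-max scale each
// fold's training patterns to [-1, 1] (same map applied to the test run),
// train the linear C-SVC and count correct test classifications over all
// folds. `betas` must already be z-scored; `run` gives each event's run
// (1-based consecutive); `perms` is n_perm x n_events with label codes
// 1..n_classes (rows are within-run permutations, so every (run, condition)
// cell stays non-empty).
// [[Rcpp::export]]
NumericVector loro_event_null_accuracies(NumericMatrix betas,
                                         IntegerVector run,
                                         IntegerMatrix perms,
                                         int n_classes, double cost) {
  const int n_ev = betas.nrow(), V = betas.ncol();
  const int n_perm = perms.nrow();
  if (run.size() != n_ev) stop("run must have one entry per event");
  int n_runs = 0;
  for (int i = 0; i < n_ev; ++i) n_runs = std::max(n_runs, run[i]);
  const int k = n_classes, np = n_runs * k;

  // event-major copy of the betas so the accumulation loop is contiguous
  std::vector<double> B((size_t)n_ev * V);
  for (int e = 0; e < n_ev; ++e)
    for (int v = 0; v < V; ++v) B[(size_t)e * V + v] = betas(e, v);

  std::vector<double> M((size_t)np * V);
  std::vector<int> cnt(np);
  NumericVector out(n_perm);
  const int n_test = k, n_train = (n_runs - 1) * k;
  NumericMatrix Xtr(n_train, V), Xte(n_test, V);
  IntegerVector ytr(n_train);

  for (int pi = 0; pi < n_perm; ++pi) {
    std::fill(M.begin(), M.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int e = 0; e < n_ev; ++e) {
      int cell = (run[e] - 1) * k + (perms(pi, e) - 1);
      cnt[cell]++;
      double* row = &M[(size_t)cell * V];
      const double* src = &B[(size_t)e * V];
      for (int v = 0; v < V; ++v) row[v] += src[v];
    }
    for (int c = 0; c < np; ++c) {
      if (cnt[c] == 0) stop("empty (run, condition) cell in permutation");
      double* row = &M[(size_t)c * V];
      for (int v = 0; v < V; ++v) row[v] /= cnt[c];
    }
    int ncorrect = 0;
    for (int r = 0; r < n_runs; ++r) {
      // assemble train/test then per-voxel min-max scale fit on train
      int ti = 0;
      for (int r2 = 0; r2 < n_runs; ++r2) {
        if (r2 == r) continue;
        for (int c = 0; c < k; ++c) {
          double* row = &M[(size_t)(r2 * k + c) * V];
          for (int v = 0; v < V; ++v) Xtr(ti, v) = row[v];
          ytr[ti] = c + 1;
          ++ti;
        }
      }
      for (int c = 0; c < k; ++c) {
        double* row = &M[(size_t)(r * k + c) * V];
        for (int v = 0; v < V; ++v) Xte(c, v) = row[v];
      }
      for (int v = 0; v < V; ++v) {
        double lo = Xtr(0, v), hi = Xtr(0, v);
        for (int i = 1; i < n_train; ++i) {
          lo = std::min(lo, Xtr(i, v)); hi = std::max(hi, Xtr(i, v));
        }
        double rng = hi - lo;
        if (rng == 0) {
          for (int i = 0; i < n_train; ++i) Xtr(i, v) = 0.0;
          for (int i = 0; i < n_test; ++i) Xte(i, v) = 0.0;
        } else {
          for (int i = 0; i < n_train; ++i)
            Xtr(i, v) = (Xtr(i, v) - lo) / rng * 2.0 - 1.0;
          for (int i = 0; i < n_test; ++i)
            Xte(i, v) = (Xte(i, v) - lo) / rng * 2.0 - 1.0;
        }
      }
      IntegerVector pred = svc_train_predict(Xtr, ytr, Xte, cost);
      for (int c = 0; c < k; ++c) if (pred[c] == c + 1) ++ncorrect;
    }
    out[pi] = (double)ncorrect / (n_runs * k);
  }
  return out;
}

// Permutation-null accuracies for a fixed leave-one-run-out fold structure.
// fold_train / fold_test: lists of numeric matrices (rows = patterns, already
// scaled per fold); train_idx / test_idx: lists of integer vectors giving, for
// each fold, the positions (1-based) of its rows inside the full pattern set
// whose labels are being permuted. perms: n_perm x n_patterns matrix of
// label codes. Returns the overall test accuracy per permutation (equal class
// counts make this identical to the mean of per-condition accuracies).
// [[Rcpp::export]]
NumericVector loro_null_accuracies(List fold_train, List fold_test,
                                   List train_idx, List test_idx,
                                   IntegerMatrix perms, double cost) {
  const int nfold = fold_train.size();
  const int nperm = perms.nrow();
  // Pre-extract fold buffers
  std::vector<NumericMatrix> ftr(nfold), fte(nfold);
  std::vector<IntegerVector> itr(nfold), ite(nfold);
  int ntest_total = 0;
  for (int f = 0; f < nfold; ++f) {
    ftr[f] = as<NumericMatrix>(fold_train[f]);
    fte[f] = as<NumericMatrix>(fold_test[f]);
    itr[f] = as<IntegerVector>(train_idx[f]);
    ite[f] = as<IntegerVector>(test_idx[f]);
    ntest_total += fte[f].nrow();
  }
  NumericVector out(nperm);
  for (int pi = 0; pi < nperm; ++pi) {
    int ncorrect = 0;
    for (int f = 0; f < nfold; ++f) {
      const int ntr = ftr[f].nrow(), nte = fte[f].nrow();
      IntegerVector ytr(ntr), yte(nte);
      for (int i = 0; i < ntr; ++i) ytr[i] = perms(pi, itr[f][i] - 1);
      for (int i = 0; i < nte; ++i) yte[i] = perms(pi, ite[f][i] - 1);
      // skip degenerate folds where training has a single class: predict it
      bool onecls = true;
      for (int i = 1; i < ntr; ++i) if (ytr[i] != ytr[0]) { onecls = false; break; }
      if (onecls) {
        for (int i = 0; i < nte; ++i) if (yte[i] == ytr[0]) ++ncorrect;
        continue;
      }
      IntegerVector pred = svc_train_predict(ftr[f], ytr, fte[f], cost);
      for (int i = 0; i < nte; ++i) if (pred[i] == yte[i]) ++ncorrect;
    }
    out[pi] = (double)ncorrect / ntest_total;
  }
  return out;
}
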