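#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// C-SVC dual solver (SMO with maximal-violating-pair working set selection,
// libsvm-style stopping rule). Problems here are tiny (n <= a few dozen
// subjects), so a dense precomputed kernel and O(n) selection per iteration
// are fine.
//
// minimize 1/2 a'Qa - e'a  s.t.  y'a = 0, 0 <= a_i <= C,  Q_ij = y_i y_j K_ij.
static void solve_smo(const double *K, int n, const std::vector<int> &tr,
                      const std::vector<double> &y, double C,
                      std::vector<double> &alpha, double &rho) {
  const int m = (int)tr.size();
  const double eps = 1e-3;
  alpha.assign(m, 0.0);
  std::vector<double> G(m, -1.0); // gradient of the dual objective
  const int max_iter = 10000 * (m > 0 ? m : 1);

  double Gmax = 0.0, Gmin = 0.0;
  for (int iter = 0; iter < max_iter; ++iter) {
    Gmax = -HUGE_VAL;
    Gmin = HUGE_VAL;
    int i = -1, j = -1;
    for (int k = 0; k < m; ++k) {
      const bool up = (y[k] > 0 && alpha[k] < C) || (y[k] < 0 && alpha[k] > 0);
      const bool lo = (y[k] > 0 && alpha[k] > 0) || (y[k] < 0 && alpha[k] < C);
      const double v = -y[k] * G[k];
      if (up && v > Gmax) { Gmax = v; i = k; }
      if (lo && v < Gmin) { Gmin = v; j = k; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    const double Kii = K[tr[i] * n + tr[i]];
    const double Kjj = K[tr[j] * n + tr[j]];
    const double Kij = K[tr[i] * n + tr[j]];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 0) eta = 1e-12;

    // step t along the feasible direction da_i = y_i t, da_j = -y_j t
    double t = (Gmax - Gmin) / eta;
    const double tmax_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    const double tmax_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    if (t > tmax_i) t = tmax_i;
    if (t > tmax_j) t = tmax_j;
    const double dai = y[i] * t, daj = -y[j] * t;
    alpha[i] += dai;
    alpha[j] += daj;
    for (int k = 0; k < m; ++k) {
      const double Qki = y[k] * y[i] * K[tr[k] * n + tr[i]];
      const double Qkj = y[k] * y[j] * K[tr[k] * n + tr[j]];
      G[k] += Qki * dai + Qkj * daj;
    }
  }

  // offset: rho = y_k G_k on free vectors, midpoint of the KKT gap otherwise
  double sum = 0.0;
  int nfree = 0;
  for (int k = 0; k < m; ++k) {
    if (alpha[k] > 0 && alpha[k] < C) { sum += y[k] * G[k]; ++nfree; }
  }
  rho = (nfree > 0) ? sum / nfree : -(Gmax + Gmin) / 2.0;
}

// Per-fold RBF kernels under leave-one-out standardization.  Standardizing
// columns by the training fold's mean/sd leaves pairwise distances dependent
// only on the fold's column sds (means cancel), so each fold needs one
// weighted distance matrix; zero-variance training columns get weight 0,
// matching the "map constant columns to 0" rule.
static void fold_kernel(const double *X, int n, int V, int hold, double gamma,
                        std::vector<double> &K) {
  std::vector<double> w(V);
  const int m = n - 1;
  for (int v = 0; v < V; ++v) {
    const double *col = X + (size_t)v * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      if (i != hold) s += col[i];
    const double mu = s / m;
    double ss = 0.0;
    for (int i = 0; i < n; ++i)
      if (i != hold) { const double d = col[i] - mu; ss += d * d; }
    const double var = ss / (m - 1);
    const double tol = 1e-12 * (1.0 + std::fabs(mu));
    w[v] = (var <= tol * tol) ? 0.0 : 1.0 / var;
  }
  K.assign((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double d2 = 0.0;
      for (int v = 0; v < V; ++v) {
        const double *col = X + (size_t)v * n;
        const double d = col[i] - col[j];
        d2 += w[v] * d * d;
      }
      const double k = std::exp(-gamma * d2);
      K[(size_t)i * n + j] = k;
      K[(size_t)j * n + i] = k;
    }
  }
}

// Predict the held-out subject of fold `hold` for labels y (+/-1).
// Ties in the decision value go to class -1 (the lower label index).
static int predict_fold(const std::vector<double> &K, int n, int hold,
                        const std::vector<double> &yfull, double C) {
  std::vector<int> tr;
  tr.reserve(n - 1);
  std::vector<double> ytr;
  ytr.reserve(n - 1);
  for (int i = 0; i < n; ++i)
    if (i != hold) { tr.push_back(i); ytr.push_back(yfull[i]); }
  std::vector<double> alpha;
  double rho;
  solve_smo(K.data(), n, tr, ytr, C, alpha, rho);
  double dec = -rho;
  for (size_t k = 0; k < tr.size(); ++k)
    dec += alpha[k] * ytr[k] * K[(size_t)tr[k] * n + hold];
  return dec > 0 ? 1 : -1;
}

static double loocv_core(const std::vector<std::vector<double>> &Ks, int n,
                         const std::vector<double> &y, double C) {
  int correct = 0;
  for (int h = 0; h < n; ++h)
    if (predict_fold(Ks[h], n, h, y, C) == (y[h] > 0 ? 1 : -1)) ++correct;
  return (double)correct / n;
}

static void all_fold_kernels(const double *X, int n, int V, double gamma,
                             std::vector<std::vector<double>> &Ks) {
  Ks.resize(n);
  for (int h = 0; h < n; ++h) fold_kernel(X, n, V, h, gamma, Ks[h]);
}

static std::vector<double> pm1(const IntegerVector &y) {
  std::vector<double> out(y.size());
  for (int i = 0; i < y.size(); ++i) out[i] = y[i] == 0 ? -1.0 : 1.0;
  return out;
}

// [[Rcpp::export]]
double cpp_loocv_accuracy(NumericMatrix X, IntegerVector y, double C,
                          double gamma) {
  const int n = X.nrow(), V = X.ncol();
  const double g = gamma > 0 ? gamma : 1.0 / V;
  std::vector<std::vector<double>> Ks;
  all_fold_kernels(X.begin(), n, V, g, Ks);
  return loocv_core(Ks, n, pm1(y), C);
}

// Label-permutation accuracies with the fold kernels computed once (they do
// not depend on labels).  perms: n_perm x n matrix of 0-based permutations.
// [[Rcpp::export]]
NumericVector cpp_loocv_perm(NumericMatrix X, IntegerVector y, double C,
                             double gamma, IntegerMatrix perms) {
  const int n = X.nrow(), V = X.ncol();
  const double g = gamma > 0 ? gamma : 1.0 / V;
  std::vector<std::vector<double>> Ks;
  all_fold_kernels(X.begin(), n, V, g, Ks);
  const std::vector<double> y0 = pm1(y);
  NumericVector out(perms.nrow());
  std::vector<double> yp(n);
  for (int r = 0; r < perms.nrow(); ++r) {
    for (int i = 0; i < n; ++i) yp[i] = y0[perms(r, i)];
    out[r] = loocv_core(Ks, n, yp, C);
  }
  return out;
}

// Whole-mask searchlight: LOOCV accuracy of the sphere centered at every
// mask voxel.  vols is a 4D array (x,y,z,subject); offsets are 0-based voxel
// offsets; gamma <= 0 resolves to 1/V per sphere.  resid_proj, if given, is
// the n x n residual-maker matrix of the covariate design, applied to each
// sphere's feature matrix before classification.
// [[Rcpp::export]]
NumericVector cpp_searchlight(NumericVector vols, IntegerVector vdim,
                              LogicalVector mask, IntegerMatrix offsets,
                              IntegerVector y, double C, double gamma,
                              bool drop_partial,
                              Nullable<NumericMatrix> resid_proj) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2], n = vdim[3];
  const size_t nvox = (size_t)nx * ny * nz;
  const int K = offsets.nrow();
  NumericVector out(nvox, NA_REAL);
  const bool proj = resid_proj.isNotNull();
  NumericMatrix P;
  if (proj) P = resid_proj.get();
  const std::vector<double> yv = pm1(y);

  std::vector<double> X((size_t)n * K), Xr;
  std::vector<int> members(K);
  std::vector<std::vector<double>> Ks;

  for (int z = 0; z < nz; ++z)
    for (int yy = 0; yy < ny; ++yy)
      for (int x = 0; x < nx; ++x) {
        const size_t c = (size_t)x + (size_t)nx * (yy + (size_t)ny * z);
        if (!mask[c]) continue;
        int V = 0;
        for (int k = 0; k < K; ++k) {
          const int ox = x + offsets(k, 0), oy = yy + offsets(k, 1),
                    oz = z + offsets(k, 2);
          if (ox < 0 || oy < 0 || oz < 0 || ox >= nx || oy >= ny || oz >= nz)
            continue;
          const size_t idx = (size_t)ox + (size_t)nx * (oy + (size_t)ny * oz);
          if (mask[idx]) members[V++] = (int)idx;
        }
        if (drop_partial && V < K) continue;
        for (int v = 0; v < V; ++v) {
          const double *src = vols.begin() + (size_t)members[v];
          for (int s = 0; s < n; ++s) X[(size_t)v * n + s] = src[nvox * s];
        }
        const double *Xp = X.data();
        if (proj) { // residualize each feature on the covariates
          Xr.assign((size_t)n * V, 0.0);
          for (int v = 0; v < V; ++v)
            for (int i = 0; i < n; ++i) {
              double acc = 0.0;
              for (int s = 0; s < n; ++s) acc += P(i, s) * X[(size_t)v * n + s];
              Xr[(size_t)v * n + i] = acc;
            }
          Xp = Xr.data();
        }
        const double g = gamma > 0 ? gamma : 1.0 / V;
        all_fold_kernels(Xp, n, V, g, Ks);
        out[c] = loocv_core(Ks, n, yv, C);
      }
  return out;
}
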