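// k-nearest-neighbor information estimators (max norm, brute force).
//
// All estimators share the same neighborhood convention:
//  * distances are Chebyshev (max-norm) over the embedding columns;
//  * eps_i is the distance from point i to its k-th nearest neighbor in the
//    JOINT space, excluding i itself and any j with |i - j| <= theiler
//    (Theiler window against serial-correlation leakage);
//  * marginal/subspace counts are of points STRICTLY inside eps_i, with the
//    same exclusions.
// Brute-force O(n^2) search with a running k-best selection is deliberate:
// n per trial is a few thousand and k is tiny, where the scan beats tree
// structures.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// running k-best container: best[0] always holds the current maximum
struct KBest {
  std::vector<double> d;
  int k, filled;
  explicit KBest(int kk) : d(kk), k(kk), filled(0) {}
  void reset() { filled = 0; }
  inline void offer(double dist) {
    if (filled < k) {
      d[filled++] = dist;
      if (filled == k) {  // move max to front
        int mx = 0;
        for (int i = 1; i < k; ++i) if (d[i] > d[mx]) mx = i;
        std::swap(d[0], d[mx]);
      }
    } else if (dist < d[0]) {
      d[0] = dist;
      int mx = 0;
      for (int i = 1; i < k; ++i) if (d[i] > d[mx]) mx = i;
      std::swap(d[0], d[mx]);
    }
  }
  inline double kth() const { return d[0]; }
};

// max-norm distance between rows i and j of an n x p column-major array
static inline double row_dist(const double *x, int n, int p, int i, int j) {
  double m = std::fabs(x[i] - x[j]);
  for (int c = 1; c < p; ++c) {
    double dd = std::fabs(x[i + c * n] - x[j + c * n]);
    if (dd > m) m = dd;
  }
  return m;
}

// KSG algorithm-1 mutual information between the row spaces of xm and ym.
// Returns the estimate in nats.
// [[Rcpp::export(name = ".ksg_mi_cpp")]]
double ksg_mi_cpp(NumericMatrix xm, NumericMatrix ym, int k, int theiler) {
  const int n = xm.nrow();
  if (ym.nrow() != n) stop("row mismatch");
  const int px = xm.ncol(), py = ym.ncol();
  const double *x = REAL(xm), *y = REAL(ym);
  std::vector<double> dx(n), dy(n);
  KBest kb(k);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    kb.reset();
    int adm = 0;
    for (int j = 0; j < n; ++j) {
      double ax = row_dist(x, n, px, i, j);
      double ay = row_dist(y, n, py, i, j);
      dx[j] = ax;
      dy[j] = ay;
      if (j != i && std::abs(i - j) > theiler) {
        ++adm;
        kb.offer(ax > ay ? ax : ay);
      }
    }
    if (adm < k) stop("too few admissible neighbors; reduce k or theiler");
    const double eps = kb.kth();
    int nx = 0, ny = 0;
    const int lo = i - theiler, hi = i + theiler;
    for (int j = 0; j < n; ++j) {
      if (j >= lo && j <= hi) continue;
      if (dx[j] < eps) ++nx;
      if (dy[j] < eps) ++ny;
    }
    acc += R::digamma((double)nx + 1.0) + R::digamma((double)ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// Frenzel-Pompe / KSG-style conditional mutual information I(A; B | Z),
// rows of am, bm, zm aligned in time. Returns nats.
// [[Rcpp::export(name = ".fp_cmi_cpp")]]
double fp_cmi_cpp(NumericMatrix am, NumericMatrix bm, NumericMatrix zm,
                  int k, int theiler) {
  const int n = am.nrow();
  if (bm.nrow() != n || zm.nrow() != n) stop("row mismatch");
  const int pa = am.ncol(), pb = bm.ncol(), pz = zm.ncol();
  const double *a = REAL(am), *b = REAL(bm), *z = REAL(zm);
  std::vector<double> da(n), db(n), dz(n);
  KBest kb(k);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    kb.reset();
    int adm = 0;
    for (int j = 0; j < n; ++j) {
      double va = row_dist(a, n, pa, i, j);
      double vb = row_dist(b, n, pb, i, j);
      double vz = row_dist(z, n, pz, i, j);
      da[j] = va; db[j] = vb; dz[j] = vz;
      if (j != i && std::abs(i - j) > theiler) {
        ++adm;
        double m = va > vb ? va : vb;
        if (vz > m) m = vz;
        kb.offer(m);
      }
    }
    if (adm < k) stop("too few admissible neighbors; reduce k or theiler");
    const double eps = kb.kth();
    int naz = 0, nbz = 0, nz = 0;
    const int lo = i - theiler, hi = i + theiler;
    for (int j = 0; j < n; ++j) {
      if (j >= lo && j <= hi) continue;
      if (dz[j] < eps) {
        ++nz;
        if (da[j] < eps) ++naz;
        if (db[j] < eps) ++nbz;
      }
    }
    acc += R::digamma((double)nz + 1.0) - R::digamma((double)naz + 1.0) -
           R::digamma((double)nbz + 1.0);
  }
  return R::digamma((double)k) + acc / n;
}

// Ragwitz local-constant predictor error over a (d, tau) grid.
// For each candidate embedding, predicts s[t+1] as the mean successor of the
// k nearest embedded states (Theiler-excluded leave-one-out) and accumulates
// squared error over a common set of query times, so all grid cells are
// scored on identical targets. Returns an MSE matrix [length(ds) x length(taus)].
// [[Rcpp::export(name = ".ragwitz_grid_cpp")]]
List ragwitz_grid_cpp(NumericVector s, IntegerVector ds,
                               IntegerVector taus, int k, int theiler,
                               int nquery) {
  const int n = s.size();
  int dmax = 0, taumax = 0;
  for (int a = 0; a < ds.size(); ++a) dmax = std::max(dmax, ds[a]);
  for (int b = 0; b < taus.size(); ++b) taumax = std::max(taumax, taus[b]);
  const int tmin = (dmax - 1) * taumax;      // first query time (0-based)
  const int tlast = n - 2;                   // must have successor s[t+1]
  if (tlast < tmin + k) stop("series too short for requested embedding grid");

  // common query times, evenly spaced
  std::vector<int> queries;
  const int span = tlast - tmin + 1;
  const int nq = std::min(nquery, span);
  for (int q = 0; q < nq; ++q)
    queries.push_back(tmin + (int)((double)q * span / nq));

  NumericMatrix mse(ds.size(), taus.size());
  NumericMatrix sdse(ds.size(), taus.size());  // SD of the squared errors
  std::vector<double> bestd(k), bests(k);

  for (int a = 0; a < ds.size(); ++a) {
    for (int b = 0; b < taus.size(); ++b) {
      const int d = ds[a], tau = taus[b];
      const int t0 = (d - 1) * tau;  // earliest valid state index
      double err = 0.0, err2 = 0.0;
      for (size_t qi = 0; qi < queries.size(); ++qi) {
        const int t = queries[qi];
        int found = 0;
        for (int u = t0; u <= tlast; ++u) {
          if (std::abs(u - t) <= theiler) continue;
          double dist = 0.0;
          for (int c = 0; c < d; ++c) {
            double dd = std::fabs(s[t - c * tau] - s[u - c * tau]);
            if (dd > dist) dist = dd;
          }
          if (found < k) {
            bestd[found] = dist;
            bests[found] = s[u + 1];
            ++found;
            if (found == k) {  // move max to front
              int mx = 0;
              for (int x = 1; x < k; ++x) if (bestd[x] > bestd[mx]) mx = x;
              std::swap(bestd[0], bestd[mx]);
              std::swap(bests[0], bests[mx]);
            }
          } else if (dist < bestd[0]) {
            bestd[0] = dist;
            bests[0] = s[u + 1];
            int mx = 0;
            for (int x = 1; x < k; ++x) if (bestd[x] > bestd[mx]) mx = x;
            std::swap(bestd[0], bestd[mx]);
            std::swap(bests[0], bests[mx]);
          }
        }
        if (found < k) stop("too few neighbors for Ragwitz predictor");
        double pred = 0.0;
        for (int x = 0; x < k; ++x) pred += bests[x];
        pred /= k;
        double e = s[t + 1] - pred;
        err += e * e;
        err2 += e * e * e * e;
      }
      const double nq2 = (double)queries.size();
      mse(a, b) = err / nq2;
      double v = err2 / nq2 - mse(a, b) * mse(a, b);
      sdse(a, b) = v > 0 ? std::sqrt(v) : 0.0;
    }
  }
  return List::create(Named("mse") = mse, Named("sdse") = sdse);
}

// Bivariate coupled AR recursion; innovations are supplied from R so that
// reproducibility is governed by R's RNG. Returns cbind(x, y) after burn-in.
// [[Rcpp::export(name = ".sim_coupled_ar_cpp")]]
NumericMatrix sim_coupled_ar_cpp(NumericVector ex, NumericVector ey,
                                 double ax, double ay, double cxy, double cyx,
                                 int lag, int burn) {
  const int total = ex.size();
  if (ey.size() != total) stop("innovation length mismatch");
  const int n = total - burn;
  std::vector<double> x(total, 0.0), y(total, 0.0);
  for (int t = 0; t < total; ++t) {
    double xp = (t >= 1) ? x[t - 1] : 0.0;
    double yp = (t >= 1) ? y[t - 1] : 0.0;
    double xl = (t >= lag) ? x[t - lag] : 0.0;
    double yl = (t >= lag) ? y[t - lag] : 0.0;
    x[t] = ax * xp + cyx * yl + ex[t];
    y[t] = ay * yp + cxy * xl + ey[t];
  }
  NumericMatrix out(n, 2);
  for (int t = 0; t < n; ++t) {
    out(t, 0) = x[burn + t];
    out(t, 1) = y[burn + t];
  }
  return out;
}
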