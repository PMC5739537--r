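#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Deterministic Partitioning Around Medoids on a precomputed distance
// matrix: classic BUILD initialization followed by SWAP to a local
// optimum. Ties break toward the lowest index, so results are exactly
// reproducible. 0-based internally; returns 1-based indices.

// [[Rcpp::export(name = ".pam_cpp")]]
List pam_cpp(NumericMatrix D, int k, IntegerVector init = IntegerVector()) {
  const int n = D.nrow();
  if (k < 1 || k > n) stop("k out of range");
  const double* Dp = REAL(D);  // column-major: D(i, j) = Dp[i + (size_t)j * n]
#define DIJ(i, j) Dp[(i) + (size_t)(j) * n]
  std::vector<int> med;
  med.reserve(k);
  std::vector<bool> is_med(n, false);

  if (init.size() == k) {
    // caller-supplied starting medoids (1-based), SWAP only
    for (int m = 0; m < k; ++m) {
      const int j = init[m] - 1;
      if (j < 0 || j >= n || is_med[j]) stop("bad initial medoids");
      med.push_back(j);
      is_med[j] = true;
    }
  } else {
    // BUILD: first medoid minimizes total distance, then greedy additions
    {
      double best = std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += DIJ(i, j);
        if (s < best - 1e-12) { best = s; bi = j; }
      }
      med.push_back(bi);
      is_med[bi] = true;
    }
    std::vector<double> dnear(n);
    for (int i = 0; i < n; ++i) dnear[i] = D(i, med[0]);
    while ((int)med.size() < k) {
      double best_gain = -1.0;
      int bc = -1;
      for (int c = 0; c < n; ++c) {
        if (is_med[c]) continue;
        double gain = 0.0;
        for (int i = 0; i < n; ++i) {
          const double diff = dnear[i] - DIJ(i, c);
          if (diff > 0) gain += diff;
        }
        if (gain > best_gain + 1e-12) { best_gain = gain; bc = c; }
      }
      med.push_back(bc);
      is_med[bc] = true;
      for (int i = 0; i < n; ++i) {
        if (DIJ(i, bc) < dnear[i]) dnear[i] = DIJ(i, bc);
      }
    }
  }

  // SWAP: repeat the best (medoid, non-medoid) exchange while it lowers
  // cost. All k exchange gains for one candidate h are accumulated in a
  // single pass over the points (FastPAM1-style), so one iteration costs
  // O(n^2) regardless of k.
  std::vector<double> d1(n), d2(n);
  std::vector<int> n1(n);
  std::vector<double> Tm(k);
  for (int iter = 0; iter < 1000; ++iter) {
    for (int i = 0; i < n; ++i) {
      d1[i] = std::numeric_limits<double>::infinity();
      d2[i] = std::numeric_limits<double>::infinity();
      n1[i] = -1;
      for (int m = 0; m < (int)med.size(); ++m) {
        const double d = DIJ(i, med[m]);
        if (d < d1[i]) {
          d2[i] = d1[i];
          d1[i] = d;
          n1[i] = m;
        } else if (d < d2[i]) {
          d2[i] = d;
        }
      }
    }
    double bestT = -1e-12;
    int bm = -1, bh = -1;
    for (int h = 0; h < n; ++h) {
      if (is_med[h]) continue;
      double base = 0.0;  // shared term: h captures points from any medoid
      std::fill(Tm.begin(), Tm.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        const double dih = DIJ(i, h);
        const double cap = dih < d1[i] ? dih - d1[i] : 0.0;
        base += cap;
        // removing i's own medoid: i moves to min(d(i,h), d2[i])
        Tm[n1[i]] += ((dih < d2[i] ? dih : d2[i]) - d1[i]) - cap;
      }
      for (int m = 0; m < k; ++m) {
        const double T = base + Tm[m];
        if (T < bestT) { bestT = T; bm = m; bh = h; }
      }
    }
    if (bm < 0) break;
    is_med[med[bm]] = false;
    med[bm] = bh;
    is_med[bh] = true;
  }

  // final assignment (ties toward the lowest medoid position)
  IntegerVector clusters(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bi = 0;
    for (int m = 0; m < k; ++m) {
      const double d = DIJ(i, med[m]);
      if (d < best - 1e-12) { best = d; bi = m; }
    }
    clusters[i] = bi + 1;
  }
  double cost = 0.0;
  for (int i = 0; i < n; ++i) cost += DIJ(i, med[clusters[i] - 1]);
  IntegerVector medoids(k);
  for (int m = 0; m < k; ++m) medoids[m] = med[m] + 1;
  return List::create(_["medoids"] = medoids, _["clusters"] = clusters,
                      _["cost"] = cost);
#undef DIJ
}

// Hausdorff distances between point subsets of one shared point pool,
// given the pool's pairwise distance matrix and an index matrix (one row
// per set, k columns, 1-based). Used by the random-design baseline where
// every sampled mutation set draws its C-alpha points from the same
// surface.
// [[Rcpp::export(name = ".hausdorff_matrix_idx_cpp")]]
NumericMatrix hausdorff_matrix_idx_cpp(IntegerMatrix idx, NumericMatrix Dpool) {
  const int m = idx.nrow(), k = idx.ncol();
  const int np = Dpool.nrow();
  const double* P = REAL(Dpool);
  // flatten the 1-based index matrix row-major into 0-based offsets
  std::vector<int> I((size_t)m * k);
  for (int a = 0; a < m; ++a) {
    for (int p = 0; p < k; ++p) I[(size_t)a * k + p] = idx(a, p) - 1;
  }
  NumericMatrix H(m, m);
  double* Hp = REAL(H);
  for (int a = 0; a < m; ++a) {
    const int* ia = &I[(size_t)a * k];
    for (int b = a + 1; b < m; ++b) {
      const int* ib = &I[(size_t)b * k];
      double h = 0.0;
      for (int p = 0; p < k; ++p) {
        const double* col = P + (size_t)ia[p] * np;
        double mn = col[ib[0]];
        for (int q = 1; q < k; ++q) {
          const double d = col[ib[q]];
          if (d < mn) mn = d;
        }
        if (mn > h) h = mn;
      }
      for (int q = 0; q < k; ++q) {
        const double* col = P + (size_t)ib[q] * np;
        double mn = col[ia[0]];
        for (int p = 1; p < k; ++p) {
          const double d = col[ia[p]];
          if (d < mn) mn = d;
        }
        if (mn > h) h = mn;
      }
      Hp[a + (size_t)b * m] = h;
      Hp[b + (size_t)a * m] = h;
    }
  }
  return H;
}
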