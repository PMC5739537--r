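#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Directed Hausdorff term: max over rows of A of the min distance to B.
static double directed(const std::vector<double>& A, int na,
                       const std::vector<double>& B, int nb) {
  double worst = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = std::numeric_limits<double>::infinity();
    const double ax = A[3 * i], ay = A[3 * i + 1], az = A[3 * i + 2];
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B[3 * j];
      const double dy = ay - B[3 * j + 1];
      const double dz = az - B[3 * j + 2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    if (best > worst) worst = best;
  }
  return std::sqrt(worst);
}

static void flatten(const NumericMatrix& m, std::vector<double>& out) {
  const int n = m.nrow();
  out.resize(3 * n);
  for (int i = 0; i < n; ++i) {
    out[3 * i] = m(i, 0);
    out[3 * i + 1] = m(i, 1);
    out[3 * i + 2] = m(i, 2);
  }
}

// [[Rcpp::export(name = ".hausdorff_cpp")]]
double hausdorff_cpp(NumericMatrix A, NumericMatrix B) {
  std::vector<double> a, b;
  flatten(A, a);
  flatten(B, b);
  const double d1 = directed(a, A.nrow(), b, B.nrow());
  const double d2 = directed(b, B.nrow(), a, A.nrow());
  return d1 > d2 ? d1 : d2;
}

// [[Rcpp::export(name = ".hausdorff_matrix_cpp")]]
NumericMatrix hausdorff_matrix_cpp(List sets) {
  const int n = sets.size();
  std::vector<std::vector<double> > pts(n);
  std::vector<int> sizes(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = sets[i];
    sizes[i] = m.nrow();
    flatten(m, pts[i]);
  }
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d1 = directed(pts[i], sizes[i], pts[j], sizes[j]);
      const double d2 = directed(pts[j], sizes[j], pts[i], sizes[i]);
      const double h = d1 > d2 ? d1 : d2;
      D(i, j) = h;
      D(j, i) = h;
    }
  }
  return D;
}
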