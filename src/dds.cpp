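#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian KDE evaluated on a grid.  Bandwidth follows Scott's rule when
// h <= 0 is passed: h = sd(x) * n^(-1/5) (sample sd, n-1 denominator).
static void kde_eval_into(const double* x, int n, const double* grid, int g,
                          double h, double* out) {
  if (h <= 0.0) {
    double m = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) m += x[i];
    m /= n;
    for (int i = 0; i < n; ++i) { double d = x[i] - m; ss += d * d; }
    double sd = (n > 1) ? std::sqrt(ss / (n - 1)) : 0.0;
    h = sd * std::pow((double)n, -0.2);
  }
  if (h <= 0.0) stop("degenerate sample: zero standard deviation");
  const double inv_h = 1.0 / h;
  const double norm = inv_h / (n * std::sqrt(2.0 * M_PI));
  std::fill(out, out + g, 0.0);
  if (g >= 2 && grid[1] > grid[0]) {
    // Uniform grid: accumulate each sample's kernel only where it is
    // numerically non-zero (|z| <= 8.5 gives exp(-36) ~ 2e-16, below
    // double precision relative to the kernel peak).
    const double dx = (grid[g - 1] - grid[0]) / (g - 1);
    const double win = 8.5 * h;
    for (int i = 0; i < n; ++i) {
      int k0 = (int)std::ceil((x[i] - win - grid[0]) / dx);
      int k1 = (int)std::floor((x[i] + win - grid[0]) / dx);
      if (k0 < 0) k0 = 0;
      if (k1 > g - 1) k1 = g - 1;
      for (int k = k0; k <= k1; ++k) {
        double z = (grid[k] - x[i]) * inv_h;
        out[k] += std::exp(-0.5 * z * z);
      }
    }
    for (int k = 0; k < g; ++k) out[k] *= norm;
  } else {
    for (int k = 0; k < g; ++k) {
      double acc = 0.0;
      const double gk = grid[k];
      for (int i = 0; i < n; ++i) {
        double z = (gk - x[i]) * inv_h;
        acc += std::exp(-0.5 * z * z);
      }
      out[k] = acc * norm;
    }
  }
}

// [[Rcpp::export]]
NumericVector kde_eval_cpp(NumericVector x, NumericVector grid, double h) {
  NumericVector out(grid.size());
  kde_eval_into(x.begin(), x.size(), grid.begin(), grid.size(), h, out.begin());
  return out;
}

// DDS for one target level: sum_k |p_j1(grid_k) - p_j2(grid_k)| where the
// two KDEs are built from the samples labelled 0 and 1.  Bandwidths are
// recomputed per subset (Scott's rule), matching the treatment of the
// observed split so permutations stay exchangeable.
static double dds_level(const double* x, const int* lab, int n,
                        const double* grid, int g,
                        std::vector<double>& buf0, std::vector<double>& buf1,
                        std::vector<double>& d0, std::vector<double>& d1) {
  buf0.clear(); buf1.clear();
  for (int i = 0; i < n; ++i) {
    if (lab[i] == 0) buf0.push_back(x[i]); else buf1.push_back(x[i]);
  }
  if (buf0.size() < 2 || buf1.size() < 2)
    stop("each irrelevant-dimension level needs at least 2 samples");
  d0.resize(g); d1.resize(g);
  kde_eval_into(buf0.data(), buf0.size(), grid, g, -1.0, d0.data());
  kde_eval_into(buf1.data(), buf1.size(), grid, g, -1.0, d1.data());
  double s = 0.0;
  for (int k = 0; k < g; ++k) s += std::fabs(d0[k] - d1[k]);
  return s;
}

// DDS over permuted label assignments.  x1/x2: pooled decoded values at the
// two target-dimension levels; lab1/lab2: one column per relabelling (column
// 0 is the observed assignment), entries 0/1 coding the irrelevant-dimension
// level.  Returns one raw DDS per column.
// [[Rcpp::export]]
NumericVector dds_perm_cpp(NumericVector x1, IntegerMatrix lab1,
                           NumericVector x2, IntegerMatrix lab2,
                           NumericVector grid) {
  const int n1 = x1.size(), n2 = x2.size(), g = grid.size();
  if (lab1.nrow() != n1 || lab2.nrow() != n2)
    stop("label matrix rows must match sample counts");
  if (lab1.ncol() != lab2.ncol())
    stop("label matrices must have the same number of columns");
  const int S = lab1.ncol();
  NumericVector out(S);
  std::vector<double> buf0, buf1, d0, d1;
  buf0.reserve(n1 + n2); buf1.reserve(n1 + n2);
  for (int s = 0; s < S; ++s) {
    double v = dds_level(x1.begin(), &lab1(0, s), n1, grid.begin(), g,
                         buf0, buf1, d0, d1);
    v += dds_level(x2.begin(), &lab2(0, s), n2, grid.begin(), g,
                   buf0, buf1, d0, d1);
    out[s] = v;
  }
  return out;
}
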