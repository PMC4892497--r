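#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<double> dvec;

// Euclidean point distance after the affine time rescaling (x,y) -> (lambda*x, y)
static inline double ptd(double x1, double y1, double x2, double y2,
                         double lambda) {
  double dx = lambda * (x1 - x2), dy = y1 - y2;
  return std::sqrt(dx * dx + dy * dy);
}

// Full n x m dynamic-programming table (row-major).  Steps {(1,0),(0,1),(1,1)}.
// sum_mode aggregates costs by sum (DTW style), otherwise by max (Frechet).
static void dp_table(const double* px, const double* py, int n,
                     const double* qx, const double* qy, int m,
                     double lambda, bool sum_mode, dvec& dp) {
  dp.resize((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = ptd(px[i], py[i], qx[j], qy[j], lambda);
      if (i == 0 && j == 0) {
        dp[0] = c;
        continue;
      }
      double prev;
      if (i == 0)
        prev = dp[(size_t)j - 1];
      else if (j == 0)
        prev = dp[(size_t)(i - 1) * m];
      else
        prev = std::min(dp[(size_t)(i - 1) * m + j - 1],
                        std::min(dp[(size_t)(i - 1) * m + j],
                                 dp[(size_t)i * m + j - 1]));
      dp[(size_t)i * m + j] = sum_mode ? (c + prev) : std::max(c, prev);
    }
  }
}

// Distance only, two rolling rows: O(m) memory.
static double dp_dist(const double* px, const double* py, int n,
                      const double* qx, const double* qy, int m,
                      double lambda, bool sum_mode, dvec& r0, dvec& r1) {
  r0.resize(m);
  r1.resize(m);
  for (int j = 0; j < m; ++j) {
    double c = ptd(px[0], py[0], qx[j], qy[j], lambda);
    r0[j] = (j == 0) ? c : (sum_mode ? c + r0[j - 1] : std::max(c, r0[j - 1]));
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = ptd(px[i], py[i], qx[j], qy[j], lambda);
      double prev = (j == 0)
                        ? r0[0]
                        : std::min(r0[j - 1], std::min(r0[j], r1[j - 1]));
      r1[j] = sum_mode ? (c + prev) : std::max(c, prev);
    }
    std::swap(r0, r1);
  }
  return r0[m - 1];
}

// Recover one optimal coupling path from the full table.
// Tie-break: diagonal first, then advance the side with more points left.
static void backtrack(const dvec& dp, int n, int m, std::vector<int>& pi,
                      std::vector<int>& pj) {
  int i = n - 1, j = m - 1;
  pi.clear();
  pj.clear();
  pi.push_back(i);
  pj.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) {
      --j;
    } else if (j == 0) {
      --i;
    } else {
      double dd = dp[(size_t)(i - 1) * m + j - 1];
      double du = dp[(size_t)(i - 1) * m + j];
      double dl = dp[(size_t)i * m + j - 1];
      double mn = std::min(dd, std::min(du, dl));
      if (dd == mn) {
        --i;
        --j;
      } else if (du == mn && dl == mn) {
        if (i >= j) --i; else --j;
      } else if (du == mn) {
        --i;
      } else {
        --j;
      }
    }
    pi.push_back(i);
    pj.push_back(j);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
}

// [[Rcpp::export]]
List cpp_frechet(NumericVector px, NumericVector py, NumericVector qx,
                 NumericVector qy, double lambda, bool sum_mode,
                 bool want_path) {
  int n = px.size(), m = qx.size();
  dvec dp;
  if (!want_path) {
    dvec r0, r1;
    double d = dp_dist(px.begin(), py.begin(), n, qx.begin(), qy.begin(), m,
                       lambda, sum_mode, r0, r1);
    return List::create(_["distance"] = d);
  }
  dp_table(px.begin(), py.begin(), n, qx.begin(), qy.begin(), m, lambda,
           sum_mode, dp);
  std::vector<int> pi, pj;
  backtrack(dp, n, m, pi, pj);
  IntegerMatrix path(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    path(k, 0) = pi[k] + 1;
    path(k, 1) = pj[k] + 1;
  }
  return List::create(_["distance"] = dp[(size_t)n * m - 1],
                      _["path"] = path);
}

// Distance matrix between a set of trajectories and a set of centres.
// [[Rcpp::export]]
NumericMatrix cpp_cross_dist(List sx, List sy, List cx, List cy, double lambda,
                             bool sum_mode) {
  int n = sx.size(), k = cx.size();
  NumericMatrix out(n, k);
  dvec r0, r1;
  for (int i = 0; i < n; ++i) {
    NumericVector xi = sx[i], yi = sy[i];
    for (int j = 0; j < k; ++j) {
      NumericVector xj = cx[j], yj = cy[j];
      out(i, j) = dp_dist(xi.begin(), yi.begin(), xi.size(), xj.begin(),
                          yj.begin(), xj.size(), lambda, sum_mode, r0, r1);
    }
  }
  return out;
}

// Weighted mean of two curves along the optimal coupling; consecutive points
// whose averaged time does not increase are collapsed by averaging values.
static void mean_pair(const dvec& px, const dvec& py, double wp,
                      const dvec& qx, const dvec& qy, double wq, double lambda,
                      bool sum_mode, dvec& ox, dvec& oy) {
  dvec dp;
  dp_table(px.data(), py.data(), (int)px.size(), qx.data(), qy.data(),
           (int)qx.size(), lambda, sum_mode, dp);
  std::vector<int> pi, pj;
  backtrack(dp, (int)px.size(), (int)qx.size(), pi, pj);
  double W = wp + wq;
  ox.clear();
  oy.clear();
  int run = 1;
  for (size_t k = 0; k < pi.size(); ++k) {
    double x = (wp * px[pi[k]] + wq * qx[pj[k]]) / W;
    double y = (wp * py[pi[k]] + wq * qy[pj[k]]) / W;
    if (!ox.empty() && x <= ox.back()) {
      oy.back() = (oy.back() * run + y) / (run + 1);
      ++run;
    } else {
      ox.push_back(x);
      oy.push_back(y);
      run = 1;
    }
  }
}

// [[Rcpp::export]]
List cpp_mean_pair(NumericVector px, NumericVector py, double wp,
                   NumericVector qx, NumericVector qy, double wq,
                   double lambda, bool sum_mode) {
  dvec ox, oy;
  dvec p_x(px.begin(), px.end()), p_y(py.begin(), py.end());
  dvec q_x(qx.begin(), qx.end()), q_y(qy.begin(), qy.end());
  mean_pair(p_x, p_y, wp, q_x, q_y, wq, lambda, sum_mode, ox, oy);
  return List::create(_["times"] = wrap(ox), _["values"] = wrap(oy),
                      _["weight"] = wp + wq);
}

// Tournament ("randomAll") n-curve mean: curves taken in the supplied order,
// merged pairwise level by level; an odd leftover is carried to the next
// round unmerged.  Weights accumulate through the merges.
// [[Rcpp::export]]
List cpp_mean_tournament(List xs, List ys, NumericVector w, IntegerVector ord,
                         double lambda, bool sum_mode) {
  int n = ord.size();
  std::vector<dvec> cx(n), cy(n);
  dvec cw(n);
  for (int i = 0; i < n; ++i) {
    int o = ord[i] - 1;
    NumericVector xi = xs[o], yi = ys[o];
    cx[i].assign(xi.begin(), xi.end());
    cy[i].assign(yi.begin(), yi.end());
    cw[i] = w[o];
  }
  while (n > 1) {
    int out = 0;
    for (int i = 0; i + 1 < n; i += 2) {
      dvec ox, oy;
      mean_pair(cx[i], cy[i], cw[i], cx[i + 1], cy[i + 1], cw[i + 1], lambda,
                sum_mode, ox, oy);
      cx[out] = ox;
      cy[out] = oy;
      cw[out] = cw[i] + cw[i + 1];
      ++out;
    }
    if (n % 2 == 1) {  // leftover carried unmerged
      cx[out] = cx[n - 1];
      cy[out] = cy[n - 1];
      cw[out] = cw[n - 1];
      ++out;
    }
    n = out;
  }
  return List::create(_["times"] = wrap(cx[0]), _["values"] = wrap(cy[0]),
                      _["weight"] = cw[0]);
}
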