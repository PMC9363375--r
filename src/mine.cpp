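// Characteristic-matrix information coefficients (MICe / TICe).
//
// The estimator follows the equicharacteristic-matrix construction: for each
// grid shape (k, l) with k * l <= B(n), one axis is mass-equipartitioned and
// the other is optimised by dynamic programming over clump boundaries; the
// matrix entry is the maximal mutual information normalised by log2 min(k, l).
// MICe is the maximum entry, TICe the sum over all admissible shapes.  Both
// orientations are computed and the entrywise maximum taken, which makes the
// statistics symmetric in (x, y).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// Assign rows 0..l-1 to n values already sorted ascending, keeping tied
// values in the same row and targeting n/l points per row.
std::vector<int> equipartitionSorted(const std::vector<double>& ys, int l) {
  const int n = static_cast<int>(ys.size());
  std::vector<int> rows(n);
  int i = 0, curr = 0;
  double h = 0.0;
  double desired = static_cast<double>(n) / l;
  while (i < n) {
    int j = i;
    while (j < n && ys[j] == ys[i]) ++j;
    const int s = j - i;
    if (h > 0.0 && curr < l - 1 &&
        std::fabs(h + s - desired) >= std::fabs(h - desired)) {
      ++curr;
      h = 0.0;
      desired = static_cast<double>(n - i) / (l - curr);
    }
    for (int t = i; t < j; ++t) rows[t] = curr;
    h += s;
    i = j;
  }
  return rows;
}

// Merge an ordered sequence of clump masses into at most cmax groups while
// keeping each clump whole (mass equipartition over clumps).
std::vector<int> groupClumps(const std::vector<int>& mass, int cmax) {
  const int m = static_cast<int>(mass.size());
  int total = 0;
  for (int v : mass) total += v;
  std::vector<int> grp(m);
  int curr = 0, consumed = 0;
  double h = 0.0;
  double desired = static_cast<double>(total) / cmax;
  for (int i = 0; i < m; ++i) {
    const int s = mass[i];
    if (h > 0.0 && curr < cmax - 1 &&
        std::fabs(h + s - desired) >= std::fabs(h - desired)) {
      ++curr;
      h = 0.0;
      desired = static_cast<double>(total - consumed) / (cmax - curr);
    }
    grp[i] = curr;
    h += s;
    consumed += s;
  }
  return grp;
}

struct HalfResult {
  // entries[t][l]: t bins on the optimised axis, l on the equipartitioned one
  std::vector<std::vector<double>> entries;
  int B;
};

// Order of indices sorting v ascending (stable).
std::vector<int> orderOf(const std::vector<double>& v) {
  std::vector<int> idx(v.size());
  for (size_t i = 0; i < v.size(); ++i) idx[i] = static_cast<int>(i);
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return idx;
}

// Optimise the x axis against an equipartitioned y axis for every l.
HalfResult halfMatrix(const std::vector<double>& x,
                      const std::vector<double>& y, int B, double cfac) {
  const int n = static_cast<int>(x.size());
  HalfResult res;
  res.B = B;
  res.entries.assign(B + 1, std::vector<double>(B + 1, 0.0));

  const std::vector<int> ordX = orderOf(x);
  const std::vector<int> ordY = orderOf(y);
  std::vector<double> ySorted(n);
  for (int i = 0; i < n; ++i) ySorted[i] = y[ordY[i]];

  for (int l = 2; l <= B / 2; ++l) {
    const int kmax = B / l;
    if (kmax < 2) continue;

    // row of every point under the l-row equipartition of y
    std::vector<int> rowSorted = equipartitionSorted(ySorted, l);
    std::vector<int> row(n);
    for (int i = 0; i < n; ++i) row[ordY[i]] = rowSorted[i];

    // clumps along x: equal-x runs merged, then same-row pure runs merged
    std::vector<int> clumpOf(n);
    int m = 0;
    {
      int i = 0;
      int prevRow = -2;  // -1 marks a mixed (tied-x, multi-row) clump
      while (i < n) {
        int j = i;
        while (j < n && x[ordX[j]] == x[ordX[i]]) ++j;
        int r = row[ordX[i]];
        bool pure = true;
        for (int t = i + 1; t < j; ++t)
          if (row[ordX[t]] != r) { pure = false; break; }
        const int thisRow = pure ? r : -1;
        if (m == 0 || thisRow == -1 || prevRow == -1 || thisRow != prevRow) {
          ++m;
        }
        for (int t = i; t < j; ++t) clumpOf[t] = m - 1;  // by x-rank
        prevRow = thisRow;
        i = j;
      }
    }
    std::vector<int> mass(m, 0);
    for (int i = 0; i < n; ++i) mass[clumpOf[i]]++;

    const int cmax = std::max(kmax + 1, static_cast<int>(cfac * kmax));
    if (m > cmax) {
      std::vector<int> grp = groupClumps(mass, cmax);
      for (int i = 0; i < n; ++i) clumpOf[i] = grp[clumpOf[i]];
      m = grp.empty() ? 0 : grp[m - 1] + 1;
      // note: grp indexed by old clump id; recompute count
      int mm = 0;
      for (int i = 0; i < n; ++i) mm = std::max(mm, clumpOf[i] + 1);
      m = mm;
    }

    // cumulative row counts at clump boundaries: cum[j][r], j = 0..m
    std::vector<std::vector<int>> cum(m + 1, std::vector<int>(l, 0));
    {
      int j = 0;
      std::vector<int> acc(l, 0);
      for (int i = 0; i < n; ++i) {
        while (j < clumpOf[i]) {
          cum[j + 1] = acc;
          ++j;
        }
        acc[row[ordX[i]]]++;
      }
      while (j < m) {
        cum[j + 1] = acc;
        ++j;
      }
    }

    // fixed row-marginal entropy H(Q), in nats
    double hq = 0.0;
    for (int r = 0; r < l; ++r) {
      const int cr = cum[m][r];
      if (cr > 0) hq -= (static_cast<double>(cr) / n) *
                        std::log(static_cast<double>(cr) / n);
    }

    // interval weight w(a..b) over clumps a..b (1-based), scaled by 1/n
    auto w = [&](int a, int b) {
      double s = 0.0;
      int nn = 0;
      for (int r = 0; r < l; ++r) nn += cum[b][r] - cum[a - 1][r];
      if (nn == 0) return 0.0;
      for (int r = 0; r < l; ++r) {
        const int cr = cum[b][r] - cum[a - 1][r];
        if (cr > 0)
          s += cr * std::log(static_cast<double>(cr) / nn);
      }
      return s / n;
    };

    const int tmax = std::min(kmax, m);
    std::vector<std::vector<double>> G(tmax + 1,
                                       std::vector<double>(m + 1, -1e300));
    for (int j = 1; j <= m; ++j) G[1][j] = w(1, j);
    for (int t = 2; t <= tmax; ++t)
      for (int j = t; j <= m; ++j) {
        double best = -1e300;
        for (int s = t - 1; s < j; ++s) {
          const double v = G[t - 1][s] + w(s + 1, j);
          if (v > best) best = v;
        }
        G[t][j] = best;
      }

    double runMax = 0.0;  // best I (bits) over <= t x-bins
    for (int t = 2; t <= kmax; ++t) {
      if (t <= tmax) {
        const double ibits = (hq + G[t][m]) / M_LN2;
        if (ibits > runMax) runMax = ibits;
      }
      const double denom = std::log2(static_cast<double>(std::min(t, l)));
      res.entries[t][l] = runMax / denom;
    }
  }
  return res;
}

struct MineOut {
  double mice;
  double tice;
};

int gridBound(int n, double alpha, int bOverride) {
  if (bOverride > 0) return std::max(4, bOverride);
  int B = static_cast<int>(std::floor(std::pow(static_cast<double>(n), alpha)));
  if (B < 4) B = 4;
  return B;
}

// combined symmetric characteristic entries; entry [k][l] for k x-bins,
// l y-bins (both >= 2, k*l <= B)
std::vector<std::vector<double>> combinedMatrix(const std::vector<double>& x,
                                                const std::vector<double>& y,
                                                int B, double cfac) {
  HalfResult hx = halfMatrix(x, y, B, cfac);
  HalfResult hy = halfMatrix(y, x, B, cfac);
  // M[k][l] = max over orientations: k x-bins optimised vs l y-bins
  // equipartitioned (hx), or l y-bins optimised vs k x-bins equipartitioned
  // (hy with its axes swapped).
  std::vector<std::vector<double>> M(B + 1, std::vector<double>(B + 1, 0.0));
  for (int k = 2; k <= B; ++k)
    for (int l = 2; l <= B; ++l) {
      if (k * l > B) continue;
      M[k][l] = std::max(hx.entries[k][l], hy.entries[l][k]);
    }
  return M;
}

MineOut mineStat(const std::vector<double>& x, const std::vector<double>& y,
                 double alpha, double cfac, int bMax) {
  const int n = static_cast<int>(x.size());
  const int B = gridBound(n, alpha, bMax);
  std::vector<std::vector<double>> M = combinedMatrix(x, y, B, cfac);
  MineOut out{0.0, 0.0};
  for (int k = 2; k <= B; ++k)
    for (int l = 2; l <= B; ++l) {
      if (k * l > B) continue;
      out.tice += M[k][l];
      if (M[k][l] > out.mice) out.mice = M[k][l];
    }
  return out;
}

std::vector<double> asStd(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

}  // namespace

// [[Rcpp::export(name = ".cpp_mine")]]
List cpp_mine(NumericVector x, NumericVector y, double alpha, double cfac,
              int bMax) {
  MineOut out = mineStat(asStd(x), asStd(y), alpha, cfac, bMax);
  return List::create(_["mice"] = out.mice, _["tice"] = out.tice);
}

// [[Rcpp::export(name = ".cpp_char_matrix")]]
NumericMatrix cpp_char_matrix(NumericVector x, NumericVector y, double alpha,
                              double cfac, int bMax) {
  const int n = x.size();
  const int B = gridBound(n, alpha, bMax);
  std::vector<std::vector<double>> M =
      combinedMatrix(asStd(x), asStd(y), B, cfac);
  NumericMatrix out(B + 1, B + 1);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int k = 2; k <= B; ++k)
    for (int l = 2; l <= B; ++l)
      if (k * l <= B) out(k, l) = M[k][l];
  return out;
}

// [[Rcpp::export(name = ".cpp_equipartition")]]
IntegerVector cpp_equipartition(NumericVector y, int l) {
  const int n = y.size();
  std::vector<double> yv = asStd(y);
  std::vector<int> ord = orderOf(yv);
  std::vector<double> ys(n);
  for (int i = 0; i < n; ++i) ys[i] = yv[ord[i]];
  std::vector<int> rowsSorted = equipartitionSorted(ys, l);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[ord[i]] = rowsSorted[i] + 1;
  return out;
}

// Batch TICe over many predictor columns and shared y permutations.
// perms is an n x nperm matrix of 1-based indices; column r of the result's
// permutation matrix uses y[perms[, r]] against every column of X.
// [[Rcpp::export(name = ".cpp_mine_batch")]]
List cpp_mine_batch(NumericMatrix X, NumericVector y, double alpha,
                    double cfac, int bMax, IntegerMatrix perms) {
  const int n = X.nrow(), p = X.ncol(), nperm = perms.ncol();
  std::vector<double> yv = asStd(y);
  NumericVector tice0(p), mice0(p);
  NumericMatrix ticePerm(p, nperm);
  std::vector<std::vector<double>> cols(p);
  for (int j = 0; j < p; ++j) {
    cols[j].resize(n);
    for (int i = 0; i < n; ++i) cols[j][i] = X(i, j);
  }
  for (int j = 0; j < p; ++j) {
    MineOut out = mineStat(cols[j], yv, alpha, cfac, bMax);
    tice0[j] = out.tice;
    mice0[j] = out.mice;
  }
  std::vector<double> yp(n);
  for (int r = 0; r < nperm; ++r) {
    for (int i = 0; i < n; ++i) yp[i] = yv[perms(i, r) - 1];
    for (int j = 0; j < p; ++j) {
      MineOut out = mineStat(cols[j], yp, alpha, cfac, bMax);
      ticePerm(j, r) = out.tice;
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["tice"] = tice0, _["mice"] = mice0,
                      _["tice_perm"] = ticePerm);
}
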