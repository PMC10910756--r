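#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// k nearest neighbours by Euclidean distance, brute force with partial
// selection. Ties broken by row index so results are deterministic.
// Returns 1-based n x k index matrix; self (the query row) is excluded.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix x, int k) {
  const int n = x.nrow(), d = x.ncol();
  if (k >= n) stop("k must be smaller than the number of rows");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = x(i, c) - x(j, c);
        s += diff * diff;
      }
      cand[m++] = std::make_pair(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int q = 0; q < k; ++q) out(i, q) = cand[q].second + 1;
  }
  return out;
}

// Jaccard similarity of k-NN sets for every directed edge (i -> knn(i)),
// deduplicated to undirected edges. Input is the 1-based matrix from cpp_knn.
// [[Rcpp::export]]
DataFrame cpp_jaccard_edges(IntegerMatrix knn) {
  const int n = knn.nrow(), k = knn.ncol();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    nb[i].resize(k);
    for (int j = 0; j < k; ++j) nb[i][j] = knn(i, j) - 1;
    std::sort(nb[i].begin(), nb[i].end());
  }
  std::vector<int> from, to;
  std::vector<double> w;
  std::vector<int> inter;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      int v = knn(i, j) - 1;
      if (v <= i) {
        // keep edge only if i is not in knn(v) (else it is emitted from v)
        if (std::binary_search(nb[v].begin(), nb[v].end(), i)) continue;
      }
      inter.clear();
      std::set_intersection(nb[i].begin(), nb[i].end(), nb[v].begin(),
                            nb[v].end(), std::back_inserter(inter));
      double ji = (double)inter.size() / (double)(2 * k - inter.size());
      from.push_back(i + 1);
      to.push_back(v + 1);
      w.push_back(ji);
    }
  }
  return DataFrame::create(_["from"] = from, _["to"] = to, _["weight"] = w);
}

// All unordered pairs (i < j) with Euclidean distance <= r, found with a
// uniform grid of cell size r. Distance boundary is inclusive.
// [[Rcpp::export]]
DataFrame cpp_close_pairs(NumericVector x, NumericVector y, double r) {
  const int n = x.size();
  std::vector<int> pi, pj;
  if (n > 1 && r > 0) {
    double xmin = *std::min_element(x.begin(), x.end());
    double ymin = *std::min_element(y.begin(), y.end());
    double xmax = *std::max_element(x.begin(), x.end());
    double ymax = *std::max_element(y.begin(), y.end());
    int ncx = std::max(1, (int)((xmax - xmin) / r) + 1);
    int ncy = std::max(1, (int)((ymax - ymin) / r) + 1);
    std::vector<std::vector<int> > grid((size_t)ncx * ncy);
    std::vector<int> gx(n), gy(n);
    for (int i = 0; i < n; ++i) {
      gx[i] = std::min(ncx - 1, (int)((x[i] - xmin) / r));
      gy[i] = std::min(ncy - 1, (int)((y[i] - ymin) / r));
      grid[(size_t)gx[i] * ncy + gy[i]].push_back(i);
    }
    const double r2 = r * r;
    for (int i = 0; i < n; ++i) {
      for (int dx = -1; dx <= 1; ++dx) {
        int cx = gx[i] + dx;
        if (cx < 0 || cx >= ncx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int cy = gy[i] + dy;
          if (cy < 0 || cy >= ncy) continue;
          const std::vector<int> &cell = grid[(size_t)cx * ncy + cy];
          for (size_t q = 0; q < cell.size(); ++q) {
            int j = cell[q];
            if (j <= i) continue;
            double ddx = x[i] - x[j], ddy = y[i] - y[j];
            if (ddx * ddx + ddy * ddy <= r2) {
              pi.push_back(i + 1);
              pj.push_back(j + 1);
            }
          }
        }
      }
    }
  }
  return DataFrame::create(_["i"] = pi, _["j"] = pj);
}

// Distance from each query point to its nearest point in (xs, ys).
// self_idx (1-based, 0 = none) marks a set member to skip for that query.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericVector xq, NumericVector yq, NumericVector xs,
                          NumericVector ys, IntegerVector self_idx) {
  const int nq = xq.size(), ns = xs.size();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int skip = self_idx[i] - 1;
    for (int j = 0; j < ns; ++j) {
      if (j == skip) continue;
      double dx = xq[i] - xs[j], dy = yq[i] - ys[j];
      double s = dx * dx + dy * dy;
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -R_PosInf;
  z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher):
// for every pixel, squared distance in pixel units to the nearest TRUE pixel.
// All-FALSE input returns Inf everywhere. A large finite sentinel is used
// internally (Inf-Inf is NaN in the parabola intersection).
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e15;
  NumericMatrix d(nr, nc);
  std::vector<double> f(std::max(nr, nc)), o(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : BIG;
    dt1d(f, o, nr);
    for (int i = 0; i < nr; ++i) d(i, j) = o[i];
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d(i, j);
    dt1d(f, o, nc);
    for (int j = 0; j < nc; ++j) d(i, j) = (o[j] >= BIG) ? R_PosInf : o[j];
  }
  return d;
}

// Connected components of a binary raster, 8- (default) or 4-connectivity.
// Returns integer labels, 0 = background, components numbered from 1 in
// scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, bool conn8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            if (!conn8 && di != 0 && dj != 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
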