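#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Prominence of every candidate local maximum of a 2-D image by flood
// descent: pixels are visited in decreasing intensity order and merged
// into components with a union-find. When a component is absorbed by one
// with a higher peak at water level v, its prominence is peak - v (the
// height of its peak above the highest saddle connecting it to a higher
// maximum). Ties: a peak is dominated by an equal-height peak of earlier
// (column-major) index, so of two equal maxima the later one carries the
// saddle prominence; equal-value merges at the summit level itself are
// plateau joins, not separate maxima (prominence 0, dropped). The
// surviving root (global maximum) gets peak - min(image).
//
// Ties in intensity are ordered by linear index (column-major, i.e.
// row-major discovery within each column block) for determinism.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
DataFrame detect_prominent_maxima(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  const double* v = img.begin();
  std::stable_sort(ord.begin(), ord.end(), [v](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });

  std::vector<int> parent(n, -1);      // -1 = unprocessed
  std::vector<double> peak_val(n);     // per root
  std::vector<int> peak_idx(n);
  std::vector<double> prom(n, -1.0);   // assigned when absorbed
  std::vector<char> is_max(n, 0);
  // maxima of a component whose prominence is still undetermined; equal
  // peaks merged below their summit level stay pending together, because
  // each measures its prominence against strictly higher terrain
  std::vector<std::vector<int>> pending(n);

  const int droff[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dcoff[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int k = 0; k < n; ++k) {
    const int p = ord[k];
    const int r = p % nr, c = p / nr;
    const double vp = v[p];
    int roots[8];
    int nroots = 0;
    for (int d = 0; d < 8; ++d) {
      const int rr = r + droff[d], cc = c + dcoff[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int q = rr + cc * nr;
      if (parent[q] < 0) continue;  // not yet flooded
      const int root = find_root(parent, q);
      bool seen = false;
      for (int s = 0; s < nroots; ++s) if (roots[s] == root) { seen = true; break; }
      if (!seen) roots[nroots++] = root;
    }
    if (nroots == 0) {
      parent[p] = p;
      peak_val[p] = vp;
      peak_idx[p] = p;
      is_max[p] = 1;
      pending[p].push_back(p);
      continue;
    }
    // winner: highest peak, ties by earliest peak pixel in sort order
    int w = roots[0];
    for (int s = 1; s < nroots; ++s) {
      const int rt = roots[s];
      if (peak_val[rt] > peak_val[w] ||
          (peak_val[rt] == peak_val[w] && peak_idx[rt] < peak_idx[w])) {
        w = rt;
      }
    }
    parent[p] = w;
    for (int s = 0; s < nroots; ++s) {
      const int rt = roots[s];
      if (rt == w) continue;
      // absorbed by dominating terrain (higher peak, or equal peak with
      // earlier index): saddle at the current water level. A join at the
      // component's own summit level is a plateau, not a separate
      // maximum.
      for (int idx : pending[rt]) {
        prom[idx] = peak_val[rt] - vp;
        if (prom[idx] <= 0.0) is_max[idx] = 0;
      }
      pending[rt].clear();
      parent[rt] = w;
    }
  }

  const double vmin = v[ord[n - 1]];
  for (int i = 0; i < n; ++i) {
    // surviving roots: no higher terrain exists; floor at the global min
    if (parent[i] == i) {
      for (int idx : pending[i]) {
        if (prom[idx] < 0.0) prom[idx] = peak_val[i] - vmin;
      }
    }
  }
  std::vector<int> out_idx;
  std::vector<double> out_prom;
  for (int i = 0; i < n; ++i) {
    if (!is_max[i]) continue;
    const double pr = prom[i];
    if (pr <= 0.0) continue;  // plateau joins, constant image, undetermined
    out_idx.push_back(i);
    out_prom.push_back(pr);
  }

  const int m = out_idx.size();
  IntegerVector row(m), col(m);
  NumericVector val(m), prominence(m);
  for (int i = 0; i < m; ++i) {
    row[i] = out_idx[i] % nr + 1;   // 1-based for R
    col[i] = out_idx[i] / nr + 1;
    val[i] = v[out_idx[i]];
    prominence[i] = out_prom[i];
  }
  return DataFrame::create(_["row"] = row, _["col"] = col,
                           _["value"] = val, _["prominence"] = prominence);
}
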