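#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Graph-based image segmentation (Felzenszwalb-Huttenlocher): 8-connected
// pixel graph, edge weight = absolute intensity difference, greedy merging
// with the adaptive threshold int(C) + k/|C|, then a minimum-size sweep.

struct DisjointSet {
  std::vector<int> parent, rank_, size;
  DisjointSet(int n) : parent(n), rank_(n, 0), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  int join(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return a;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
    if (rank_[a] == rank_[b]) rank_[a]++;
    return a;
  }
};

struct GEdge { float w; int a, b; };

// [[Rcpp::export(name = ".cpp_felzenszwalb")]]
IntegerMatrix cpp_felzenszwalb(NumericMatrix img, double k, int min_size) {
  int nr = img.nrow(), nc = img.ncol();
  int n = nr * nc;
  std::vector<GEdge> edges;
  edges.reserve(4 * n);
  const int dr[4] = {0, 1, 1, 1};
  const int dc[4] = {1, 0, 1, -1};
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      for (int d = 0; d < 4; ++d) {
        int r2 = r + dr[d], c2 = c + dc[d];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        GEdge e;
        e.w = (float)std::fabs(img(r, c) - img(r2, c2));
        e.a = r + c * nr;
        e.b = r2 + c2 * nr;
        edges.push_back(e);
      }
    }
  }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const GEdge &x, const GEdge &y) { return x.w < y.w; });
  DisjointSet ds(n);
  std::vector<float> thr(n, (float)k);
  for (size_t i = 0; i < edges.size(); ++i) {
    int a = ds.find(edges[i].a), b = ds.find(edges[i].b);
    if (a == b) continue;
    if (edges[i].w <= thr[a] && edges[i].w <= thr[b]) {
      int m = ds.join(a, b);
      thr[m] = edges[i].w + (float)(k / ds.size[m]);
    }
  }
  for (size_t i = 0; i < edges.size(); ++i) {
    int a = ds.find(edges[i].a), b = ds.find(edges[i].b);
    if (a != b && (ds.size[a] < min_size || ds.size[b] < min_size)) ds.join(a, b);
  }
  // relabel components 1..K
  std::vector<int> relabel(n, 0);
  int next = 0;
  IntegerMatrix lab(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int root = ds.find(r + c * nr);
      if (relabel[root] == 0) relabel[root] = ++next;
      lab(r, c) = relabel[root];
    }
  }
  return lab;
}

// Region statistics for a label map: size, mean intensity, bounding box
// (0-based half-open, x = column, y = row). Labels must be 1..K.
// [[Rcpp::export(name = ".cpp_region_stats")]]
List cpp_region_stats(IntegerMatrix lab, NumericMatrix img) {
  int nr = lab.nrow(), nc = lab.ncol();
  int K = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > K) K = lab(r, c);
  NumericVector sum(K), size(K);
  IntegerVector x0(K, nc), y0(K, nr), x1(K, 0), y1(K, 0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = lab(r, c) - 1;
      sum[i] += img(r, c);
      size[i] += 1;
      if (c < x0[i]) x0[i] = c;
      if (r < y0[i]) y0[i] = r;
      if (c + 1 > x1[i]) x1[i] = c + 1;
      if (r + 1 > y1[i]) y1[i] = r + 1;
    }
  }
  NumericVector mean(K);
  for (int i = 0; i < K; ++i) mean[i] = sum[i] / size[i];
  return List::create(_["size"] = size, _["mean"] = mean,
                      _["x0"] = x0, _["y0"] = y0, _["x1"] = x1, _["y1"] = y1);
}

// Adjacency pairs (i < j, 1-based labels) of a label map, 4-connectivity
// [[Rcpp::export(name = ".cpp_region_adjacency")]]
IntegerMatrix cpp_region_adjacency(IntegerMatrix lab) {
  int nr = lab.nrow(), nc = lab.ncol();
  std::vector<std::pair<int, int> > pairs;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int a = lab(r, c);
      if (r + 1 < nr) {
        int b = lab(r + 1, c);
        if (a != b) pairs.push_back(std::minmax(a, b));
      }
      if (c + 1 < nc) {
        int b = lab(r, c + 1);
        if (a != b) pairs.push_back(std::minmax(a, b));
      }
    }
  }
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  IntegerMatrix out(pairs.size(), 2);
  for (size_t i = 0; i < pairs.size(); ++i) {
    out(i, 0) = pairs[i].first;
    out(i, 1) = pairs[i].second;
  }
  return out;
}
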