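#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <queue>
#include <cstdint>

using namespace Rcpp;

// Pairwise distances under the cylinder metric: x wraps with period lx,
// y is plain Euclidean. lx <= 0 disables wrapping.
// [[Rcpp::export(rng = false)]]
NumericMatrix cylinder_dist_cpp(NumericVector x, NumericVector y, double lx) {
  const int n = x.size();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = std::fabs(x[i] - x[j]);
      if (lx > 0 && dx > lx - dx) dx = lx - dx;
      const double dy = y[i] - y[j];
      const double v = std::sqrt(dx * dx + dy * dy);
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}

namespace {

struct UnionFind {
  std::vector<int> parent, rank_;
  explicit UnionFind(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
    return true;
  }
};

struct Edge {
  double w;
  int i, j;
};

// a triangle in the filtration: ordered by (diameter, vertex-lexicographic
// key), which refines the filtration and gives a deterministic total order
struct Entry {
  double w;
  int64_t key;
  bool operator<(const Entry& o) const {
    if (w != o.w) return w < o.w;
    return key < o.key;
  }
  bool operator>(const Entry& o) const {
    if (w != o.w) return w > o.w;
    return key > o.key;
  }
  bool operator==(const Entry& o) const { return key == o.key; }
};

// Working column as a lazy min-heap over GF(2): entries with even
// multiplicity cancel on extraction. Adding another column is a bulk push,
// so a long reduction chain never re-copies the accumulated column.
struct WorkingColumn {
  std::priority_queue<Entry, std::vector<Entry>, std::greater<Entry>> q;
  void push(const Entry& e) { q.push(e); }
  void push_all(const std::vector<Entry>& v) {
    for (const Entry& e : v) q.push(e);
  }
  // smallest entry with odd multiplicity; false if the column is zero.
  // The pivot is removed from the heap; re-push it to keep the column.
  bool pop_pivot(Entry& out) {
    while (!q.empty()) {
      Entry t = q.top();
      q.pop();
      if (!q.empty() && q.top() == t) {
        q.pop();  // cancels mod 2
      } else {
        out = t;
        return true;
      }
    }
    return false;
  }
  // drain into an ascending, cancelled vector
  void drain(std::vector<Entry>& out) {
    out.clear();
    Entry t{0.0, 0};
    while (pop_pivot(t)) out.push_back(t);
  }
};

}  // namespace

// Vietoris-Rips persistence pairs in dimensions 0 and 1 from a distance
// matrix, truncated at filtration value `cap` (distance scale). Dimension 0
// uses union-find on the sorted edge list. Dimension 1 reduces the
// coboundary matrix (persistent cohomology, which yields the same pairs as
// homology but avoids the long reduction chains of the triangle boundary
// matrix): columns are the cofacet lists of the cycle-creating edges,
// processed in decreasing filtration order, with the merge edges cleared by
// the union-find pass. Features alive at the cap get death = Inf.
// [[Rcpp::export(rng = false)]]
DataFrame rips_pairs_cpp(NumericMatrix dmat, double cap, int maxdim) {
  const int n = dmat.nrow();
  if (n < 1) stop("distance matrix must have at least one point");

  std::vector<Edge> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dmat(i, j) <= cap) edges.push_back({dmat(i, j), i, j});
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int m = static_cast<int>(edges.size());

  std::vector<double> dims, births, deaths;
  UnionFind uf(n);
  std::vector<int> creators;  // edge ids creating 1-cycles (positive edges)
  int n_comp = n;
  for (int e = 0; e < m; ++e) {
    if (uf.unite(edges[e].i, edges[e].j)) {
      dims.push_back(0.0);
      births.push_back(0.0);
      deaths.push_back(edges[e].w);
      --n_comp;
    } else {
      creators.push_back(e);
    }
  }
  for (int c = 0; c < n_comp; ++c) {  // essential components
    dims.push_back(0.0);
    births.push_back(0.0);
    deaths.push_back(R_PosInf);
  }

  if (maxdim >= 1 && !creators.empty()) {
    std::vector<std::vector<int>> nbr(n);  // ascending neighbour lists
    for (int e = 0; e < m; ++e) {
      nbr[edges[e].i].push_back(edges[e].j);
      nbr[edges[e].j].push_back(edges[e].i);
    }
    for (int i = 0; i < n; ++i) std::sort(nbr[i].begin(), nbr[i].end());

    const int64_t N = n;
    // cofacets of edge (i, j): triangles (i, j, k) over common neighbours k
    auto build_column = [&](int i, int j, double wij,
                            std::vector<Entry>& col) {
      col.clear();
      const std::vector<int>& a = nbr[i];
      const std::vector<int>& b = nbr[j];
      size_t p = 0, q = 0;
      while (p < a.size() && q < b.size()) {
        if (a[p] < b[q]) ++p;
        else if (b[q] < a[p]) ++q;
        else {
          const int k = a[p];
          const double w = std::max({wij, dmat(i, k), dmat(j, k)});
          if (w <= cap) {
            int v0 = i, v1 = j, v2 = k;
            if (v0 > v1) std::swap(v0, v1);
            if (v1 > v2) std::swap(v1, v2);
            if (v0 > v1) std::swap(v0, v1);
            col.push_back({w, (static_cast<int64_t>(v0) * N + v1) * N + v2});
          }
          ++p; ++q;
        }
      }
      std::sort(col.begin(), col.end());
    };

    // pivot (earliest cofacet) -> owner column. Columns claimed without any
    // addition are not stored: their reduced form equals their coboundary
    // and is rebuilt on demand.
    std::unordered_map<int64_t, int> pivot_owner;
    pivot_owner.reserve(creators.size() * 2);
    std::vector<int> owner_edge;
    std::vector<std::vector<Entry>> owner_col;
    std::vector<Entry> init, other;

    for (auto it = creators.rbegin(); it != creators.rend(); ++it) {
      const int e = *it;
      build_column(edges[e].i, edges[e].j, edges[e].w, init);
      WorkingColumn col;
      col.push_all(init);
      int n_adds = 0;
      Entry piv{0.0, 0};
      bool alive = false;
      while (col.pop_pivot(piv)) {
        auto hit = pivot_owner.find(piv.key);
        if (hit == pivot_owner.end()) {
          alive = true;
          break;
        }
        const int o = hit->second;
        col.push(piv);  // keep the pivot; it cancels against the owner's
        if (owner_col[o].empty()) {
          const int oe = owner_edge[o];
          build_column(edges[oe].i, edges[oe].j, edges[oe].w, other);
          col.push_all(other);
        } else {
          col.push_all(owner_col[o]);
        }
        ++n_adds;
      }
      if (!alive) {  // no cofacet kills this cycle below the cap
        dims.push_back(1.0);
        births.push_back(edges[e].w);
        deaths.push_back(R_PosInf);
      } else {
        pivot_owner[piv.key] = static_cast<int>(owner_edge.size());
        owner_edge.push_back(e);
        if (n_adds == 0) {
          owner_col.push_back(std::vector<Entry>());
        } else {
          std::vector<Entry> rest;
          col.drain(rest);  // entries above the pivot, ascending
          std::vector<Entry> reduced;
          reduced.reserve(rest.size() + 1);
          reduced.push_back(piv);
          reduced.insert(reduced.end(), rest.begin(), rest.end());
          owner_col.push_back(std::move(reduced));
        }
        if (piv.w > edges[e].w) {
          dims.push_back(1.0);
          births.push_back(edges[e].w);
          deaths.push_back(piv.w);
        }
      }
    }
  }

  return DataFrame::create(_["dim"] = IntegerVector(dims.begin(), dims.end()),
                           _["birth"] = births, _["death"] = deaths);
}
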