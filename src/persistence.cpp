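// Vietoris-Rips filtration and persistence by boundary-matrix reduction
// over GF(2), with representative cycles.
//
// Conventions (fixed throughout the package):
//  * radius filtration: a simplex enters at HALF its diameter, so an edge of
//    length d has filtration radius d/2 (balls of radius r touch when r = d/2);
//  * hard truncation at r_max: simplices with radius > r_max never exist;
//    classes alive at r_max are reported with death = NA ("truncated");
//  * total order on simplices: (radius, dimension, lexicographic vertex
//    tuple).  The order is deterministic, which makes the reduction -- and
//    hence the choice of representatives -- deterministic on tie-heavy
//    lattice data.
//  * zero-persistence pairs (birth == death) are dropped.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

typedef std::vector<int> Col;  // sorted ascending list of row indices (GF(2) chain)

// symmetric difference of two sorted vectors
Col col_add(const Col& a, const Col& b) {
  Col out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

struct Simplex {
  double r;
  std::array<int, 4> v;  // vertex ids, ascending; unused = -1
  int dim;
};

bool simplex_less(const Simplex& a, const Simplex& b) {
  if (a.r != b.r) return a.r < b.r;
  return a.v < b.v;  // lexicographic on vertex tuples (same dim per container)
}

// half of Euclidean distance between rows i, j of an n x d coordinate matrix
inline double radius_ij(const NumericMatrix& X, int i, int j) {
  double s = 0.0;
  for (int c = 0; c < X.ncol(); ++c) {
    double d = X(i, c) - X(j, c);
    s += d * d;
  }
  return 0.5 * std::sqrt(s);
}

// Reduce the boundary matrix with columns `cols` (rows indexed 0..nrow-1).
// Results: pair_row[j] = pivot row of reduced column j, or -1 if the column
// reduced to zero (positive simplex).  reduced[j] holds the reduced column
// for pivot columns; vmat[j] (if track_v) holds the accumulated combination
// V with boundary(V[j]) = reduced[j], giving cycles for zero columns.
void reduce_matrix(std::vector<Col>& cols, int nrow,
                   std::vector<int>& pair_row,
                   std::vector<Col>* vmat) {
  const int m = (int)cols.size();
  std::vector<int> pivot_owner(nrow, -1);
  pair_row.assign(m, -1);
  if (vmat) {
    vmat->assign(m, Col());
    for (int j = 0; j < m; ++j) (*vmat)[j].push_back(j);
  }
  for (int j = 0; j < m; ++j) {
    Col& cur = cols[j];
    while (!cur.empty()) {
      int low = cur.back();
      int owner = pivot_owner[low];
      if (owner < 0) break;
      cur = col_add(cur, cols[owner]);
      if (vmat) (*vmat)[j] = col_add((*vmat)[j], (*vmat)[owner]);
    }
    if (!cur.empty()) {
      pair_row[j] = cur.back();
      pivot_owner[cur.back()] = j;
    }
  }
}

}  // namespace

// Enumerate the Vietoris-Rips filtration of a point cloud up to dimension
// max_dim + 1 and radius r_max.  Returns, per simplex dimension (1-based
// list element = dimension + 1), a matrix of vertex ids (1-based) with one
// row per simplex, plus the vector of filtration radii, both in filtration
// order.
// [[Rcpp::export]]
List cpp_rips_filtration(NumericMatrix coords, double r_max, int max_dim) {
  const int n = coords.nrow();
  const int top = max_dim + 1;

  // pairwise radii, cached (n is capped upstream)
  std::vector<std::vector<double>> R(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      R[i][j] = R[j][i] = radius_ij(coords, i, j);

  std::vector<std::vector<Simplex>> simp(top + 1);
  for (int i = 0; i < n; ++i)
    simp[0].push_back(Simplex{0.0, {i, -1, -1, -1}, 0});
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (R[i][j] <= r_max)
        simp[1].push_back(Simplex{R[i][j], {i, j, -1, -1}, 1});
  if (top >= 2) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (R[i][j] > r_max) continue;
        for (int k = j + 1; k < n; ++k) {
          double r = std::max(R[i][j], std::max(R[i][k], R[j][k]));
          if (r <= r_max) simp[2].push_back(Simplex{r, {i, j, k, -1}, 2});
        }
      }
  }
  if (top >= 3) {
    for (size_t t = 0; t < simp[2].size(); ++t) {
      const Simplex& s = simp[2][t];
      for (int l = s.v[2] + 1; l < n; ++l) {
        double r = std::max(s.r,
          std::max(R[s.v[0]][l], std::max(R[s.v[1]][l], R[s.v[2]][l])));
        if (r <= r_max) simp[3].push_back(Simplex{r, {s.v[0], s.v[1], s.v[2], l}, 3});
      }
    }
  }

  List out(top + 1);
  for (int d = 0; d <= top; ++d) {
    std::sort(simp[d].begin(), simp[d].end(), simplex_less);
    const int m = (int)simp[d].size();
    IntegerMatrix V(m, d + 1);
    NumericVector rr(m);
    for (int s = 0; s < m; ++s) {
      for (int c = 0; c <= d; ++c) V(s, c) = simp[d][s].v[c] + 1;
      rr[s] = simp[d][s].r;
    }
    out[d] = List::create(_["vertices"] = V, _["radius"] = rr);
  }
  return out;
}

// Persistence of a filtration as produced by cpp_rips_filtration.
// `simplices` is the per-dimension list; homology is computed in dimensions
// 0 .. max_dim.  Returns features (dim, birth, death with NA = truncated)
// and, aligned with them, representative chains as integer matrices of
// vertex ids (one simplex per row): the birth vertex for dim 0, an edge set
// for dim 1, a triangle set for dim 2.
// [[Rcpp::export]]
List cpp_persistence(List simplices, int n_points, double r_max, int max_dim) {
  const int top = max_dim + 1;

  // unpack into vertex arrays + radii per dimension
  std::vector<std::vector<std::array<int, 4>>> verts(top + 1);
  std::vector<std::vector<double>> rad(top + 1);
  for (int d = 0; d <= top && d < simplices.size(); ++d) {
    List ld = simplices[d];
    IntegerMatrix V = ld["vertices"];
    NumericVector rr = ld["radius"];
    verts[d].resize(V.nrow());
    rad[d].resize(V.nrow());
    for (int s = 0; s < V.nrow(); ++s) {
      std::array<int, 4> a = {-1, -1, -1, -1};
      for (int c = 0; c <= d; ++c) a[c] = V(s, c) - 1;
      verts[d][s] = a;
      rad[d][s] = rr[s];
    }
  }

  // row lookup: vertex tuple -> index within dimension d (filtration order)
  auto key_of = [n_points](const std::array<int, 4>& v, int d) -> std::int64_t {
    std::int64_t k = 0;
    for (int c = 0; c <= d; ++c) k = k * (std::int64_t)n_points + v[c];
    return k;
  };
  std::vector<std::unordered_map<std::int64_t, int>> index(top + 1);
  for (int d = 0; d <= top; ++d) {
    index[d].reserve(verts[d].size() * 2 + 1);
    for (int s = 0; s < (int)verts[d].size(); ++s)
      index[d][key_of(verts[d][s], d)] = s;
  }

  // boundary columns of dimension-d simplices (rows: (d-1)-simplices)
  auto boundary_cols = [&](int d) {
    std::vector<Col> cols(verts[d].size());
    for (int s = 0; s < (int)verts[d].size(); ++s) {
      Col c;
      for (int omit = 0; omit <= d; ++omit) {
        std::array<int, 4> f = {-1, -1, -1, -1};
        int w = 0;
        for (int c2 = 0; c2 <= d; ++c2)
          if (c2 != omit) f[w++] = verts[d][s][c2];
        c.push_back(index[d - 1].at(key_of(f, d - 1)));
      }
      std::sort(c.begin(), c.end());
      cols[s] = c;
    }
    return cols;
  };

  struct Feat { int dim; double birth; double death; Col chain; };
  std::vector<Feat> feats;

  // paired_row[d][i] = 1 if (d)-simplex i was the pivot of a (d+1)-column
  std::vector<std::vector<char>> is_pivot_row(top + 1);
  for (int d = 0; d <= top; ++d) is_pivot_row[d].assign(verts[d].size(), 0);
  // positive[d][i] = 1 if column i of boundary_d reduced to zero
  std::vector<std::vector<char>> positive(top + 1);
  positive[0].assign(verts[0].size(), 1);  // vertices create components
  // essential cycle chains for positive d-simplices (from V of boundary_d)
  std::vector<std::unordered_map<int, Col>> cycle_of(top + 1);
  for (int s = 0; s < (int)verts[0].size(); ++s)
    cycle_of[0][s] = Col{s};

  for (int d = 1; d <= top; ++d) {
    std::vector<Col> cols = boundary_cols(d);
    std::vector<int> pair_row;
    // V is needed to read off cycles of positive d-simplices, i.e. whenever
    // homology in dimension d is reported (d <= max_dim)
    bool track_v = (d <= max_dim);
    std::vector<Col> vmat;
    reduce_matrix(cols, (int)verts[d - 1].size(), pair_row,
                  track_v ? &vmat : nullptr);

    positive[d].assign(verts[d].size(), 0);
    for (int j = 0; j < (int)verts[d].size(); ++j) {
      if (pair_row[j] < 0) {
        positive[d][j] = 1;
        if (track_v) cycle_of[d][j] = vmat[j];
      } else {
        int i = pair_row[j];
        is_pivot_row[d - 1][i] = 1;
        double birth = rad[d - 1][i], death = rad[d][j];
        if (death > birth)  // drop zero-persistence pairs
          feats.push_back(Feat{d - 1, birth, death, cols[j]});
      }
    }
    // essential classes of dimension d-1: positive, never a pivot row
    for (int i = 0; i < (int)verts[d - 1].size(); ++i) {
      if (positive[d - 1][i] && !is_pivot_row[d - 1][i]) {
        Col chain = (d - 1 == 0) ? Col{i} : cycle_of[d - 1][i];
        feats.push_back(Feat{d - 1, rad[d - 1][i], NA_REAL, chain});
      }
    }
    cycle_of[d - 1].clear();
  }
  std::sort(feats.begin(), feats.end(), [](const Feat& a, const Feat& b) {
    if (a.dim != b.dim) return a.dim < b.dim;
    if (a.birth != b.birth) return a.birth < b.birth;
    double da = ISNA(a.death) ? R_PosInf : a.death;
    double db = ISNA(b.death) ? R_PosInf : b.death;
    return da < db;
  });

  const int nf = (int)feats.size();
  IntegerVector fdim(nf);
  NumericVector birth(nf), death(nf);
  List reps(nf);
  for (int f = 0; f < nf; ++f) {
    fdim[f] = feats[f].dim;
    birth[f] = feats[f].birth;
    death[f] = feats[f].death;
    int d = feats[f].dim;
    IntegerMatrix M((int)feats[f].chain.size(), d + 1);
    for (int s = 0; s < (int)feats[f].chain.size(); ++s)
      for (int c = 0; c <= d; ++c)
        M(s, c) = verts[d][feats[f].chain[s]][c] + 1;
    reps[f] = M;
  }
  return List::create(_["dim"] = fdim, _["birth"] = birth, _["death"] = death,
                      _["representatives"] = reps);
}
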