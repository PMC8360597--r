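// Brute-force persistence oracle for small point clouds.
//
// Independent of the reduction engine in persistence.cpp: persistence pair
// multiplicities are recovered from persistent Betti numbers computed by
// rank-nullity over GF(2) at every critical radius,
//   beta_p(b, d) = rank[ Z_p(K_b) | B_p(K_d) ] - rank[ B_p(K_d) ],
// with Z_p(K_b) a nullspace basis of the dimension-p boundary map restricted
// to simplices of radius <= b, and B_p(K_d) the boundary columns of the
// (p+1)-simplices of radius <= d.  The multiplicity of the interval (b_k, d_l]
// is the usual inclusion-exclusion over adjacent grid values.  Intended for
// clouds of at most ~14 points; cost grows combinatorially.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <map>
#include <cstdint>
using namespace Rcpp;

namespace {

typedef std::vector<std::uint64_t> BitVec;

struct Elim {  // incremental GF(2) column elimination
  int nw;
  std::vector<BitVec> pivots;
  std::vector<int> pivot_rows;
  explicit Elim(int nrows) : nw((nrows + 63) / 64) {}
  static int high_bit(const BitVec& v) {
    for (int w = (int)v.size() - 1; w >= 0; --w)
      if (v[w]) return w * 64 + (63 - __builtin_clzll(v[w]));
    return -1;
  }
  // returns true if the column increased the rank; col is modified in place
  bool add(BitVec& col, BitVec* companion = nullptr,
           std::vector<BitVec>* companions = nullptr) {
    int hb;
    while ((hb = high_bit(col)) >= 0) {
      int owner = -1;
      for (size_t k = 0; k < pivot_rows.size(); ++k)
        if (pivot_rows[k] == hb) { owner = (int)k; break; }
      if (owner < 0) break;
      for (int w = 0; w < nw; ++w) col[w] ^= pivots[owner][w];
      if (companion && companions)
        for (size_t w = 0; w < companion->size(); ++w)
          (*companion)[w] ^= (*companions)[owner][w];
    }
    if (hb < 0) return false;
    pivots.push_back(col);
    pivot_rows.push_back(hb);
    return true;
  }
};

struct OSimplex {
  double r;
  std::array<int, 4> v;
};

}  // namespace

// [[Rcpp::export]]
List cpp_oracle_persistence(NumericMatrix coords, double r_max, int max_dim) {
  const int n = coords.nrow();
  const int top = max_dim + 1;
  std::vector<std::vector<double>> R(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < coords.ncol(); ++c) {
        double d = coords(i, c) - coords(j, c);
        s += d * d;
      }
      R[i][j] = R[j][i] = 0.5 * std::sqrt(s);
    }

  // all simplices up to dimension top, radius <= r_max, sorted by radius
  std::vector<std::vector<OSimplex>> simp(top + 1);
  for (int i = 0; i < n; ++i) simp[0].push_back({0.0, {i, -1, -1, -1}});
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (R[i][j] <= r_max) simp[1].push_back({R[i][j], {i, j, -1, -1}});
  if (top >= 2)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        for (int k = j + 1; k < n; ++k) {
          double r = std::max(R[i][j], std::max(R[i][k], R[j][k]));
          if (r <= r_max) simp[2].push_back({r, {i, j, k, -1}});
        }
  if (top >= 3)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        for (int k = j + 1; k < n; ++k)
          for (int l = k + 1; l < n; ++l) {
            double r = std::max({R[i][j], R[i][k], R[i][l],
                                 R[j][k], R[j][l], R[k][l]});
            if (r <= r_max) simp[3].push_back({r, {i, j, k, l}});
          }
  for (int d = 0; d <= top; ++d)
    std::sort(simp[d].begin(), simp[d].end(),
              [](const OSimplex& a, const OSimplex& b) {
                if (a.r != b.r) return a.r < b.r;
                return a.v < b.v;
              });

  // index simplices within their dimension
  auto key_of = [n](const std::array<int, 4>& v, int d) -> std::int64_t {
    std::int64_t k = 0;
    for (int c = 0; c <= d; ++c) k = k * (std::int64_t)n + v[c];
    return k;
  };
  std::vector<std::map<std::int64_t, int>> index(top + 1);
  for (int d = 0; d <= top; ++d)
    for (int s = 0; s < (int)simp[d].size(); ++s)
      index[d][key_of(simp[d][s].v, d)] = s;

  // boundary of dimension-d simplex s as a bit vector over (d-1)-simplices
  auto boundary_vec = [&](int d, int s) {
    BitVec b(((int)simp[d - 1].size() + 63) / 64, 0);
    for (int omit = 0; omit <= d; ++omit) {
      std::array<int, 4> f = {-1, -1, -1, -1};
      int w = 0;
      for (int c = 0; c <= d; ++c)
        if (c != omit) f[w++] = simp[d][s].v[c];
      int row = index[d - 1].at(key_of(f, d - 1));
      b[row / 64] ^= (std::uint64_t(1) << (row % 64));
    }
    return b;
  };

  std::vector<int> out_dim;
  std::vector<double> out_birth, out_death;

  for (int p = 0; p <= max_dim; ++p) {
    const int np = (int)simp[p].size();
    const int nq = (p + 1 <= top) ? (int)simp[p + 1].size() : 0;
    if (np == 0) continue;

    // birth candidates: distinct radii at which p-simplices enter
    std::vector<double> births;
    for (int s = 0; s < np; ++s)
      if (births.empty() || simp[p][s].r > births.back())
        births.push_back(simp[p][s].r);
    // death candidates: distinct radii at which (p+1)-simplices enter
    std::vector<double> deaths;
    for (int s = 0; s < nq; ++s)
      if (deaths.empty() || simp[p + 1][s].r > deaths.back())
        deaths.push_back(simp[p + 1][s].r);
    const int K = (int)births.size(), L = (int)deaths.size();

    // rank of B_p(K_d) at each death candidate (incremental over columns)
    std::vector<int> rankB(L + 1, 0);
    {
      Elim el(np);
      int rank = 0, s = 0;
      for (int l = 1; l <= L; ++l) {
        while (s < nq && simp[p + 1][s].r <= deaths[l - 1]) {
          BitVec c = boundary_vec(p + 1, s);
          if (el.add(c)) ++rank;
          ++s;
        }
        rankB[l] = rank;
      }
    }

    // nullspace bases Z_p(K_b) for each birth candidate, as vectors in C_p
    // (for p = 0 the cycle space is all of C_0)
    std::vector<std::vector<BitVec>> Z(K);
    if (p == 0) {
      for (int k = 0; k < K; ++k) {  // K == 1: all vertices at radius 0
        for (int s = 0; s < np; ++s) {
          BitVec e((np + 63) / 64, 0);
          e[s / 64] |= (std::uint64_t(1) << (s % 64));
          Z[k].push_back(e);
        }
      }
    } else {
      Elim el((int)simp[p - 1].size());
      std::vector<BitVec> companions;
      int s = 0;
      for (int k = 0; k < K; ++k) {
        if (k > 0) Z[k] = Z[k - 1];
        while (s < np && simp[p][s].r <= births[k]) {
          BitVec c = boundary_vec(p, s);
          BitVec comp((np + 63) / 64, 0);
          comp[s / 64] |= (std::uint64_t(1) << (s % 64));
          if (!el.add(c, &comp, &companions)) {
            Z[k].push_back(comp);  // a new p-cycle
          } else {
            companions.push_back(comp);
          }
          ++s;
        }
      }
    }

    // beta[k][l], k = 0..K (0 = before first birth), l = 0..L (0 = no
    // (p+1)-simplices yet)
    std::vector<std::vector<int>> beta(K + 1, std::vector<int>(L + 1, 0));
    for (int k = 1; k <= K; ++k) {
      Elim el(np);
      int rZ = 0;
      for (size_t z = 0; z < Z[k - 1].size(); ++z) {
        BitVec c = Z[k - 1][z];
        if (el.add(c)) ++rZ;
      }
      beta[k][0] = rZ;  // dim Z_p(K_b), B empty
      int rZB = rZ, s = 0;
      for (int l = 1; l <= L; ++l) {
        while (s < nq && simp[p + 1][s].r <= deaths[l - 1]) {
          BitVec c = boundary_vec(p + 1, s);
          if (el.add(c)) ++rZB;
          ++s;
        }
        beta[k][l] = rZB - rankB[l];
      }
    }

    // interval multiplicities by inclusion-exclusion on the candidate grid
    for (int k = 1; k <= K; ++k) {
      for (int l = 1; l <= L; ++l) {
        if (deaths[l - 1] <= births[k - 1]) continue;  // zero/negative persistence
        int mu = (beta[k][l - 1] - beta[k][l]) -
                 (beta[k - 1][l - 1] - beta[k - 1][l]);
        for (int m = 0; m < mu; ++m) {
          out_dim.push_back(p);
          out_birth.push_back(births[k - 1]);
          out_death.push_back(deaths[l - 1]);
        }
      }
      int mu_ess = beta[k][L] - beta[k - 1][L];
      for (int m = 0; m < mu_ess; ++m) {
        out_dim.push_back(p);
        out_birth.push_back(births[k - 1]);
        out_death.push_back(NA_REAL);
      }
    }
  }

  return List::create(_["dim"] = wrap(out_dim), _["birth"] = wrap(out_birth),
                      _["death"] = wrap(out_death));
}
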