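// Z2 simplicial homology: boundary-matrix ranks and persistence pairing.
// Simplices arrive from R as integer vectors of sorted vertex ids; filtration
// order (time, dim, lex) is established on the R side.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct VecHash {
  std::size_t operator()(const std::vector<int>& v) const {
    std::size_t h = v.size();
    for (int x : v)
      h ^= std::hash<int>()(x) + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
    return h;
  }
};

typedef std::unordered_map<std::vector<int>, int, VecHash> SimplexIndex;

// symmetric difference of two ascending-sorted columns (GF(2) addition)
std::vector<int> sym_diff(const std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

// rank of a GF(2) matrix given as columns of ascending row indices
int gf2_rank(std::vector<std::vector<int> >& cols) {
  std::unordered_map<int, std::vector<int> > pivot_col;
  int rank = 0;
  for (std::size_t j = 0; j < cols.size(); ++j) {
    std::vector<int> col = cols[j];
    while (!col.empty()) {
      int p = col.back();
      std::unordered_map<int, std::vector<int> >::iterator it = pivot_col.find(p);
      if (it == pivot_col.end()) {
        pivot_col[p] = col;
        ++rank;
        break;
      }
      col = sym_diff(col, it->second);
    }
  }
  return rank;
}

} // namespace

// Betti numbers b_0..b_dmax over Z2 via rank(boundary_d).
// simplices: list of sorted integer vectors. Throws if not face-closed.
// [[Rcpp::export]]
IntegerVector betti_z2_cpp(List simplices, int d_max) {
  int m = simplices.size();
  int top = 0;
  std::vector<std::vector<std::vector<int> > > by_dim; // [dim][i] = vertex set
  std::vector<SimplexIndex> index_by_dim;
  for (int i = 0; i < m; ++i) {
    IntegerVector s = simplices[i];
    std::vector<int> v(s.begin(), s.end());
    int d = (int)v.size() - 1;
    if (d < 0) stop("empty simplex");
    if (d > top) top = d;
    if ((int)by_dim.size() <= d) { by_dim.resize(d + 1); index_by_dim.resize(d + 1); }
    if (index_by_dim[d].count(v)) continue; // ignore duplicates
    index_by_dim[d][v] = (int)by_dim[d].size();
    by_dim[d].push_back(v);
  }
  std::vector<int> rank_d(top + 2, 0); // rank of boundary_d, d = 1..top
  for (int d = 1; d <= top; ++d) {
    std::vector<std::vector<int> > cols;
    cols.reserve(by_dim[d].size());
    for (std::size_t j = 0; j < by_dim[d].size(); ++j) {
      const std::vector<int>& v = by_dim[d][j];
      std::vector<int> col;
      col.reserve(v.size());
      for (std::size_t k = 0; k < v.size(); ++k) {
        std::vector<int> face;
        face.reserve(v.size() - 1);
        for (std::size_t l = 0; l < v.size(); ++l)
          if (l != k) face.push_back(v[l]);
        SimplexIndex::iterator it = index_by_dim[d - 1].find(face);
        if (it == index_by_dim[d - 1].end())
          stop("complex is not closed under faces");
        col.push_back(it->second);
      }
      std::sort(col.begin(), col.end());
      cols.push_back(col);
    }
    rank_d[d] = gf2_rank(cols);
  }
  int kmax = d_max < 0 ? top : d_max;
  IntegerVector betti(kmax + 1);
  for (int k = 0; k <= kmax; ++k) {
    int nk = (k < (int)by_dim.size()) ? (int)by_dim[k].size() : 0;
    int rk = (k <= top) ? rank_d[k] : 0;
    int rk1 = (k + 1 <= top) ? rank_d[k + 1] : 0;
    betti[k] = nk - rk - rk1;
  }
  return betti;
}

// Persistence pairing by standard column reduction with the twist (clearing)
// optimisation. Simplices must already be in filtration order.
// Returns an (n_pairs x 3) integer matrix: dim, birth index, death index
// (1-based positions in the filtration; death = NA for essential classes).
// [[Rcpp::export]]
IntegerMatrix persistence_z2_cpp(List simplices) {
  int m = simplices.size();
  std::vector<std::vector<int> > verts(m);
  std::vector<int> dim(m);
  SimplexIndex global;
  int top = 0;
  for (int i = 0; i < m; ++i) {
    IntegerVector s = simplices[i];
    verts[i].assign(s.begin(), s.end());
    dim[i] = (int)verts[i].size() - 1;
    if (dim[i] > top) top = dim[i];
    if (global.count(verts[i])) stop("duplicate simplex in filtration");
    global[verts[i]] = i;
  }
  // boundary columns in global filtration indices
  std::vector<std::vector<int> > reduced(m);
  std::vector<int> pivot_owner(m, -1); // row -> column that has this pivot
  std::vector<char> cleared(m, 0);     // columns known to die as pivots
  std::vector<int> death_of(m, -1);    // birth index -> death index
  std::vector<char> is_positive(m, 0);

  for (int d = top; d >= 1; --d) {
    for (int j = 0; j < m; ++j) {
      if (dim[j] != d) continue;
      if (cleared[j]) continue; // killed by a (d+1)-column: positive, paired
      std::vector<int> col;
      col.reserve(d + 1);
      for (int k = 0; k <= d; ++k) {
        std::vector<int> face;
        face.reserve(d);
        for (int l = 0; l <= d; ++l)
          if (l != k) face.push_back(verts[j][l]);
        SimplexIndex::iterator it = global.find(face);
        if (it == global.end()) stop("filtration is not closed under faces");
        if (it->second > j) stop("face appears after its coface in the filtration");
        col.push_back(it->second);
      }
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int p = col.back();
        if (pivot_owner[p] < 0) {
          pivot_owner[p] = j;
          reduced[j] = col;
          death_of[p] = j;
          cleared[p] = 1;
          break;
        }
        col = sym_diff(col, reduced[pivot_owner[p]]);
      }
      if (col.empty()) is_positive[j] = 1;
    }
  }
  // dimension-0 columns are all positive (empty boundary)
  for (int j = 0; j < m; ++j)
    if (dim[j] == 0) is_positive[j] = 1;

  std::vector<int> out_dim, out_birth, out_death;
  for (int i = 0; i < m; ++i) {
    bool born = is_positive[i] || cleared[i];
    if (!born) continue;
    if (!is_positive[i] && !cleared[i]) continue;
    if (is_positive[i] || cleared[i]) {
      if (death_of[i] >= 0) {
        out_dim.push_back(dim[i]);
        out_birth.push_back(i + 1);
        out_death.push_back(death_of[i] + 1);
      } else if (is_positive[i]) {
        out_dim.push_back(dim[i]);
        out_birth.push_back(i + 1);
        out_death.push_back(NA_INTEGER);
      }
    }
  }
  IntegerMatrix res(out_dim.size(), 3);
  for (std::size_t r = 0; r < out_dim.size(); ++r) {
    res(r, 0) = out_dim[r];
    res(r, 1) = out_birth[r];
    res(r, 2) = out_death[r];
  }
  colnames(res) = CharacterVector::create("dim", "birth", "death");
  return res;
}
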