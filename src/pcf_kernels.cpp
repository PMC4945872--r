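#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Per-ring neighbour counts with buffer-zone edge correction.
// occ: logical occupancy matrix; offsets: list of integer matrices
// (n_off x 2, columns di/dj in cell units).  A focal cell is used for a
// ring only if every ring offset lands inside the grid, which for the
// symmetric rings reduces to a per-ring margin on the max |component|.
// [[Rcpp::export]]
List cpp_ring_counts(LogicalMatrix occ, List offsets) {
  const int nr = occ.nrow(), nc = occ.ncol();
  const int K = offsets.size();

  std::vector<char> grid((size_t)nr * nc);
  std::vector<int> oi, oj, olin;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const bool v = occ(i, j) == TRUE;
      grid[(size_t)j * nr + i] = v;
      if (v) { oi.push_back(i); oj.push_back(j); olin.push_back(j * nr + i); }
    }

  NumericVector counts(K);
  IntegerVector nfocal(K);
  const char* G = grid.data();
  for (int k = 0; k < K; ++k) {
    IntegerMatrix off = offsets[k];
    const int noff = off.nrow();
    int m = 0;
    std::vector<int> lin(noff);
    for (int t = 0; t < noff; ++t) {
      const int di = off(t, 0), dj = off(t, 1);
      lin[t] = dj * nr + di;
      const int a = std::abs(di), b = std::abs(dj);
      if (a > m) m = a;
      if (b > m) m = b;
    }
    double tot = 0.0;
    int nf = 0;
    for (size_t u = 0; u < oi.size(); ++u) {
      const int i = oi[u], j = oj[u];
      if (i < m || i >= nr - m || j < m || j >= nc - m) continue;
      ++nf;
      const char* base = G + olin[u];
      int c = 0;
      for (int t = 0; t < noff; ++t) c += base[lin[t]];
      tot += c;
    }
    counts[k] = tot;
    nfocal[k] = nf;
  }
  return List::create(_["count"] = counts, _["n_focal"] = nfocal);
}

// Resampled g(r).  The ordered neighbour pairs of the full occupied set
// are enumerated once per call and grouped by ring (keeping only pairs
// whose focal cell is buffer-valid for that ring); each draw then just
// counts the pairs with both endpoints in the subsample.
// draws: n_draws x m matrix of 1-based indices into the occupied-cell
// list.  density_mode: 0 = fixed density `p_fixed`, 1 = per-ring
// buffer-interior density of the draw (subsample focal count divided by
// interior_cells).  Returns g (n_draws x K), NA where a ring has no valid
// focal cell.
// [[Rcpp::export]]
NumericMatrix cpp_resample_g(IntegerVector occ_i, IntegerVector occ_j,
                             int nr, int nc, List offsets,
                             IntegerMatrix draws, double p_fixed,
                             int density_mode, NumericVector interior_cells) {
  const int K = offsets.size();
  const int n_draws = draws.nrow();
  const int m_draw = draws.ncol();
  const int n_occ = occ_i.size();

  // occupied-cell id grid
  std::vector<int> id((size_t)nr * nc, -1);
  for (int u = 0; u < n_occ; ++u) id[(size_t)occ_j[u] * nr + occ_i[u]] = u;

  // per-ring linear offsets, margins, validity of each occupied cell
  std::vector<int> margin(K), noff(K);
  std::vector<std::vector<int> > lin(K);
  for (int k = 0; k < K; ++k) {
    IntegerMatrix off = offsets[k];
    noff[k] = off.nrow();
    lin[k].resize(noff[k]);
    int m = 0;
    for (int t = 0; t < noff[k]; ++t) {
      const int di = off(t, 0), dj = off(t, 1);
      lin[k][t] = dj * nr + di;
      const int a = std::abs(di), b = std::abs(dj);
      if (a > m) m = a;
      if (b > m) m = b;
    }
    margin[k] = m;
  }
  std::vector<std::vector<char> > valid(K, std::vector<char>(n_occ));
  for (int k = 0; k < K; ++k) {
    const int m = margin[k];
    for (int u = 0; u < n_occ; ++u) {
      valid[k][u] = (occ_i[u] >= m && occ_i[u] < nr - m &&
                     occ_j[u] >= m && occ_j[u] < nc - m);
    }
  }

  // ordered neighbour pairs of the full set, grouped by ring
  std::vector<std::vector<int> > pair_a(K), pair_b(K);
  for (int u = 0; u < n_occ; ++u) {
    const int base = occ_j[u] * nr + occ_i[u];
    for (int k = 0; k < K; ++k) {
      if (!valid[k][u]) continue;
      const std::vector<int>& lk = lin[k];
      for (int t = 0; t < noff[k]; ++t) {
        const int v = id[base + lk[t]];
        if (v >= 0) { pair_a[k].push_back(u); pair_b[k].push_back(v); }
      }
    }
  }

  std::vector<char> in(n_occ, 0);
  NumericMatrix g(n_draws, K);
  for (int d = 0; d < n_draws; ++d) {
    for (int t = 0; t < m_draw; ++t) in[draws(d, t) - 1] = 1;
    for (int k = 0; k < K; ++k) {
      int nf = 0;
      const std::vector<char>& vk = valid[k];
      for (int t = 0; t < m_draw; ++t) nf += vk[draws(d, t) - 1];
      if (nf == 0 || noff[k] == 0) { g(d, k) = NA_REAL; continue; }
      const std::vector<int>& pa = pair_a[k];
      const std::vector<int>& pb = pair_b[k];
      long long cnt = 0;
      const size_t np = pa.size();
      for (size_t t = 0; t < np; ++t) cnt += (in[pa[t]] & in[pb[t]]);
      double p = p_fixed;
      if (density_mode == 1) p = (double)nf / interior_cells[k];
      g(d, k) = (p > 0) ? ((double)cnt / ((double)nf * noff[k])) / p : NA_REAL;
    }
    for (int t = 0; t < m_draw; ++t) in[draws(d, t) - 1] = 0;
  }
  return g;
}
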