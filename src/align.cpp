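#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap alignment. Gap of length k costs gap_open + k * gap_ext
// (BLAST convention; gap_open 11 / gap_ext 1 makes a length-1 gap cost 12).
// Sequences arrive as 0-based integer codes indexing the substitution matrix.

static const double NEG_INF = -1e18;

struct SwResult {
  double score;
  int matches;
  int aligned_cols;
  int q_start, q_end, s_start, s_end; // 1-based, 0 when empty alignment
};

struct SwBuffers {
  std::vector<double> H, E, F;
  std::vector<unsigned char> ptrH, ptrE, ptrF;
  void resize(size_t cells) {
    if (H.size() < cells) {
      H.resize(cells); E.resize(cells); F.resize(cells);
      ptrH.resize(cells); ptrE.resize(cells); ptrF.resize(cells);
    }
  }
};

static SwResult sw_core(const int* a, int n, const int* b, int m,
                        const NumericMatrix& sub, double gap_open,
                        double gap_ext, SwBuffers& buf) {
  const size_t cells = size_t(n + 1) * size_t(m + 1);
  buf.resize(cells);
  double* H = buf.H.data();
  double* E = buf.E.data();
  double* F = buf.F.data();
  unsigned char* ptrH = buf.ptrH.data();
  unsigned char* ptrE = buf.ptrE.data();
  unsigned char* ptrF = buf.ptrF.data();
  auto at = [m](int i, int j) { return size_t(i) * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) {
    H[at(0, j)] = 0.0; E[at(0, j)] = NEG_INF; F[at(0, j)] = NEG_INF;
    ptrH[at(0, j)] = 0;
  }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    H[at(i, 0)] = 0.0; E[at(i, 0)] = NEG_INF; F[at(i, 0)] = NEG_INF;
    ptrH[at(i, 0)] = 0;
    for (int j = 1; j <= m; ++j) {
      const size_t k = at(i, j);
      double e_open = H[at(i, j - 1)] - gap_open - gap_ext;
      double e_ext  = E[at(i, j - 1)] - gap_ext;
      E[k] = e_ext > e_open ? e_ext : e_open;
      ptrE[k] = (e_ext > e_open) ? 1 : 0;
      double f_open = H[at(i - 1, j)] - gap_open - gap_ext;
      double f_ext  = F[at(i - 1, j)] - gap_ext;
      F[k] = f_ext > f_open ? f_ext : f_open;
      ptrF[k] = (f_ext > f_open) ? 1 : 0;
      double diag = H[at(i - 1, j - 1)] + sub(a[i - 1], b[j - 1]);
      double h = 0.0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E[k] > h) { h = E[k]; p = 2; }
      if (F[k] > h) { h = F[k]; p = 3; }
      H[k] = h; ptrH[k] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  SwResult r; r.score = best; r.matches = 0; r.aligned_cols = 0;
  r.q_start = r.q_end = r.s_start = r.s_end = 0;
  if (best > 0) {
    int i = bi, j = bj; int state = 0;
    r.q_end = bi; r.s_end = bj;
    while (i > 0 || j > 0) {
      size_t k = at(i, j);
      if (state == 0) {
        unsigned char p = ptrH[k];
        if (p == 0) break;
        if (p == 1) {
          r.aligned_cols++;
          if (a[i - 1] == b[j - 1]) r.matches++;
          i--; j--;
        } else if (p == 2) state = 2;
        else state = 3;
      } else if (state == 2) {
        r.aligned_cols++;
        if (ptrE[k] == 0) state = 0;
        j--;
      } else {
        r.aligned_cols++;
        if (ptrF[k] == 0) state = 0;
        i--;
      }
    }
    r.q_start = i + 1; r.s_start = j + 1;
  }
  return r;
}

// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_ext) {
  SwBuffers buf;
  SwResult r = sw_core(a.begin(), a.size(), b.begin(), b.size(), sub,
                       gap_open, gap_ext, buf);
  double covq = (r.q_end > 0) ? double(r.q_end - r.q_start + 1) / a.size()
                              : 0.0;
  double covs = (r.s_end > 0) ? double(r.s_end - r.s_start + 1) / b.size()
                              : 0.0;
  double ident = (r.aligned_cols > 0)
                     ? double(r.matches) / r.aligned_cols : 0.0;
  return List::create(_["score"] = r.score, _["identity"] = ident,
                      _["matches"] = r.matches,
                      _["aligned_cols"] = r.aligned_cols,
                      _["q_start"] = r.q_start, _["q_end"] = r.q_end,
                      _["s_start"] = r.s_start, _["s_end"] = r.s_end,
                      _["coverage_q"] = covq, _["coverage_s"] = covs);
}

// Batch SW: every sequence of `qs` against every sequence of `ss`.
// Returns score / identity / coverage matrices (|qs| x |ss|).
// [[Rcpp::export]]
List cpp_sw_batch(List qs, List ss, NumericMatrix sub, double gap_open,
                  double gap_ext) {
  const int na = qs.size(), nb = ss.size();
  NumericMatrix score(na, nb), ident(na, nb), covq(na, nb), covs(na, nb);
  std::vector<IntegerVector> av(na), bv(nb);
  for (int x = 0; x < na; ++x) av[x] = qs[x];
  for (int y = 0; y < nb; ++y) bv[y] = ss[y];
  SwBuffers buf;
  for (int x = 0; x < na; ++x) {
    for (int y = 0; y < nb; ++y) {
      SwResult r = sw_core(av[x].begin(), av[x].size(), bv[y].begin(),
                           bv[y].size(), sub, gap_open, gap_ext, buf);
      score(x, y) = r.score;
      ident(x, y) = (r.aligned_cols > 0)
                        ? double(r.matches) / r.aligned_cols : 0.0;
      covq(x, y) = (r.q_end > 0)
                       ? double(r.q_end - r.q_start + 1) / av[x].size() : 0.0;
      covs(x, y) = (r.s_end > 0)
                       ? double(r.s_end - r.s_start + 1) / bv[y].size() : 0.0;
    }
  }
  return List::create(_["score"] = score, _["identity"] = ident,
                      _["coverage_q"] = covq, _["coverage_s"] = covs);
}

// Global (Needleman-Wunsch) alignment with affine gaps, end gaps penalized.
// Returns aligned position vectors (1-based; 0 marks a gap).
// [[Rcpp::export]]
List cpp_nw_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  std::vector<double> H(size_t(n + 1) * (m + 1), NEG_INF),
      E(size_t(n + 1) * (m + 1), NEG_INF), F(size_t(n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> ptrH(size_t(n + 1) * (m + 1), 0),
      ptrE(size_t(n + 1) * (m + 1), 0), ptrF(size_t(n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return size_t(i) * (m + 1) + j; };
  H[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    E[at(0, j)] = -gap_open - j * gap_ext;
    H[at(0, j)] = E[at(0, j)];
    ptrH[at(0, j)] = 2; ptrE[at(0, j)] = (j > 1) ? 1 : 0;
  }
  for (int i = 1; i <= n; ++i) {
    F[at(i, 0)] = -gap_open - i * gap_ext;
    H[at(i, 0)] = F[at(i, 0)];
    ptrH[at(i, 0)] = 3; ptrF[at(i, 0)] = (i > 1) ? 1 : 0;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t k = at(i, j);
      double e_open = H[at(i, j - 1)] - gap_open - gap_ext;
      double e_ext  = E[at(i, j - 1)] - gap_ext;
      E[k] = std::max(e_open, e_ext);
      ptrE[k] = (e_ext > e_open) ? 1 : 0;
      double f_open = H[at(i - 1, j)] - gap_open - gap_ext;
      double f_ext  = F[at(i - 1, j)] - gap_ext;
      F[k] = std::max(f_open, f_ext);
      ptrF[k] = (f_ext > f_open) ? 1 : 0;
      double diag = H[at(i - 1, j - 1)] + sub(a[i - 1], b[j - 1]);
      double h = diag; unsigned char p = 1;
      if (E[k] > h) { h = E[k]; p = 2; }
      if (F[k] > h) { h = F[k]; p = 3; }
      H[k] = h; ptrH[k] = p;
    }
  }
  std::vector<int> ai, bi;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    size_t k = at(i, j);
    if (state == 0) {
      unsigned char p = ptrH[k];
      if (p == 1) { ai.push_back(i); bi.push_back(j); i--; j--; }
      else if (p == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ai.push_back(0); bi.push_back(j);
      if (ptrE[k] == 0) state = 0;
      j--;
    } else {
      ai.push_back(i); bi.push_back(0);
      if (ptrF[k] == 0) state = 0;
      i--;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = H[at(n, m)],
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()));
}
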