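#include <Rcpp.h>
#include <cstdint>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) over raw character sequences.
// A gap of length g costs gap_open + (g - 1) * gap_ext (both <= 0).
// Two modes:
//   free_target_ends = false : global (Needleman-Wunsch) on both sequences.
//   free_target_ends = true  : "glocal" -- the query (a) is aligned
//     end-to-end, the target (b) may have unaligned flanks. Used for
//     seed-and-extend placement of an allele inside a genomic window.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b,
               double match, double mismatch,
               double gap_open, double gap_ext,
               bool free_target_ends) {
  const int m = a.size(), n = b.size();
  // state matrices: M diag, X gap in target (consumes a), Y gap in query
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> X((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Y((m + 1) * (n + 1), NEG_INF);
  // traceback: 0 = from M, 1 = from X, 2 = from Y
  std::vector<uint8_t> tM((m + 1) * (n + 1), 0);
  std::vector<uint8_t> tX((m + 1) * (n + 1), 0);
  std::vector<uint8_t> tY((m + 1) * (n + 1), 0);
  auto ix = [n](int i, int j) { return i * (n + 1) + j; };

  M[ix(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[ix(i, 0)] = gap_open + (i - 1) * gap_ext;
    tX[ix(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    if (free_target_ends) {
      M[ix(0, j)] = 0.0;  // free leading target bases
    } else {
      Y[ix(0, j)] = gap_open + (j - 1) * gap_ext;
      tY[ix(0, j)] = (j == 1) ? 0 : 2;
    }
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M
      double bm = M[ix(i - 1, j - 1)], bx = X[ix(i - 1, j - 1)],
             by = Y[ix(i - 1, j - 1)];
      uint8_t tb = 0; double best = bm;
      if (bx > best) { best = bx; tb = 1; }
      if (by > best) { best = by; tb = 2; }
      if (best > NEG_INF / 2) { M[ix(i, j)] = best + s; tM[ix(i, j)] = tb; }
      // X : consume a[i-1] against a gap
      double xm = M[ix(i - 1, j)] + gap_open;
      double xx = X[ix(i - 1, j)] + gap_ext;
      if (xm >= xx) { X[ix(i, j)] = xm; tX[ix(i, j)] = 0; }
      else          { X[ix(i, j)] = xx; tX[ix(i, j)] = 1; }
      // Y : consume b[j-1] against a gap
      double ym = M[ix(i, j - 1)] + gap_open;
      double yy = Y[ix(i, j - 1)] + gap_ext;
      if (ym >= yy) { Y[ix(i, j)] = ym; tY[ix(i, j)] = 0; }
      else          { Y[ix(i, j)] = yy; tY[ix(i, j)] = 2; }
    }
  }

  // locate end cell
  int ei = m, ej = n; uint8_t es = 0; double score;
  if (free_target_ends) {
    score = NEG_INF; ej = 0;
    for (int j = 0; j <= n; ++j) {
      if (M[ix(m, j)] > score) { score = M[ix(m, j)]; ej = j; es = 0; }
      if (X[ix(m, j)] > score) { score = X[ix(m, j)]; ej = j; es = 1; }
    }
  } else {
    score = M[ix(m, n)]; es = 0;
    if (X[ix(m, n)] > score) { score = X[ix(m, n)]; es = 1; }
    if (Y[ix(m, n)] > score) { score = Y[ix(m, n)]; es = 2; }
  }

  // traceback
  std::string aa, bb;
  aa.reserve(m + n); bb.reserve(m + n);
  int i = ei, j = ej; uint8_t st = es;
  int t_end = ej;
  while (true) {
    if (free_target_ends) { if (i == 0) break; }
    else                  { if (i == 0 && j == 0) break; }
    if (st == 0) {
      uint8_t prev = tM[ix(i, j)];
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      --i; --j; st = prev;
    } else if (st == 1) {
      uint8_t prev = tX[ix(i, j)];
      aa.push_back(a[i - 1]); bb.push_back('-');
      --i; st = prev;
    } else {
      uint8_t prev = tY[ix(i, j)];
      aa.push_back('-'); bb.push_back(b[j - 1]);
      --j; st = prev;
    }
  }
  int t_start = j;  // 0-based start of aligned target block
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  int matches = 0, columns = aa.size();
  for (size_t c = 0; c < aa.size(); ++c)
    if (aa[c] == bb[c] && aa[c] != '-') ++matches;

  return List::create(_["score"] = score,
                      _["a_aln"] = aa, _["b_aln"] = bb,
                      _["t_start"] = t_start, _["t_end"] = t_end,
                      _["matches"] = matches, _["columns"] = columns);
}

// FNV-1a 32-bit content hash, returned as 8 lowercase hex digits.
// Used for stable cross-sample provisional naming of novel alleles.
// [[Rcpp::export]]
std::string cpp_hash8(std::string s) {
  uint32_t h = 2166136261u;
  for (unsigned char c : s) {
    h ^= (uint32_t)c;
    h *= 16777619u;
  }
  char buf[9];
  snprintf(buf, sizeof(buf), "%08x", h);
  return std::string(buf);
}
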