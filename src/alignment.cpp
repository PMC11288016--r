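#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local Smith-Waterman with linear gap costs, optionally restricted to a
// diagonal band.  Diagonal of cell (i,j) is d = j - i (1-based row i over the
// query a, column j over the target b).  Cells with d outside [dmin, dmax]
// are unreachable; a full alignment uses dmin = -len(a), dmax = len(b).
// 'N' (or any non-ACGT letter) never matches anything, including itself.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b,
                     int match, int mismatch, int gap,
                     int dmin, int dmax) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0)
    stop("sequences must be non-empty");
  const double ncell = (double)(la + 1) * (double)(lb + 1);
  if (ncell > 64e6)
    stop("sequence pair too long for exhaustive alignment matrix");

  std::vector<int> ac(la), bc(lb);
  for (int i = 0; i < la; ++i) ac[i] = base_code(a[i]);
  for (int j = 0; j < lb; ++j) bc[j] = base_code(b[j]);

  const int W = lb + 1;
  std::vector<int> H((size_t)(la + 1) * W, 0);
  // 0 stop, 1 diagonal, 2 up (gap in b), 3 left (gap in a)
  std::vector<unsigned char> D((size_t)(la + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(1, i + dmin), jhi = std::min(lb, i + dmax);
    const size_t row = (size_t)i * W, prev = (size_t)(i - 1) * W;
    for (int j = jlo; j <= jhi; ++j) {
      int s = (ac[i - 1] == bc[j - 1] && ac[i - 1] != 4) ? match : mismatch;
      int sc = H[prev + j - 1] + s;
      unsigned char dir = 1;
      int up = H[prev + j] - gap;
      if (up > sc) { sc = up; dir = 2; }
      int left = H[row + j - 1] - gap;
      if (left > sc) { sc = left; dir = 3; }
      if (sc <= 0) { sc = 0; dir = 0; }
      H[row + j] = sc;
      D[row + j] = dir;
      if (sc > best) { best = sc; bi = i; bj = j; }
    }
  }

  int matches = 0, mismatches = 0, gapopens = 0, columns = 0;
  int i = bi, j = bj, qe = bi, te = bj;
  int lastdir = 1;
  while (i > 0 && j > 0 && D[(size_t)i * W + j] != 0 && H[(size_t)i * W + j] > 0) {
    unsigned char dir = D[(size_t)i * W + j];
    ++columns;
    if (dir == 1) {
      if (ac[i - 1] == bc[j - 1] && ac[i - 1] != 4) ++matches; else ++mismatches;
      --i; --j;
    } else if (dir == 2) {
      if (lastdir != 2) ++gapopens;
      --i;
    } else {
      if (lastdir != 3) ++gapopens;
      --j;
    }
    lastdir = dir;
  }
  int qs = i + 1, ts = j + 1;
  if (best == 0) { qs = qe = ts = te = 0; columns = 0; }

  return List::create(
    _["score"] = best, _["qstart"] = qs, _["qend"] = qe,
    _["tstart"] = ts, _["tend"] = te, _["matches"] = matches,
    _["mismatches"] = mismatches, _["gapopens"] = gapopens,
    _["columns"] = columns);
}

// Primer3-style ungapped antiparallel complementarity score.  For every
// relative offset, a run score accumulates +1 per complementary pair and -1
// per non-pair, floored at zero (Kadane with reset); the result is the
// maximum over offsets.  anchor_end = 1 restricts to runs ending at a's 3'
// terminus.  min_loop >= 0 treats b as the same molecule as a (hairpin):
// position i of a may only pair with position j > i + min_loop.

static inline bool is_comp(int x, int y) {
  return (x == 0 && y == 3) || (x == 3 && y == 0) ||
         (x == 1 && y == 2) || (x == 2 && y == 1);
}

// [[Rcpp::export]]
int cpp_comp_score(std::string a, std::string b, bool anchor_end, int min_loop) {
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> ac(la), bc(lb);
  for (int i = 0; i < la; ++i) ac[i] = base_code(a[i]);
  for (int j = 0; j < lb; ++j) bc[j] = base_code(b[j]);
  int best = 0;
  for (int off = 0; off <= la + lb - 2; ++off) {
    // pairs (i, j = off - i), antiparallel duplex
    int run = 0, ahead = 0; // 'ahead': best run ending at current i
    for (int i = std::max(0, off - lb + 1); i <= std::min(la - 1, off); ++i) {
      int j = off - i;
      if (min_loop >= 0 && j - i - 1 < min_loop) continue;
      run += is_comp(ac[i], bc[j]) ? 1 : -1;
      if (run < 0) run = 0;
      ahead = run;
      if (!anchor_end && run > best) best = run;
      if (anchor_end && i == la - 1 && ahead > best) best = ahead;
    }
  }
  return best;
}
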