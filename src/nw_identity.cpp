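#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps:
// match +1, mismatch -1, gap open 2, gap extend 1 (a gap of length L
// costs 2 + L). Returns the number of aligned positions carrying the
// same standard amino-acid letter; ambiguity letters never count as
// identical even when equal. Tie-breaks are fixed (diagonal, then gap
// in b, then gap in a), so results are deterministic.

static const int NEG = -1000000000;

static inline bool is_standard(char c) {
  switch (c) {
    case 'A': case 'C': case 'D': case 'E': case 'F': case 'G':
    case 'H': case 'I': case 'K': case 'L': case 'M': case 'N':
    case 'P': case 'Q': case 'R': case 'S': case 'T': case 'V':
    case 'W': case 'Y': return true;
    default: return false;
  }
}

// state codes: 0 = M (diagonal), 1 = X (gap in b, consume a),
// 2 = Y (gap in a, consume b)
static void nw_identical(const std::string& a, const std::string& b,
                         int& ident_out, int& score_out) {
  const int n = (int) a.size(), m = (int) b.size();
  const int GO = 2, GE = 1;
  const int W = m + 1;
  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
                   Y((n + 1) * W, NEG);
  // ptr[s][idx]: predecessor state when arriving at idx in state s
  std::vector<signed char> pM((n + 1) * W, -1), pX((n + 1) * W, -1),
                           pY((n + 1) * W, -1);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) { X[i * W] = -(GO + GE * i); pX[i * W] = 1; }
  pX[W] = 0;  // first gap opens out of M at the origin
  for (int j = 1; j <= m; ++j) { Y[j] = -(GO + GE * j); pY[j] = 2; }
  pY[1] = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j, di = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      const int s = (a[i - 1] == b[j - 1]) ? 1 : -1;
      // M: best predecessor at the diagonal
      int bestv = M[di]; signed char bests = 0;
      if (X[di] > bestv) { bestv = X[di]; bests = 1; }
      if (Y[di] > bestv) { bestv = Y[di]; bests = 2; }
      if (bestv > NEG) { M[idx] = bestv + s; pM[idx] = bests; }
      // X: consume a[i-1] against a gap
      int xv = (M[up] > NEG) ? M[up] - (GO + GE) : NEG;
      signed char xs = 0;
      if (X[up] > NEG && X[up] - GE > xv) { xv = X[up] - GE; xs = 1; }
      if (Y[up] > NEG && Y[up] - (GO + GE) > xv) {
        xv = Y[up] - (GO + GE); xs = 2;
      }
      if (xv > NEG) { X[idx] = xv; pX[idx] = xs; }
      // Y: consume b[j-1] against a gap
      int yv = (M[lf] > NEG) ? M[lf] - (GO + GE) : NEG;
      signed char ys = 0;
      if (Y[lf] > NEG && Y[lf] - GE > yv) { yv = Y[lf] - GE; ys = 2; }
      if (X[lf] > NEG && X[lf] - (GO + GE) > yv) {
        yv = X[lf] - (GO + GE); ys = 1;
      }
      if (yv > NEG) { Y[idx] = yv; pY[idx] = ys; }
    }
  }
  const int end = n * W + m;
  int state = 0, best = M[end];
  if (X[end] > best) { best = X[end]; state = 1; }
  if (Y[end] > best) { best = Y[end]; state = 2; }
  int i = n, j = m, ident = 0;
  while (i > 0 || j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      const char ca = a[i - 1], cb = b[j - 1];
      if (ca == cb && is_standard(ca)) ++ident;
      state = pM[idx]; --i; --j;
    } else if (state == 1) {
      state = pX[idx]; --i;
    } else {
      state = pY[idx]; --j;
    }
  }
  ident_out = ident;
  score_out = best;
}

// [[Rcpp::export(name = ".nw_identity_count")]]
IntegerMatrix nw_identity_count(std::string a, CharacterVector b) {
  IntegerMatrix out(2, b.size());
  for (R_xlen_t k = 0; k < b.size(); ++k) {
    std::string bk = as<std::string>(b[k]);
    int ident = 0, score = 0;
    // canonical argument order makes the count symmetric by construction
    if (bk.size() < a.size() || (bk.size() == a.size() && bk < a))
      nw_identical(bk, a, ident, score);
    else
      nw_identical(a, bk, ident, score);
    out(0, k) = ident;
    out(1, k) = score;
  }
  return out;
}
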