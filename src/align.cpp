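#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks: A=1, C=2, G=4, T/U=8.
static int iupac_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'M': return 1 | 2;
    case 'R': return 1 | 4;
    case 'W': return 1 | 8;
    case 'S': return 2 | 4;
    case 'Y': return 2 | 8;
    case 'K': return 4 | 8;
    case 'V': return 1 | 2 | 4;
    case 'H': return 1 | 2 | 8;
    case 'D': return 1 | 4 | 8;
    case 'B': return 2 | 4 | 8;
    case 'N': return 1 | 2 | 4 | 8;
    default:  return 0;
  }
}

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state DP.
// A gap of length g costs gap_open + (g-1) * gap_extend (penalties passed as
// negative scores). A column "matches" when the two IUPAC sets intersect, so
// an ambiguity code in the query matches any base contained in its set.
// Traceback ties are broken diagonal > up (gap in b) > left (gap in a).
//
// States: M = column consumes both sequences, X = gap in b (consumes a, "up"),
// Y = gap in a (consumes b, "left").
// [[Rcpp::export]]
List nw_align_c(std::string a, std::string b,
                double match, double mismatch,
                double gap_open, double gap_extend) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  std::vector<int> ma(n), mb(m);
  for (int i = 0; i < n; ++i) {
    ma[i] = iupac_mask(a[i]);
    if (ma[i] == 0) stop("invalid nucleotide character in first sequence");
  }
  for (int j = 0; j < m; ++j) {
    mb[j] = iupac_mask(b[j]);
    if (mb[j] == 0) stop("invalid nucleotide character in second sequence");
  }

  const double NEG = -1e18;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[j]     = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int id = i * W + j, dg = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      const double s = (ma[i - 1] & mb[j - 1]) ? match : mismatch;
      double best = M[dg];
      if (X[dg] > best) best = X[dg];
      if (Y[dg] > best) best = Y[dg];
      M[id] = best + s;
      double xo = M[up] + gap_open, xe = X[up] + gap_extend, xy = Y[up] + gap_open;
      X[id] = xo >= xe ? (xo >= xy ? xo : xy) : (xe >= xy ? xe : xy);
      double yo = M[lf] + gap_open, ye = Y[lf] + gap_extend, yx = X[lf] + gap_open;
      Y[id] = yo >= ye ? (yo >= yx ? yo : yx) : (ye >= yx ? ye : yx);
    }
  }

  // final state, tie preference M (diagonal) > X (up) > Y (left)
  int i = n, j = m, state;
  double score;
  {
    const int id = n * W + m;
    if (M[id] >= X[id] && M[id] >= Y[id]) { state = 0; score = M[id]; }
    else if (X[id] >= Y[id])              { state = 1; score = X[id]; }
    else                                  { state = 2; score = Y[id]; }
  }

  long matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    const int id = i * W + j;
    if (state == 0) {
      // column (a[i-1], b[j-1])
      ++cols;
      if (ma[i - 1] & mb[j - 1]) ++matches;
      const int dg = (i - 1) * W + (j - 1);
      const double prev = M[id] - ((ma[i - 1] & mb[j - 1]) ? match : mismatch);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[dg] == prev) state = 0;
      else if (X[dg] == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      // gap in b: consume a[i-1]
      ++cols;
      const int up = (i - 1) * W + j;
      double cur = X[id];
      --i;
      if (M[up] + gap_open == cur) state = 0;
      else if (X[up] + gap_extend == cur) state = 1;
      else state = 2;
    } else {
      // gap in a: consume b[j-1]
      ++cols;
      const int lf = i * W + (j - 1);
      double cur = Y[id];
      --j;
      if (M[lf] + gap_open == cur) state = 0;
      else if (Y[lf] + gap_extend == cur) state = 2;
      else state = 1;
    }
  }

  return List::create(
    _["identity"] = 100.0 * (double) matches / (double) cols,
    _["alignment_length"] = (double) cols,
    _["matches"] = (double) matches,
    _["score"] = score);
}
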