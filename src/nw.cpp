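#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Banded global alignment (Needleman-Wunsch, linear gap penalty).
//
// a, b: 1-based integer symbol codes. band < 0 requests the full dynamic
// programming matrix. The band is centred on the straight line from (0,0)
// to (n,m) in the DP grid; its half-width is widened automatically so that
// consecutive rows always overlap.
//
// Tie-break, applied at fill time so the traceback is deterministic:
//   diagonal > up (gap in b, consumes a) > left (gap in a, consumes b).
//
// Returns list(ai, bi, score, band_hit): ai/bi are 1-based indices into a
// and b per alignment column, NA for a gap; band_hit reports whether the
// optimal path touched the band boundary anywhere strictly inside the grid
// (callers should then retry with a wider band).
// [[Rcpp::export(name = ".nw_align_c")]]
List nw_align_c(IntegerVector a, IntegerVector b,
                double match, double mismatch, double gap, int band) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e300;

  // trivial cases: one sequence empty -> all gap columns
  if (n == 0 || m == 0) {
    int len = n + m;
    IntegerVector ai(len, NA_INTEGER), bi(len, NA_INTEGER);
    for (int i = 0; i < n; ++i) ai[i] = i + 1;
    for (int j = 0; j < m; ++j) bi[n + j] = j + 1;
    return List::create(_["ai"] = ai, _["bi"] = bi,
                        _["score"] = gap * len, _["band_hit"] = false);
  }

  long w = (band < 0) ? (long)std::max(n, m) : (long)band;
  long drift = (long)std::ceil((double)m / n) + 1;
  if (w < drift) w = drift;
  if (w < 1) w = 1;

  std::vector<int> lo(n + 1), hi(n + 1);
  for (int i = 0; i <= n; ++i) {
    double c = (double)i * m / n;
    long l = (long)std::floor(c) - w;
    long h = (long)std::ceil(c) + w;
    lo[i] = (int)(l < 0 ? 0 : l);
    hi[i] = (int)(h > m ? m : h);
  }
  lo[0] = 0;
  hi[n] = m;

  int width = 0;
  for (int i = 0; i <= n; ++i)
    if (hi[i] - lo[i] + 1 > width) width = hi[i] - lo[i] + 1;

  std::vector<double> S((size_t)(n + 1) * width, NEG);
  std::vector<unsigned char> P((size_t)(n + 1) * width, 0);
#define IDX(i, j) ((size_t)(i) * width + ((j) - lo[i]))

  for (int j = lo[0]; j <= hi[0]; ++j) {
    S[IDX(0, j)] = gap * j;
    P[IDX(0, j)] = (j > 0) ? 3 : 0;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = lo[i]; j <= hi[i]; ++j) {
      double best = NEG;
      unsigned char ptr = 0;
      if (j >= 1 && j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) {
        double sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
        double s = S[IDX(i - 1, j - 1)];
        if (s > NEG / 2) { best = s + sub; ptr = 1; }
      }
      if (j >= lo[i - 1] && j <= hi[i - 1]) {
        double s = S[IDX(i - 1, j)];
        if (s > NEG / 2 && s + gap > best) { best = s + gap; ptr = 2; }
      }
      if (j >= 1 && j - 1 >= lo[i]) {
        double s = S[IDX(i, j - 1)];
        if (s > NEG / 2 && s + gap > best) { best = s + gap; ptr = 3; }
      }
      S[IDX(i, j)] = best;
      P[IDX(i, j)] = ptr;
    }
  }

  double score = S[IDX(n, m)];

  // traceback
  std::vector<int> rai, rbi;
  rai.reserve(n + m);
  rbi.reserve(n + m);
  bool band_hit = false;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (j > 0 && j < m && (j == lo[i] || j == hi[i])) band_hit = true;
    unsigned char p = P[IDX(i, j)];
    if (p == 1) {
      rai.push_back(i); rbi.push_back(j); --i; --j;
    } else if (p == 2) {
      rai.push_back(i); rbi.push_back(NA_INTEGER); --i;
    } else if (p == 3) {
      rai.push_back(NA_INTEGER); rbi.push_back(j); --j;
    } else {
      stop("alignment traceback failed (band too narrow)");
    }
  }
  int len = rai.size();
  IntegerVector ai(len), bi(len);
  for (int k = 0; k < len; ++k) {
    ai[k] = rai[len - 1 - k];
    bi[k] = rbi[len - 1 - k];
  }
#undef IDX
  return List::create(_["ai"] = ai, _["bi"] = bi,
                      _["score"] = score, _["band_hit"] = band_hit);
}
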