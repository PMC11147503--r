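#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// End-free ("glocal") alignment of a read against a reference with a
// two-piece affine gap penalty: a gap of length k costs
//   min(gap_open + k * gap_extend, gap_open2 + k * gap_extend2),
// the second piece keeping long gaps (e.g. a 143 bp insert) contiguous
// instead of fragmenting through chance micro-matches. The reference
// flanks are free; the read must be fully aligned, so unaligned read ends
// appear as terminal insertions (converted to soft clips downstream).
//
// Banding restricts the diagonal offset d = j - i to
// [min(0, m-n) - band, max(0, m-n) + band]; `touched_boundary` reports
// whether the optimal traceback ran along the band edge, signalling the
// caller to widen.
//
// Tie-breaking is deterministic: diagonal is preferred, then deletion,
// then insertion; among equal end cells the leftmost reference end wins.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// traceback codes: 1 = M, 2 = X (short del), 3 = Y (short ins),
// 4 = fresh start, 5 = X2 (long del), 6 = Y2 (long ins)

// [[Rcpp::export(name = ".align_glocal_cpp")]]
List align_glocal_cpp(std::string read, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      double gap_open2, double gap_extend2,
                      int band) {
  const int n = read.size(), m = ref.size();
  if (n == 0 || m == 0) stop("empty read or reference");
  const long dlo = std::min(0, m - n) - band;
  const long dhi = std::max(0, m - n) + band;
  const bool full = (dlo <= -n) && (dhi >= m);

  const size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<double> M(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF),
                      X2(sz, NEG_INF), Y2(sz, NEG_INF);
  std::vector<unsigned char> tbM(sz, 0), tbX(sz, 0), tbY(sz, 0),
                             tbX2(sz, 0), tbY2(sz, 0);
  #define IDX(i, j) ((size_t)(i) * (m + 1) + (j))

  for (int j = 0; j <= m; ++j) { M[IDX(0, j)] = 0.0; tbM[IDX(0, j)] = 4; }
  for (int i = 1; i <= n; ++i) {
    long d0 = -(long)i;
    if (d0 >= dlo && d0 <= dhi) {
      Y[IDX(i, 0)] = -(gap_open + gap_extend * i);
      tbY[IDX(i, 0)] = (i == 1) ? 1 : 3;
      Y2[IDX(i, 0)] = -(gap_open2 + gap_extend2 * i);
      tbY2[IDX(i, 0)] = (i == 1) ? 1 : 6;
    }
  }

  for (int i = 1; i <= n; ++i) {
    int jlo = (int)std::max(1L, (long)i + dlo);
    int jhi = (int)std::min((long)m, (long)i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      const size_t c = IDX(i, j), d = IDX(i - 1, j - 1),
                   u = IDX(i - 1, j), l = IDX(i, j - 1);
      const double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      // M: prefer M > X > X2 > Y > Y2 on ties
      double best = M[d]; unsigned char from = 1;
      if (X[d] > best)  { best = X[d];  from = 2; }
      if (X2[d] > best) { best = X2[d]; from = 5; }
      if (Y[d] > best)  { best = Y[d];  from = 3; }
      if (Y2[d] > best) { best = Y2[d]; from = 6; }
      if (best > NEG_INF) { M[c] = best + s; tbM[c] = from; }
      // X / X2: gap in read (deletion from reference), consumes ref
      double xo = (M[l] > NEG_INF) ? M[l] - gap_open - gap_extend : NEG_INF;
      double xe = (X[l] > NEG_INF) ? X[l] - gap_extend : NEG_INF;
      if (xo >= xe) { if (xo > NEG_INF) { X[c] = xo; tbX[c] = 1; } }
      else { X[c] = xe; tbX[c] = 2; }
      double x2o = (M[l] > NEG_INF) ? M[l] - gap_open2 - gap_extend2 : NEG_INF;
      double x2e = (X2[l] > NEG_INF) ? X2[l] - gap_extend2 : NEG_INF;
      if (x2o >= x2e) { if (x2o > NEG_INF) { X2[c] = x2o; tbX2[c] = 1; } }
      else { X2[c] = x2e; tbX2[c] = 5; }
      // Y / Y2: insertion (consumes read)
      double yo = (M[u] > NEG_INF) ? M[u] - gap_open - gap_extend : NEG_INF;
      double ye = (Y[u] > NEG_INF) ? Y[u] - gap_extend : NEG_INF;
      if (yo >= ye) { if (yo > NEG_INF) { Y[c] = yo; tbY[c] = 1; } }
      else { Y[c] = ye; tbY[c] = 3; }
      double y2o = (M[u] > NEG_INF) ? M[u] - gap_open2 - gap_extend2 : NEG_INF;
      double y2e = (Y2[u] > NEG_INF) ? Y2[u] - gap_extend2 : NEG_INF;
      if (y2o >= y2e) { if (y2o > NEG_INF) { Y2[c] = y2o; tbY2[c] = 1; } }
      else { Y2[c] = y2e; tbY2[c] = 6; }
    }
  }

  // end: read fully consumed, free reference suffix; leftmost j on ties
  double best = NEG_INF; int bj = -1; int bstate = 1;
  for (int j = 0; j <= m; ++j) {
    const size_t c = IDX(n, j);
    if (M[c] > best)  { best = M[c];  bj = j; bstate = 1; }
    if (Y[c] > best)  { best = Y[c];  bj = j; bstate = 3; }
    if (Y2[c] > best) { best = Y2[c]; bj = j; bstate = 6; }
  }
  if (bj < 0) return List::create(_["ok"] = false);

  // traceback; a cell in state M with i == 0 is a free start
  std::string opstr;
  int i = n, j = bj, state = bstate;
  bool touched = false;
  while (!(i == 0 && state == 1)) {
    long dcur = (long)j - i;
    if (!full && (dcur <= dlo || dcur >= dhi)) touched = true;
    unsigned char f;
    if (state == 1) {
      f = tbM[IDX(i, j)];
      opstr.push_back('M'); --i; --j;
    } else if (state == 2) {
      f = tbX[IDX(i, j)];
      opstr.push_back('D'); --j;
      if (f == 1) { state = 1; continue; }
    } else if (state == 5) {
      f = tbX2[IDX(i, j)];
      opstr.push_back('D'); --j;
      if (f == 1) { state = 1; continue; }
    } else if (state == 3) {
      f = tbY[IDX(i, j)];
      opstr.push_back('I'); --i;
      if (f == 1) { state = 1; continue; }
    } else {
      f = tbY2[IDX(i, j)];
      opstr.push_back('I'); --i;
      if (f == 1) { state = 1; continue; }
    }
    state = (f == 4) ? 1 : f;
  }
  std::reverse(opstr.begin(), opstr.end());

  std::vector<std::string> ops; std::vector<int> lens;
  for (char ch : opstr) {
    if (!ops.empty() && ops.back()[0] == ch) lens.back()++;
    else { ops.push_back(std::string(1, ch)); lens.push_back(1); }
  }
  return List::create(
    _["ok"] = true, _["score"] = best, _["ref_start"] = j,
    _["op"] = ops, _["len"] = lens,
    _["touched_boundary"] = touched);
}
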