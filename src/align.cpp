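#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh). A gap run of length L costs
// gap_open + gap_extend * (L - 1), so open == extend gives linear gap costs.
// Traceback ties are broken diagonal > up (gap in b) > left (gap in a) so the
// reported alignment is deterministic. Scores use rolling rows; only the
// 2-bit-per-state traceback is kept in full.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List align_affine_cpp(std::string a, std::string b,
                      int match, int mismatch,
                      int gap_open, int gap_extend,
                      bool free_end_gaps) {
  const int n = (int) a.size(), m = (int) b.size();
  const int GO = gap_open, GE = gap_extend;
  // state 0 = M (diagonal), 1 = X (up: a[i] over gap), 2 = Y (left: gap over b[j])
  std::vector<int> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1),
      Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
  std::vector<unsigned char> trace((size_t)(n + 1) * (m + 1));
  // trace byte: bits 0-1 predecessor of M, 2-3 of X, 4-5 of Y
  const size_t W = m + 1;

  Mprev[0] = 0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG; Xprev[j] = NEG;
    Yprev[j] = free_end_gaps ? 0 : -(GO + GE * (j - 1));
    trace[j] = 2u << 4;
  }

  // best scores on the last row/column for free end gaps
  int best = NEG, ei = n, ej = m, estate = 0;

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG; Ycur[0] = NEG;
    Xcur[0] = free_end_gaps ? 0 : -(GO + GE * (i - 1));
    trace[(size_t)i * W] = 1u << 2;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      unsigned char tb = 0;
      int s = (ai == b[j - 1] && ai != 'N') ? match : -mismatch;
      // M: preference M > X > Y on ties
      int vM = Mprev[j - 1], v = vM; unsigned char t = 0;
      if (Xprev[j - 1] > v) { v = Xprev[j - 1]; t = 1; }
      if (Yprev[j - 1] > v) { v = Yprev[j - 1]; t = 2; }
      Mcur[j] = (v <= NEG) ? NEG : v + s;
      tb |= t;
      // X (consume a[i], gap in b)
      v = (Mprev[j] <= NEG) ? NEG : Mprev[j] - GO; t = 0;
      int w = (Xprev[j] <= NEG) ? NEG : Xprev[j] - GE;
      if (w > v) { v = w; t = 1; }
      w = (Yprev[j] <= NEG) ? NEG : Yprev[j] - GO;
      if (w > v) { v = w; t = 2; }
      Xcur[j] = v;
      tb |= t << 2;
      // Y (consume b[j], gap in a)
      v = (Mcur[j - 1] <= NEG) ? NEG : Mcur[j - 1] - GO; t = 0;
      w = (Xcur[j - 1] <= NEG) ? NEG : Xcur[j - 1] - GO;
      if (w > v) { v = w; t = 1; }
      w = (Ycur[j - 1] <= NEG) ? NEG : Ycur[j - 1] - GE;
      if (w > v) { v = w; t = 2; }
      Ycur[j] = v;
      tb |= t << 4;
      trace[(size_t)i * W + j] = tb;

      if (free_end_gaps && (j == m || i == n)) {
        if (Mcur[j] > best) { best = Mcur[j]; ei = i; ej = j; estate = 0; }
        if (Xcur[j] > best) { best = Xcur[j]; ei = i; ej = j; estate = 1; }
        if (Ycur[j] > best) { best = Ycur[j]; ei = i; ej = j; estate = 2; }
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  // after the swap the final row lives in *prev
  if (!free_end_gaps) {
    best = Mprev[m]; estate = 0;
    if (Xprev[m] > best) { best = Xprev[m]; estate = 1; }
    if (Yprev[m] > best) { best = Yprev[m]; estate = 2; }
    ei = n; ej = m;
  } else {
    // the empty-prefix corner can beat interior cells on degenerate input
    if (0 > best && n == 0) { best = 0; ei = 0; ej = 0; estate = 0; }
  }

  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  for (int i = n; i > ei; --i) { ga.push_back(a[i - 1]); gb.push_back('-'); }
  for (int j = m; j > ej; --j) { ga.push_back('-'); gb.push_back(b[j - 1]); }
  int i = ei, j = ej, state = estate;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    unsigned char tb = trace[(size_t)i * W + j];
    if (state == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; state = tb & 3u;
    } else if (state == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; state = (tb >> 2) & 3u;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; state = (tb >> 4) & 3u;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = (double) best);
}

// Ungapped X-drop extension along one diagonal of a self-comparison.
// Positions i (5' copy) and j (3' copy) are 0-based seed starts, len the seed
// length; scores +1 match / -mismatch_pen, stop when running score drops more
// than xdrop below the running maximum. Returns 0-based [start_i, end_i] of
// the extended run on the 5' copy plus the match count.
// [[Rcpp::export]]
IntegerVector extend_diagonal_cpp(std::string s, int i, int j, int len,
                                  int mismatch_pen, int xdrop) {
  const int n = (int) s.size();
  int best_left = i, best_right = i + len - 1;
  long run = 0, mx = 0;
  for (int k = i + len, l = j + len; l < n && k < j; ++k, ++l) {
    run += (s[k] == s[l] && s[k] != 'N') ? 1 : -mismatch_pen;
    if (run > mx) { mx = run; best_right = k; }
    if (mx - run > xdrop) break;
  }
  run = 0; mx = 0;
  for (int k = i - 1, l = j - 1; k >= 0 && l >= i + len; --k, --l) {
    run += (s[k] == s[l] && s[k] != 'N') ? 1 : -mismatch_pen;
    if (run > mx) { mx = run; best_left = k; }
    if (mx - run > xdrop) break;
  }
  int matches = 0;
  int off = j - i;
  for (int k = best_left; k <= best_right; ++k) {
    if (s[k] == s[k + off] && s[k] != 'N') ++matches;
  }
  return IntegerVector::create(best_left, best_right, matches);
}

// Site-pattern counts for two equal-length gapped rows under complete
// deletion: n comparable sites, transition and transversion difference counts.
// [[Rcpp::export]]
IntegerVector site_patterns_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("rows differ in length");
  auto code = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'G': return 1;
                 case 'C': return 2; case 'T': return 3; default: return -1; }
  };
  int n = 0, ts = 0, tv = 0;
  for (size_t k = 0; k < a.size(); ++k) {
    int x = code(a[k]), y = code(b[k]);
    if (x < 0 || y < 0) continue;
    ++n;
    if (x != y) {
      if ((x < 2) == (y < 2)) ++ts; else ++tv;
    }
  }
  return IntegerVector::create(n, ts, tv);
}
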