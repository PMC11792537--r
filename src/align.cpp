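#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
#include <array>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh). A gap of length L
// costs gap_open + L * gap_ext, matching the BLASTN-style -5/-2 convention
// when gap_open = 5 and gap_ext = 2 (penalties passed as positive numbers).
//
// Two entry points share the recurrence but not the search strategy:
//  * cpp_local_align: single best alignment, optionally restricted to a
//    diagonal band (j - i within [band_lo, band_hi]) with one forbidden
//    diagonal (used to exclude the trivial self-identity);
//  * cpp_sw_enumerate: iterative extraction of all local alignments with
//    score >= min_score over the full matrix, masking the bounding
//    rectangle of each accepted alignment before re-running the DP.
//
// Tie-break order everywhere: diagonal > vertical (gap in b) > horizontal
// (gap in a), and among equal best scores the smallest (i, j) end cell.

struct AlnResult {
  int score;
  int start1, end1, start2, end2;  // 1-based, inclusive; 0 if empty
  std::string aln1, aln2;
};

static inline int subst(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return mismatch;  // never reward ambiguity
  return (x == y) ? match : -mismatch;
}

// Core DP. allowed(i,j) gives cell admissibility (1-based i over a, j over b).
template <typename Allowed>
static AlnResult sw_core(const std::string& a, const std::string& b,
                         int match, int mismatch, int gap_open, int gap_ext,
                         Allowed allowed) {
  const int n = a.size(), m = b.size();
  const int NEG = INT_MIN / 4;
  const int gop = gap_open + gap_ext;  // cost of opening a length-1 gap
  // pointer codes: 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG);  // gap in a (left)
  std::vector<int> Fcur(m + 1, NEG), Fprev(m + 1, NEG);  // gap in b (up)
  std::vector<unsigned char> ptrH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> ptrE((size_t)(n + 1) * (m + 1), 0);  // 1: from H
  std::vector<unsigned char> ptrF((size_t)(n + 1) * (m + 1), 0);  // 1: from H
  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t at = (size_t)i * (m + 1) + j;
      if (!allowed(i, j)) {
        Hcur[j] = 0; Ecur[j] = NEG; Fcur[j] = NEG;
        ptrH[at] = 0;
        continue;
      }
      int e_open = Hcur[j - 1] - gop;
      int e_ext  = Ecur[j - 1] - gap_ext;
      int E = (e_open >= e_ext) ? e_open : e_ext;
      ptrE[at] = (e_open >= e_ext) ? 1 : 0;
      Ecur[j] = E;

      int f_open = Hprev[j] - gop;
      int f_ext  = Fprev[j] - gap_ext;
      int F = (f_open >= f_ext) ? f_open : f_ext;
      ptrF[at] = (f_open >= f_ext) ? 1 : 0;
      Fcur[j] = F;

      int diag = Hprev[j - 1] + subst(a[i - 1], b[j - 1], match, mismatch);
      int h = 0; unsigned char p = 0;
      if (diag >= h) { h = diag; p = 1; }
      if (F > h)     { h = F;    p = 2; }
      if (E > h)     { h = E;    p = 3; }
      if (h <= 0)    { h = 0;    p = 0; }
      Hcur[j] = h; ptrH[at] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }

  AlnResult res;
  res.score = best;
  if (best <= 0) { res.start1 = res.end1 = res.start2 = res.end2 = 0; return res; }

  // traceback over stored pointers
  std::string x, y;
  int i = bi, j = bj;
  int state = 0;  // 0 in H, 1 in F (up), 2 in E (left)
  while (true) {
    size_t at = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char p = ptrH[at];
      if (p == 0) break;
      if (p == 1) { x += a[i - 1]; y += b[j - 1]; --i; --j; }
      else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {       // gap in b: consume a[i]
      x += a[i - 1]; y += '-';
      unsigned char from_h = ptrF[at];
      --i;
      if (from_h) state = 0;
    } else {                        // gap in a: consume b[j]
      x += '-'; y += b[j - 1];
      unsigned char from_h = ptrE[at];
      --j;
      if (from_h) state = 0;
    }
  }
  std::reverse(x.begin(), x.end());
  std::reverse(y.begin(), y.end());
  res.start1 = i + 1; res.end1 = bi;
  res.start2 = j + 1; res.end2 = bj;
  res.aln1 = x; res.aln2 = y;
  return res;
}

static List as_list(const AlnResult& r) {
  return List::create(_["score"] = r.score,
                      _["start1"] = r.start1, _["end1"] = r.end1,
                      _["start2"] = r.start2, _["end2"] = r.end2,
                      _["aln1"] = r.aln1, _["aln2"] = r.aln2);
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int band_lo, int band_hi, int forbid_diag,
                     bool use_band, bool use_forbid) {
  AlnResult r = sw_core(a, b, match, mismatch, gap_open, gap_ext,
    [&](int i, int j) {
      int d = j - i;
      if (use_band && (d < band_lo || d > band_hi)) return false;
      if (use_forbid && d == forbid_diag) return false;
      return true;
    });
  return as_list(r);
}

// Masks only the bounding rectangle of each accepted alignment so that a
// repeat serving several partners (one DGR template repeat with multiple
// variable repeats) is reported once per partner.
// [[Rcpp::export]]
List cpp_sw_enumerate(std::string a, std::string b,
                      int match, int mismatch, int gap_open, int gap_ext,
                      int min_score, bool upper_only, int max_hits) {
  std::vector<std::array<int, 4>> rects;
  List hits;
  for (int pass = 0; pass < max_hits; ++pass) {
    AlnResult r = sw_core(a, b, match, mismatch, gap_open, gap_ext,
      [&](int i, int j) {
        if (upper_only && j <= i) return false;
        for (const auto& rc : rects) {
          if (i >= rc[0] && i <= rc[1] && j >= rc[2] && j <= rc[3])
            return false;
        }
        return true;
      });
    if (r.score < min_score || r.end1 == 0) break;
    hits.push_back(as_list(r));
    rects.push_back({r.start1, r.end1, r.start2, r.end2});
  }
  return hits;
}
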