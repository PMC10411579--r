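#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Seeded approximate-occurrence search used for flank anchoring and bait
// placement. Candidate locations come from exact k-mer seeds tiled along the
// pattern; each candidate window is then scored by a full semi-global
// (free text ends) edit-distance DP that also tracks the alignment start.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;   // N, X separators, IUPAC codes: never seed-match
  }
}

// [[Rcpp::export]]
List cpp_kmer_index(std::string text, int k) {
  if (k < 4 || k > 15) stop("k must be in [4, 15]");
  const int n = (int) text.size();
  std::vector<std::pair<int, int> > entries;  // (code, pos)
  entries.reserve(n > k ? n - k + 1 : 0);
  int code = 0, valid = 0;
  const int mask = (1 << (2 * k)) - 1;
  for (int i = 0; i < n; ++i) {
    int b = base_code(text[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    valid = std::min(valid + 1, k);
    if (valid == k) entries.push_back(std::make_pair(code, i - k + 1));
  }
  std::sort(entries.begin(), entries.end());
  IntegerVector keys(entries.size()), pos(entries.size());
  for (size_t i = 0; i < entries.size(); ++i) {
    keys[i] = entries[i].first;
    pos[i] = entries[i].second;
  }
  return List::create(_["keys"] = keys, _["pos"] = pos, _["k"] = k);
}

// Banded semi-global DP of pattern against text[ws, we): per-end-position
// distance and alignment start for the final pattern row (rolling rows).
// Cells outside the band around the candidate diagonals (width spread +
// 2*max_dist) cannot belong to an alignment within the edit budget.
static const int DP_INF = 1 << 28;
static void window_dp(const std::string &pat, const std::string &text,
                      int ws, int we, int dlo, int dhi, int max_dist,
                      std::vector<int> &dist_out, std::vector<int> &start_out) {
  const int m = (int) pat.size();
  const int w = we - ws;
  std::vector<int> dPrev(w + 1, DP_INF), dCur(w + 1, DP_INF),
                   sPrev(w + 1, 0), sCur(w + 1, 0);
  // row 0: free start anywhere in the window
  for (int j = 0; j <= w; ++j) { dPrev[j] = 0; sPrev[j] = j; }
  const int slack = max_dist + 1;
  bool dead = false;
  for (int i = 1; i <= m; ++i) {
    // valid text columns for pattern row i lie near diagonals dlo..dhi
    int jlo = std::max(0, i + (dlo - ws) - slack);
    int jhi = std::min(w, i + (dhi - ws) + slack);
    if (jlo > jhi) { dead = true; break; }  // band left the window
    if (jlo > 0) dCur[jlo - 1] = DP_INF;
    if (jhi < w) dCur[jhi + 1] = DP_INF;
    const char pc = pat[i - 1];
    if (jlo == 0) { dCur[0] = i; sCur[0] = 0; ++jlo; }
    for (int j = jlo; j <= jhi; ++j) {
      const char tc = text[ws + j - 1];
      int sub = dPrev[j - 1] + (pc == tc && pc != 'X' && tc != 'X' ? 0 : 1);
      int del = dPrev[j] + 1;      // consume pattern char, gap in text
      int ins = dCur[j - 1] + 1;   // consume text char, gap in pattern
      int d = sub, s = sPrev[j - 1];
      if (del < d) { d = del; s = sPrev[j]; }
      if (ins < d) { d = ins; s = sCur[j - 1]; }
      dCur[j] = d; sCur[j] = s;
    }
    std::swap(dPrev, dCur); std::swap(sPrev, sCur);
  }
  // cells outside the final row's band are stale: mask them
  int jlo_m = std::max(0, std::min(w + 1, m + (dlo - ws) - slack));
  int jhi_m = std::min(w, m + (dhi - ws) + slack);
  if (dead) jlo_m = w + 1;  // no full-pattern alignment fits this window
  for (int j = 0; j < jlo_m; ++j) dPrev[j] = DP_INF;
  for (int j = jhi_m + 1; j <= w; ++j) dPrev[j] = DP_INF;
  dist_out.assign(dPrev.begin(), dPrev.end());
  start_out.assign(sPrev.begin(), sPrev.end());
}

// Search pattern in text using a prebuilt k-mer index. Returns a matrix of
// accepted hits (columns: start, end, dist; 0-based half-open), best first,
// collapsed so no two hits overlap by more than half the pattern length.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_search(std::string pattern, std::string text,
                              IntegerVector keys, IntegerVector pos,
                              int k, int max_dist, int max_hits = 16,
                              int min_support = 1) {
  const int m = (int) pattern.size();
  const int n = (int) text.size();
  if (m < k) stop("pattern shorter than seed length");
  if (max_dist < 0) stop("max_dist must be >= 0");

  // Tile seeds every k bases plus one flush with the pattern end.
  std::vector<int> offsets;
  for (int o = 0; o + k <= m; o += k) offsets.push_back(o);
  if (offsets.empty() || offsets.back() != m - k) offsets.push_back(m - k);

  std::vector<int> diags;
  for (size_t oi = 0; oi < offsets.size(); ++oi) {
    int o = offsets[oi];
    int code = 0; bool ok = true;
    for (int i = 0; i < k; ++i) {
      int b = base_code(pattern[o + i]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | b;
    }
    if (!ok) continue;
    IntegerVector::iterator lo = std::lower_bound(keys.begin(), keys.end(), code);
    for (IntegerVector::iterator it = lo; it != keys.end() && *it == code; ++it) {
      int p = pos[it - keys.begin()];
      diags.push_back(p - o);
    }
  }
  if (diags.empty()) return IntegerMatrix(0, 3);
  std::sort(diags.begin(), diags.end());
  // per-diagonal seed support (before dedup), for low-support filtering
  std::vector<int> support;
  {
    std::vector<int> uniq;
    for (size_t i = 0; i < diags.size(); ++i) {
      if (uniq.empty() || diags[i] != uniq.back()) {
        uniq.push_back(diags[i]); support.push_back(1);
      } else ++support.back();
    }
    diags.swap(uniq);
  }

  // Cluster nearby diagonals into candidate windows.
  struct Hit { int start, end, dist; };
  std::vector<Hit> hits;
  size_t i0 = 0;
  std::vector<int> dist_row, start_row;
  while (i0 < diags.size()) {
    size_t i1 = i0;
    int cl_support = support[i0];
    while (i1 + 1 < diags.size() &&
           diags[i1 + 1] - diags[i1] <= max_dist &&
           diags[i1 + 1] - diags[i0] <= 2 * max_dist) {
      ++i1;
      cl_support += support[i1];
    }
    if (cl_support < min_support) { i0 = i1 + 1; continue; }
    int ws = std::max(0, diags[i0] - max_dist);
    int we = std::min(n, diags[i1] + m + max_dist);
    if (we > ws) {
      window_dp(pattern, text, ws, we, diags[i0], diags[i1], max_dist,
                dist_row, start_row);
      // local minima over end positions, one representative per basin
      int w = we - ws;
      int j = 1;
      while (j <= w) {
        if (dist_row[j] <= max_dist &&
            (j == 1 || dist_row[j] <= dist_row[j - 1]) &&
            (j == w || dist_row[j] < dist_row[j + 1])) {
          Hit h; h.start = ws + start_row[j]; h.end = ws + j; h.dist = dist_row[j];
          hits.push_back(h);
        }
        ++j;
      }
    }
    i0 = i1 + 1;
  }
  if (hits.empty()) return IntegerMatrix(0, 3);

  std::sort(hits.begin(), hits.end(),
            [](const Hit &a, const Hit &b) {
              return a.dist != b.dist ? a.dist < b.dist : a.start < b.start;
            });
  // Greedy acceptance: a hit is a distinct location if it overlaps every
  // accepted hit by at most half the pattern length.
  std::vector<Hit> kept;
  for (size_t i = 0; i < hits.size() && (int) kept.size() < max_hits; ++i) {
    bool dup = false;
    for (size_t q = 0; q < kept.size(); ++q) {
      int ov = std::min(hits[i].end, kept[q].end) -
               std::max(hits[i].start, kept[q].start);
      if (ov > m / 2) { dup = true; break; }
    }
    if (!dup) kept.push_back(hits[i]);
  }
  IntegerMatrix out((int) kept.size(), 3);
  for (size_t i = 0; i < kept.size(); ++i) {
    out(i, 0) = kept[i].start; out(i, 1) = kept[i].end; out(i, 2) = kept[i].dist;
  }
  colnames(out) = CharacterVector::create("start", "end", "dist");
  return out;
}
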