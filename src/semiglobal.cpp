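#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Semi-global (infix) edit distance: the pattern must align end-to-end,
// both ends of the text are free; unit costs for mismatch/insertion/deletion.
// Rows index the pattern, columns the text; two rolling columns suffice.
// [[Rcpp::export]]
int sg_distance_cpp(const std::string& pattern, const std::string& text) {
  const int m = pattern.size(), n = text.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int i = 0; i <= m; ++i) prev[i] = i;
  int best = m;  // pattern vs the empty substring
  for (int j = 1; j <= n; ++j) {
    cur[0] = 0;  // free start in the text
    for (int i = 1; i <= m; ++i) {
      int c = prev[i - 1] + (pattern[i - 1] != text[j - 1] ? 1 : 0);
      if (prev[i] + 1 < c) c = prev[i] + 1;
      if (cur[i - 1] + 1 < c) c = cur[i - 1] + 1;
      cur[i] = c;
    }
    if (cur[m] < best) best = cur[m];
    std::swap(prev, cur);
  }
  return best;
}

// Minimum Hamming distance of the pattern over all full-length windows of
// the text (mismatch-only mode; no indels). A text shorter than the
// pattern has no window and scores the pattern length.
// [[Rcpp::export]]
int hamming_min_cpp(const std::string& pattern, const std::string& text) {
  const int m = pattern.size(), n = text.size();
  if (n < m) return m;
  int best = m;
  for (int j = 0; j + m <= n; ++j) {
    int mm = 0;
    for (int i = 0; i < m && mm < best; ++i)
      mm += (pattern[i] != text[j + i]) ? 1 : 0;
    if (mm < best) best = mm;
  }
  return best;
}

struct Hit {
  int start, end, d, mm, ins, del;
  std::string aq, at;
};

// Scan a text for all semi-global matches of the pattern with d <= d_max.
// Every end column with D[m][j] <= d_max is traced back (diagonal moves
// preferred so alignments carry the fewest indels); alignments sharing a
// local region are then merged keeping lowest d, then leftmost start,
// then fewest indels. Coordinates are 0-based half-open on the text.
// [[Rcpp::export]]
DataFrame sg_scan_cpp(const std::string& pattern, const std::string& text,
                      int d_max) {
  const int m = pattern.size(), n = text.size();
  std::vector<Hit> hits;
  if (n > 0 && m > 0) {
    // full DP matrix, row-major: D[i * (n + 1) + j]
    std::vector<int> D((m + 1) * (n + 1));
    for (int j = 0; j <= n; ++j) D[j] = 0;
    for (int i = 1; i <= m; ++i) {
      D[i * (n + 1)] = i;
      for (int j = 1; j <= n; ++j) {
        int c = D[(i - 1) * (n + 1) + (j - 1)] +
                (pattern[i - 1] != text[j - 1] ? 1 : 0);
        int up = D[(i - 1) * (n + 1) + j] + 1;     // consume pattern only
        int left = D[i * (n + 1) + (j - 1)] + 1;   // consume text only
        if (up < c) c = up;
        if (left < c) c = left;
        D[i * (n + 1) + j] = c;
      }
    }
    for (int jend = 1; jend <= n; ++jend) {
      if (D[m * (n + 1) + jend] > d_max) continue;
      // traceback; prefer diagonal, then up, then left
      int i = m, j = jend, mm = 0, ins = 0, del = 0;
      std::string aq, at;
      while (i > 0) {
        int here = D[i * (n + 1) + j];
        if (j > 0 &&
            here == D[(i - 1) * (n + 1) + (j - 1)] +
                        (pattern[i - 1] != text[j - 1] ? 1 : 0)) {
          if (pattern[i - 1] != text[j - 1]) ++mm;
          aq += pattern[i - 1];
          at += text[j - 1];
          --i; --j;
        } else if (here == D[(i - 1) * (n + 1) + j] + 1) {
          ++ins;  // extra pattern base, gap in the text
          aq += pattern[i - 1];
          at += '-';
          --i;
        } else {
          ++del;  // text base skipped, gap in the pattern
          aq += '-';
          at += text[j - 1];
          --j;
        }
      }
      std::reverse(aq.begin(), aq.end());
      std::reverse(at.begin(), at.end());
      Hit h;
      h.start = j; h.end = jend; h.d = D[m * (n + 1) + jend];
      h.mm = mm; h.ins = ins; h.del = del; h.aq = aq; h.at = at;
      hits.push_back(h);
    }
  }
  // merge overlapping alignments of the same local site
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.start != b.start) return a.start < b.start;
    return a.end < b.end;
  });
  std::vector<Hit> kept;
  size_t k = 0;
  while (k < hits.size()) {
    size_t grp_end = k;
    int reach = hits[k].end;
    while (grp_end + 1 < hits.size() && hits[grp_end + 1].start < reach) {
      ++grp_end;
      reach = std::max(reach, hits[grp_end].end);
    }
    size_t best = k;
    for (size_t t = k + 1; t <= grp_end; ++t) {
      const Hit &a = hits[t], &b = hits[best];
      if (a.d < b.d ||
          (a.d == b.d && (a.start < b.start ||
                          (a.start == b.start &&
                           a.ins + a.del < b.ins + b.del))))
        best = t;
    }
    kept.push_back(hits[best]);
    k = grp_end + 1;
  }
  const int nh = kept.size();
  IntegerVector start(nh), end(nh), d(nh), mm(nh), ins(nh), del(nh);
  CharacterVector aq(nh), at(nh);
  for (int t = 0; t < nh; ++t) {
    start[t] = kept[t].start; end[t] = kept[t].end; d[t] = kept[t].d;
    mm[t] = kept[t].mm; ins[t] = kept[t].ins; del[t] = kept[t].del;
    aq[t] = kept[t].aq; at[t] = kept[t].at;
  }
  return DataFrame::create(
      _["start"] = start, _["end"] = end, _["d"] = d,
      _["n_mismatch"] = mm, _["n_ins"] = ins, _["n_del"] = del,
      _["aligned_query"] = aq, _["aligned_target"] = at,
      _["stringsAsFactors"] = false);
}
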