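#include <Rcpp.h>
#include <algorithm>
#include <cctype>
#include <string>
#include <vector>

using namespace Rcpp;

// Semi-global (infix) Levenshtein matching of short probes in long reads.
//
// Cost model: unit cost for substitutions and indels; 'N' (either side)
// never matches. DP is over pattern rows x subject columns with a free
// start (row 0 all zero) and free end (any column of the last row).
// Alongside the distance we propagate the 0-based start offset of the
// best path, preferring the leftmost start on ties, so every candidate
// end position yields a concrete placement (start, end, edits).

namespace {

struct Hit {
  int start;   // 1-based inclusive, on the forward subject
  int end;     // 1-based inclusive
  int edits;
  int strand;  // +1 forward, -1 reverse complement
};

inline char complement_base(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

std::string reverse_complement(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = complement_base(s[i]);
  return out;
}

inline bool bases_match(char a, char b) {
  a = std::toupper(static_cast<unsigned char>(a));
  b = std::toupper(static_cast<unsigned char>(b));
  if (a == 'N' || b == 'N') return false;
  return a == b;
}

// Reference row DP over a (short) subject slice: returns, for the path
// with minimal edits ending exactly at the slice end, the edits and the
// leftmost 0-based start offset within the slice. Used to resolve
// placements at candidate end columns.
void slice_dp(const char* subject, int n, const std::string& pattern,
              int& edits_out, int& start_out) {
  const int m = static_cast<int>(pattern.size());
  std::vector<int> prev_d(n + 1), cur_d(n + 1);
  std::vector<int> prev_s(n + 1), cur_s(n + 1);
  for (int j = 0; j <= n; ++j) { prev_d[j] = 0; prev_s[j] = j; }
  for (int i = 1; i <= m; ++i) {
    cur_d[0] = i;
    cur_s[0] = 0;
    for (int j = 1; j <= n; ++j) {
      const int sub = prev_d[j - 1] +
                      (bases_match(pattern[i - 1], subject[j - 1]) ? 0 : 1);
      const int del = prev_d[j] + 1;
      const int ins = cur_d[j - 1] + 1;
      int best = sub, start = prev_s[j - 1];
      if (del < best || (del == best && prev_s[j] < start)) {
        best = del; start = prev_s[j];
      }
      if (ins < best || (ins == best && cur_s[j - 1] < start)) {
        best = ins; start = cur_s[j - 1];
      }
      cur_d[j] = best;
      cur_s[j] = start;
    }
    std::swap(prev_d, cur_d);
    std::swap(prev_s, cur_s);
  }
  edits_out = prev_d[n];
  start_out = prev_s[n];
}

// Myers (1999) bit-parallel approximate search: minimal edit distance of
// the pattern over all substrings ending at each column, for m <= 64.
// Candidate end columns (score <= max_edits) are resolved to concrete
// placements with slice_dp over the preceding m + max_edits characters.
void scan_one_strand(const std::string& subject, const std::string& pattern,
                     int max_edits, int strand, std::vector<Hit>& hits) {
  const int n = static_cast<int>(subject.size());
  const int m = static_cast<int>(pattern.size());
  if (m == 0 || m > n || m > 64) {
    if (m > 64 && m <= n) {  // rare: fall back to the full row DP
      int e, s;
      for (int j = m - max_edits; j <= n; ++j) {
        const int w = std::min(j, m + max_edits);
        slice_dp(subject.data() + (j - w), w, pattern, e, s);
        if (e <= max_edits && s < w) {
          Hit h; h.edits = e; h.strand = strand;
          const int st = j - w + s;  // 0-based
          if (strand > 0) { h.start = st + 1; h.end = j; }
          else { h.start = n - j + 1; h.end = n - st; }
          hits.push_back(h);
        }
      }
    }
    return;
  }

  uint64_t peq[256] = {0};
  for (int i = 0; i < m; ++i) {
    const char c = std::toupper(static_cast<unsigned char>(pattern[i]));
    if (c == 'A' || c == 'C' || c == 'G' || c == 'T') {
      peq[static_cast<unsigned char>(c)] |= (uint64_t{1} << i);
      peq[static_cast<unsigned char>(std::tolower(c))] |=
          (uint64_t{1} << i);
    }
  }
  const uint64_t high = uint64_t{1} << (m - 1);
  uint64_t pv = ~uint64_t{0}, mv = 0;
  int score = m;
  const char* txt = subject.data();

  for (int j = 1; j <= n; ++j) {
    const uint64_t eq = peq[static_cast<unsigned char>(txt[j - 1])];
    const uint64_t xv = eq | mv;
    const uint64_t xh = (((eq & pv) + pv) ^ pv) | eq;
    uint64_t ph = mv | ~(xh | pv);
    uint64_t mh = pv & xh;
    if (ph & high) ++score;
    else if (mh & high) --score;
    ph <<= 1;
    mh <<= 1;
    pv = mh | ~(xv | ph);
    mv = ph & xv;

    if (score <= max_edits) {
      const int w = std::min(j, m + max_edits);
      int e, s;
      slice_dp(subject.data() + (j - w), w, pattern, e, s);
      if (e <= max_edits && s < w) {
        Hit h; h.edits = e; h.strand = strand;
        const int st = j - w + s;  // 0-based start on this strand
        if (strand > 0) { h.start = st + 1; h.end = j; }
        else { h.start = n - j + 1; h.end = n - st; }
        hits.push_back(h);
      }
    }
  }
}

// Among overlapping candidate placements keep the lowest-edit one;
// ties broken by leftmost start, then shortest span. Output ascending
// by start.
std::vector<Hit> select_nonoverlapping(std::vector<Hit> cand) {
  std::sort(cand.begin(), cand.end(), [](const Hit& a, const Hit& b) {
    if (a.edits != b.edits) return a.edits < b.edits;
    if (a.start != b.start) return a.start < b.start;
    const int wa = a.end - a.start, wb = b.end - b.start;
    if (wa != wb) return wa < wb;
    return a.strand > b.strand;
  });
  std::vector<Hit> kept;
  for (const Hit& h : cand) {
    bool clash = false;
    for (const Hit& k : kept) {
      if (h.start <= k.end && k.start <= h.end) { clash = true; break; }
    }
    if (!clash) kept.push_back(h);
  }
  std::sort(kept.begin(), kept.end(), [](const Hit& a, const Hit& b) {
    return a.start < b.start;
  });
  return kept;
}

void scan_pair(const std::string& subject, const std::string& subject_rc,
               const std::string& pattern, int max_edits, bool both_strands,
               std::vector<Hit>& out) {
  std::vector<Hit> cand;
  scan_one_strand(subject, pattern, max_edits, +1, cand);
  if (both_strands)
    scan_one_strand(subject_rc, pattern, max_edits, -1, cand);
  std::vector<Hit> kept = select_nonoverlapping(std::move(cand));
  out.insert(out.end(), kept.begin(), kept.end());
}

}  // namespace

// Returns a plain list of parallel integer vectors (strand coded +1/-1);
// the R wrapper assembles the data.frame, which is much cheaper than
// DataFrame::create for the many small per-read calls.
// [[Rcpp::export(name = ".probe_scan_cpp")]]
List probe_scan_cpp(CharacterVector subjects, CharacterVector patterns,
                    int max_edits, bool both_strands = true) {
  std::vector<int> subj_idx, pat_idx, starts, ends, edits, strands;
  std::vector<std::string> pats(patterns.size());
  for (R_xlen_t pi = 0; pi < patterns.size(); ++pi)
    pats[pi] = as<std::string>(patterns[pi]);

  for (R_xlen_t si = 0; si < subjects.size(); ++si) {
    const std::string subject = as<std::string>(subjects[si]);
    const std::string subject_rc =
        both_strands ? reverse_complement(subject) : std::string();
    for (size_t pi = 0; pi < pats.size(); ++pi) {
      std::vector<Hit> hits;
      scan_pair(subject, subject_rc, pats[pi], max_edits, both_strands,
                hits);
      for (const Hit& h : hits) {
        subj_idx.push_back(static_cast<int>(si) + 1);
        pat_idx.push_back(static_cast<int>(pi) + 1);
        starts.push_back(h.start);
        ends.push_back(h.end);
        edits.push_back(h.edits);
        strands.push_back(h.strand);
      }
    }
  }

  return List::create(
      _["subject"] = wrap(subj_idx), _["pattern"] = wrap(pat_idx),
      _["start"] = wrap(starts), _["end"] = wrap(ends),
      _["strand"] = wrap(strands), _["edits"] = wrap(edits));
}

// Vectorised reverse complement over {A,C,G,T,N}.
// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = reverse_complement(as<std::string>(x[i]));
  }
  return out;
}

// Plain Levenshtein distance between two short strings ('N' never
// matches), used for probe-set QC and barcode calling.
// [[Rcpp::export(name = ".edit_distance_cpp")]]
int edit_distance_cpp(std::string a, std::string b) {
  const int n = static_cast<int>(a.size());
  const int m = static_cast<int>(b.size());
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      cur[j] = std::min({prev[j - 1] + (bases_match(a[i - 1], b[j - 1]) ? 0 : 1),
                         prev[j] + 1, cur[j - 1] + 1});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
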