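#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Base-match test: 'N' matches nothing (scored as mismatch everywhere).
static inline bool base_eq(char a, char b) {
  return a == b && a != 'N';
}

struct SwResult {
  int score;
  int ref_start;   // 0-based
  int read_start;  // 0-based
  std::string cigar;
  int edits;       // mismatches + gap bases inside the local alignment
  bool ok;
};

// Smith-Waterman local alignment with linear gap penalty and full traceback.
// Deterministic tie-breaking: the best cell is the highest score with the
// smallest reference end, then smallest read end; traceback prefers
// diagonal over up (read-consuming gap) over left (ref-consuming gap).
static SwResult sw_one(const std::string& read, const std::string& ref,
                       int match, int mismatch, int gap) {
  const int m = (int)read.size(), n = (int)ref.size();
  SwResult res; res.ok = false; res.score = 0;
  if (m == 0 || n == 0) return res;

  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  auto at = [&](int i, int j) -> int& { return H[(size_t)i * (n + 1) + j]; };

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int sub = base_eq(read[i - 1], ref[j - 1]) ? match : mismatch;
      int d = at(i - 1, j - 1) + sub;
      int u = at(i - 1, j) + gap;   // consume read base (insertion vs ref)
      int l = at(i, j - 1) + gap;   // consume ref base (deletion vs read)
      int h = d;
      if (u > h) h = u;
      if (l > h) h = l;
      if (h < 0) h = 0;
      at(i, j) = h;
      if (h > best || (h == best && (j < bj || (j == bj && i < bi)))) {
        if (h > 0) { best = h; bi = i; bj = j; }
      }
    }
  }
  if (best <= 0) return res;

  // Traceback from (bi, bj) until a zero cell.
  int i = bi, j = bj, edits = 0;
  std::vector<std::pair<char, int> > ops;  // reversed CIGAR runs
  auto push_op = [&](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  while (i > 0 && j > 0 && at(i, j) > 0) {
    int h = at(i, j);
    int sub = base_eq(read[i - 1], ref[j - 1]) ? match : mismatch;
    if (h == at(i - 1, j - 1) + sub) {
      push_op('M');
      if (!base_eq(read[i - 1], ref[j - 1])) edits++;
      --i; --j;
    } else if (h == at(i - 1, j) + gap) {
      push_op('I'); edits++; --i;
    } else {
      push_op('D'); edits++; --j;
    }
  }
  std::string cig;
  for (int k = (int)ops.size() - 1; k >= 0; --k)
    cig += std::to_string(ops[k].second) + ops[k].first;

  res.score = best;
  res.read_start = i;
  res.ref_start = j;
  res.cigar = cig;
  res.edits = edits;
  res.ok = true;
  return res;
}

//' @noRd
// [[Rcpp::export(name = ".sw_pair")]]
List sw_pair(std::string read, std::string ref,
             int match, int mismatch, int gap) {
  SwResult r = sw_one(read, ref, match, mismatch, gap);
  return List::create(_["score"] = r.ok ? r.score : 0,
                      _["ref_start"] = r.ok ? r.ref_start : -1,
                      _["read_start"] = r.ok ? r.read_start : -1,
                      _["cigar"] = r.cigar,
                      _["edits"] = r.ok ? r.edits : NA_INTEGER,
                      _["ok"] = r.ok);
}

// Best alignment of one read against a vector of candidate references.
// Ties: higher score, then fewer edits, then earlier candidate.
// [[Rcpp::export(name = ".sw_best")]]
List sw_best(std::string read, CharacterVector refs,
             int match, int mismatch, int gap) {
  int best_idx = -1;
  SwResult best; best.ok = false; best.score = -1; best.edits = 0;
  for (int c = 0; c < refs.size(); ++c) {
    SwResult r = sw_one(read, as<std::string>(refs[c]), match, mismatch, gap);
    if (!r.ok) continue;
    if (r.score > best.score ||
        (r.score == best.score && r.edits < best.edits)) {
      best = r; best_idx = c;
    }
  }
  if (best_idx < 0)
    return List::create(_["idx"] = NA_INTEGER);
  return List::create(_["idx"] = best_idx + 1,
                      _["score"] = best.score,
                      _["ref_start"] = best.ref_start,
                      _["read_start"] = best.read_start,
                      _["cigar"] = best.cigar,
                      _["edits"] = best.edits);
}

// 3' adapter search: best semi-global match of an adapter *prefix* against a
// read *suffix*, anchored at the read's 3' end, free start inside the read.
// One O(K x n) DP per read (K = adapter length): D[i][j] = minimum edit
// distance of adapter[0..i) against read[s..j) over all starts s, with the
// leftmost start recorded on ties. A matched prefix length L qualifies when
// edits <= floor(max_error_rate * L) and L >= min_overlap; the longest
// qualifying L wins (its recorded edits/start are minimal/leftmost for
// that L).
// Returns, per read: start (0-based removal point, -1 = no match),
// matched adapter length, edits.
// [[Rcpp::export(name = ".adapter_match")]]
DataFrame adapter_match(CharacterVector reads, std::string adapter,
                        double max_error_rate, int min_overlap) {
  const int K = (int)adapter.size();
  const int nr = reads.size();
  IntegerVector out_start(nr), out_len(nr), out_edits(nr);

  std::vector<int> prevD(1), prevO(1), curD(1), curO(1);
  for (int r = 0; r < nr; ++r) {
    std::string read = as<std::string>(reads[r]);
    const int n = (int)read.size();
    prevD.assign(n + 1, 0);
    prevO.assign(n + 1, 0);
    for (int j = 0; j <= n; ++j) prevO[j] = j;  // free start: origin = j
    curD.assign(n + 1, 0); curO.assign(n + 1, 0);

    int best_L = -1, best_edits = 0, best_start = -1;
    for (int i = 1; i <= K; ++i) {
      curD[0] = i;      // adapter prefix unmatched before read start
      curO[0] = 0;
      for (int j = 1; j <= n; ++j) {
        int cd = prevD[j - 1] + (base_eq(adapter[i - 1], read[j - 1]) ? 0 : 1);
        int co = prevO[j - 1];
        int ud = prevD[j] + 1;                 // skip adapter base
        if (ud < cd || (ud == cd && prevO[j] < co)) { cd = ud; co = prevO[j]; }
        int ld = curD[j - 1] + 1;              // skip read base
        if (ld < cd || (ld == cd && curO[j - 1] < co)) { cd = ld; co = curO[j - 1]; }
        curD[j] = cd; curO[j] = co;
      }
      if (i >= min_overlap) {
        int edits = curD[n], start = curO[n];
        if (start < n && edits <= (int)std::floor(max_error_rate * i)) {
          best_L = i; best_edits = edits; best_start = start;
        }
      }
      prevD.swap(curD); prevO.swap(curO);
    }
    out_start[r] = best_L > 0 ? best_start : -1;
    out_len[r] = best_L > 0 ? best_L : 0;
    out_edits[r] = best_L > 0 ? best_edits : NA_INTEGER;
  }
  return DataFrame::create(_["start"] = out_start,
                           _["length"] = out_len,
                           _["edits"] = out_edits,
                           _["stringsAsFactors"] = false);
}
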