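#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match = 1, mismatch = 0,
// linear gap = -1. Among score-optimal alignments the one with the most
// matched columns (then most aligned columns) is taken, so the reported
// identity is deterministic.
struct Cell {
  int score;
  int match;   // identical aligned residues
  int aligned; // non-gap columns (matches + mismatches)
};

static inline bool better(const Cell &a, const Cell &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.match != b.match) return a.match > b.match;
  return a.aligned > b.aligned;
}

static Cell nw_core(const std::string &a, const std::string &b) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<Cell> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = {-j, 0, 0};
  for (int i = 1; i <= m; ++i) {
    cur[0] = {-i, 0, 0};
    const char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const bool eq = (ai == b[j - 1]);
      Cell diag = {prev[j - 1].score + (eq ? 1 : 0),
                   prev[j - 1].match + (eq ? 1 : 0),
                   prev[j - 1].aligned + 1};
      Cell up   = {prev[j].score - 1, prev[j].match, prev[j].aligned};
      Cell left = {cur[j - 1].score - 1, cur[j - 1].match, cur[j - 1].aligned};
      Cell best = diag;
      if (better(up, best)) best = up;
      if (better(left, best)) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
IntegerVector nw_counts(std::string a, std::string b) {
  Cell c = nw_core(a, b);
  return IntegerVector::create(_["score"] = c.score, _["match"] = c.match,
                               _["aligned"] = c.aligned);
}

// Align one query against many subjects; returns a 3-column matrix
// (score, match, aligned), one row per subject.
// [[Rcpp::export]]
IntegerMatrix nw_counts_many(std::string query, CharacterVector subjects) {
  const int n = subjects.size();
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    Cell c = nw_core(query, std::string(subjects[i]));
    out(i, 0) = c.score;
    out(i, 1) = c.match;
    out(i, 2) = c.aligned;
  }
  colnames(out) = CharacterVector::create("score", "match", "aligned");
  return out;
}
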