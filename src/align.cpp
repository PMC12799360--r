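#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh), one query vs a
// batch of subjects. A gap of length L costs `gap_open + L * gap_extend`
// (BLAST convention; 11 + L with the defaults used by the package).
//
// Two passes per subject: a score-only pass with rolling rows, then, only
// when the score reaches `score_min` (> 0), a full DP with deterministic
// traceback (diagonal preferred over subject-gap over query-gap) to count
// matches, alignment columns and the aligned query span. Subjects below
// `score_min` report their score with zeroed alignment statistics; callers
// use a `score_min` no larger than the score their downstream filters
// could accept, so nothing reportable is lost.

static const int NEG = -1000000000;

static int sw_score_only(const int* q, int m, const int* s, int n,
                         const int* sub, int na, int go, int ge,
                         std::vector<int>& h_row, std::vector<int>& e_row) {
  std::fill(h_row.begin(), h_row.begin() + n + 1, 0);
  std::fill(e_row.begin(), e_row.begin() + n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int h_diag = 0;   // H[i-1][j-1]
    int h_left = 0;   // H[i][j-1]
    int e_left = NEG; // E[i][j-1]
    const int* srow = sub + q[i - 1] * na;
    for (int j = 1; j <= n; ++j) {
      int e = std::max(h_left - go, e_left - ge);
      // F needs per-column state: reuse e_row slot trick is unsafe; use
      // h_row[j] (still holding H[i-1][j]) before overwrite.
      int f_here = std::max(h_row[j] - go, e_row[j] - ge); // e_row[j] = F[i-1][j]
      int d = h_diag + srow[s[j - 1]];
      int h = std::max(0, std::max(d, std::max(e, f_here)));
      h_diag = h_row[j];
      h_row[j] = h;
      e_row[j] = f_here;  // becomes F[i][j] for the next row
      h_left = h;
      e_left = e;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_batch")]]
NumericMatrix sw_batch(IntegerVector query, List subjects,
                       IntegerMatrix submat, int gap_open, int gap_extend,
                       int score_min = 1) {
  const int m = query.size();
  const int ns = subjects.size();
  const int na = submat.nrow();
  NumericMatrix out(ns, 5);
  colnames(out) = CharacterVector::create("score", "matches", "columns",
                                          "qstart", "qend");
  const int go = gap_open + gap_extend;  // cost of a length-1 gap
  const int ge = gap_extend;
  if (score_min < 1) score_min = 1;

  // flatten the substitution matrix row-major: sub[a * na + b]
  std::vector<int> sub(na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b)
      sub[a * na + b] = submat(a, b);
  const int* q = INTEGER(query);

  size_t max_n = 0;
  for (int s = 0; s < ns; ++s)
    max_n = std::max(max_n, (size_t)Rf_length(subjects[s]));
  std::vector<int> h_row(max_n + 1), e_row(max_n + 1);
  std::vector<int> H, E, F;  // full matrices, reused across subjects

  for (int si = 0; si < ns; ++si) {
    IntegerVector subj = subjects[si];
    const int n = subj.size();
    const int* sv = INTEGER(subj);

    int best = sw_score_only(q, m, sv, n, sub.data(), na, go, ge, h_row, e_row);
    out(si, 0) = best;
    if (best < score_min) continue;

    const size_t sz = (size_t)(m + 1) * (n + 1);
    if (H.size() < sz) { H.resize(sz); E.resize(sz); F.resize(sz); }
    auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
    for (int j = 0; j <= n; ++j) { H[at(0, j)] = 0; E[at(0, j)] = NEG; F[at(0, j)] = NEG; }
    int bi = 0, bj = 0; best = 0;
    for (int i = 1; i <= m; ++i) {
      H[at(i, 0)] = 0; E[at(i, 0)] = NEG; F[at(i, 0)] = NEG;
      const int* srow = sub.data() + q[i - 1] * na;
      for (int j = 1; j <= n; ++j) {
        int e = std::max(H[at(i, j - 1)] - go, E[at(i, j - 1)] - ge);
        int f = std::max(H[at(i - 1, j)] - go, F[at(i - 1, j)] - ge);
        int d = H[at(i - 1, j - 1)] + srow[sv[j - 1]];
        int h = std::max(0, std::max(d, std::max(e, f)));
        E[at(i, j)] = e; F[at(i, j)] = f; H[at(i, j)] = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }

    int matches = 0, columns = 0, qstart = 0, qend = bi;
    int i = bi, j = bj;
    char state = 'H';
    while (i > 0 && j > 0) {
      if (state == 'H') {
        if (H[at(i, j)] == 0) break;
        int sc = sub[q[i - 1] * na + sv[j - 1]];
        if (H[at(i, j)] == H[at(i - 1, j - 1)] + sc) {
          ++columns;
          if (q[i - 1] == sv[j - 1]) ++matches;
          qstart = i;
          --i; --j;
        } else if (H[at(i, j)] == E[at(i, j)]) {
          state = 'E';
        } else {
          state = 'F';
        }
      } else if (state == 'E') {  // gap column consuming a subject residue
        ++columns;
        if (E[at(i, j)] == H[at(i, j - 1)] - go) { --j; state = 'H'; }
        else --j;
      } else {                    // gap column consuming a query residue
        ++columns;
        qstart = i;
        if (F[at(i, j)] == H[at(i - 1, j)] - go) { --i; state = 'H'; }
        else --i;
      }
    }
    out(si, 0) = best;
    out(si, 1) = matches;
    out(si, 2) = columns;
    out(si, 3) = qstart;
    out(si, 4) = qend;
  }
  return out;
}
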