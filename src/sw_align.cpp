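#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// Convention: opening a gap costs `gap_open` for its first column and
// `gap_extend` for each further column, i.e. a k-column gap scores
// gap_open + (k-1) * gap_extend.
//
// Deterministic optimum and traceback:
//  - the best cell is the first maximal H encountered scanning rows then
//    columns;
//  - at each H cell ties are resolved diagonal, then up (gap in the
//    subject, consuming the query), then left;
//  - inside a gap state, closing the gap (returning to H) is preferred
//    over extending it.
//
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  double match = 2.0, double mismatch = -3.0,
                  double gap_open = -5.0, double gap_extend = -2.0) {
  const int n = (int) query.size();
  const int m = (int) subject.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");

  const double NEG = -1e18;
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG); // gap in query (consumes subject)
  std::vector<double> F((n + 1) * (m + 1), NEG); // gap in subject (consumes query)
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H[idx(i, j - 1)] + gap_open,
                          E[idx(i, j - 1)] + gap_extend);
      double f = std::max(H[idx(i - 1, j)] + gap_open,
                          F[idx(i - 1, j)] + gap_extend);
      char a = query[i - 1], b = subject[j - 1];
      // N never counts as a match
      double s = (a == b && a != 'N') ? match : mismatch;
      double h = H[idx(i - 1, j - 1)] + s;
      double val = h;
      if (f > val) val = f;
      if (e > val) val = e;
      if (val < 0.0) val = 0.0;
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = val;
      if (val > best) { best = val; bi = i; bj = j; }
    }
  }

  int hit_len = 0, matches = 0;
  int qs = 0, qe = 0, ss = 0, se = 0;
  if (best > 0.0) {
    int i = bi, j = bj;
    qe = bi; se = bj;
    int state = 0; // 0 = H, 1 = F (up), 2 = E (left)
    while (true) {
      if (state == 0) {
        double h = H[idx(i, j)];
        if (h <= 0.0 || i == 0 || j == 0) break;
        char a = query[i - 1], b = subject[j - 1];
        double s = (a == b && a != 'N') ? match : mismatch;
        if (H[idx(i - 1, j - 1)] + s == h) {
          ++hit_len;
          if (a == b && a != 'N') ++matches;
          --i; --j;
        } else if (F[idx(i, j)] == h) {
          state = 1;
        } else if (E[idx(i, j)] == h) {
          state = 2;
        } else {
          stop("traceback inconsistency"); // defensive; unreachable
        }
      } else if (state == 1) {
        ++hit_len; // query letter vs gap
        if (H[idx(i - 1, j)] + gap_open == F[idx(i, j)]) {
          --i; state = 0;
        } else {
          --i; state = 1;
        }
      } else {
        ++hit_len; // gap vs subject letter
        if (H[idx(i, j - 1)] + gap_open == E[idx(i, j)]) {
          --j; state = 0;
        } else {
          --j; state = 2;
        }
      }
    }
    qs = i + 1; ss = j + 1;
  }

  return List::create(_["score"] = best,
                      _["hit_len"] = hit_len,
                      _["matches"] = matches,
                      _["query_start"] = qs, _["query_end"] = qe,
                      _["subject_start"] = ss, _["subject_end"] = se);
}
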