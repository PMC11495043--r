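#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman with deterministic traceback.
//
// a, b: 1-based indices into the substitution matrix `sub`.
// Gap model: a gap of length k costs gap_open + k * gap_extend (both
// penalties are non-positive). Traceback ties are broken preferring the
// diagonal, then the vertical (gap in b), then the horizontal move; the
// optimal end cell is the first (lowest query index, then subject index)
// cell attaining the maximum score.
//
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e300;
  // DP matrices, (n+1) x (m+1), row-major vectors.
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      double prev = std::max(std::max(M[at(i - 1, j - 1)],
                                      X[at(i - 1, j - 1)]),
                             std::max(Y[at(i - 1, j - 1)], 0.0));
      M[at(i, j)] = prev + s;
      X[at(i, j)] = std::max(M[at(i - 1, j)] + gap_open + gap_extend,
                             X[at(i - 1, j)] + gap_extend);
      Y[at(i, j)] = std::max(M[at(i, j - 1)] + gap_open + gap_extend,
                             Y[at(i, j - 1)] + gap_extend);
      if (M[at(i, j)] > best) {
        best = M[at(i, j)];
        bi = i; bj = j;
      }
    }
  }

  int qstart = NA_INTEGER, qend = NA_INTEGER;
  int sstart = NA_INTEGER, send = NA_INTEGER;
  int matches = 0, mismatches = 0, gap_opens = 0, aln_len = 0;
  if (best > 0.0) {
    qend = bi; send = bj;
    int i = bi, j = bj;
    char state = 'M';
    while (i > 0 && j > 0) {
      if (state == 'M') {
        double here = M[at(i, j)];
        double s = sub(a[i - 1] - 1, b[j - 1] - 1);
        ++aln_len;
        if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
        qstart = i; sstart = j;
        double need = here - s;
        if (need == 0.0) break; // local start
        // tie order: diagonal M, vertical X, horizontal Y
        if (i > 1 && j > 1 && M[at(i - 1, j - 1)] == need) {
          --i; --j; state = 'M';
        } else if (X[at(i - 1, j - 1)] == need) {
          --i; --j; state = 'X';
        } else if (Y[at(i - 1, j - 1)] == need) {
          --i; --j; state = 'Y';
        } else {
          break; // local start (need == 0)
        }
      } else if (state == 'X') {
        double here = X[at(i, j)];
        ++aln_len;
        if (M[at(i - 1, j)] + gap_open + gap_extend == here) {
          ++gap_opens;
          --i; state = 'M';
        } else {
          --i; state = 'X';
        }
      } else { // Y
        double here = Y[at(i, j)];
        ++aln_len;
        if (M[at(i, j - 1)] + gap_open + gap_extend == here) {
          ++gap_opens;
          --j; state = 'M';
        } else {
          --j; state = 'Y';
        }
      }
    }
  }

  return List::create(
    _["score"] = best,
    _["qstart"] = qstart, _["qend"] = qend,
    _["sstart"] = sstart, _["send"] = send,
    _["alignment_length"] = aln_len,
    _["matches"] = matches,
    _["mismatches"] = mismatches,
    _["gap_opens"] = gap_opens);
}
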