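#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Gap of length L costs open + L*ext,
// matching the Biostrings gapOpening/gapExtension convention. Characters
// absent from the substitution matrix score 'unknown_score'; '#' is a hard
// mask that no alignment may touch.
//
// Returns best local alignment with 1-based coordinates and column stats.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".sw_local")]]
List sw_local(std::string query, std::string subject,
              NumericMatrix submat, double gap_open, double gap_ext,
              double unknown_score = -4.0) {
  const int m = query.size(), n = subject.size();

  // 128x128 lookup from the matrix dimnames
  std::vector<double> lut(128 * 128, unknown_score);
  CharacterVector rn = rownames(submat), cn = colnames(submat);
  std::vector<int> ridx(128, -1), cidx(128, -1);
  for (int i = 0; i < rn.size(); ++i) ridx[(unsigned char)CHAR(STRING_ELT(rn, i))[0]] = i;
  for (int j = 0; j < cn.size(); ++j) cidx[(unsigned char)CHAR(STRING_ELT(cn, j))[0]] = j;
  for (int a = 0; a < 128; ++a)
    for (int b = 0; b < 128; ++b) {
      if (a == '#' || b == '#') { lut[a * 128 + b] = NEG_INF; continue; }
      if (ridx[a] >= 0 && cidx[b] >= 0)
        lut[a * 128 + b] = submat(ridx[a], cidx[b]);
    }

  const double og = -(gap_open + gap_ext), eg = -gap_ext;
  std::vector<double> M((m + 1) * (n + 1), 0.0), X((m + 1) * (n + 1), NEG_INF),
      Y((m + 1) * (n + 1), NEG_INF);
  // traceback: 0 stop, 1 diag(M), 2 up(X: gap in subject), 3 left(Y: gap in query)
  std::vector<unsigned char> tbM((m + 1) * (n + 1), 0), tbX((m + 1) * (n + 1), 0),
      tbY((m + 1) * (n + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const unsigned char qa = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int ij = i * (n + 1) + j;
      const int up = (i - 1) * (n + 1) + j, lf = ij - 1, dg = up - 1;
      // X: gap in subject (consume query)
      double xo = M[up] + og, xe = X[up] + eg;
      X[ij] = xo >= xe ? xo : xe; tbX[ij] = xo >= xe ? 1 : 2;
      // Y: gap in query (consume subject)
      double yo = M[lf] + og, ye = Y[lf] + eg;
      Y[ij] = yo >= ye ? yo : ye; tbY[ij] = yo >= ye ? 1 : 3;
      // M
      double s = lut[qa * 128 + (unsigned char)subject[j - 1]];
      double md = (M[dg] > X[dg] ? (M[dg] > Y[dg] ? M[dg] : Y[dg])
                                 : (X[dg] > Y[dg] ? X[dg] : Y[dg]));
      unsigned char from = 1;
      if (X[dg] > M[dg] && X[dg] >= Y[dg]) from = 2;
      else if (Y[dg] > M[dg] && Y[dg] > X[dg]) from = 3;
      double v = md + s;
      if (v < 0.0 || s <= NEG_INF / 2) { v = s <= NEG_INF / 2 ? NEG_INF : 0.0; from = 0; }
      if (v == 0.0) from = 0;
      M[ij] = v; tbM[ij] = from;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }

  int qend = bi, send = bj, qstart = bi, sstart = bj;
  int len = 0, matches = 0, mism = 0, gapopen = 0, gaps = 0;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0; // 0 = M
    char lastgap = 0;
    while (i > 0 && j > 0) {
      const int ij = i * (n + 1) + j;
      if (state == 0) {
        unsigned char from = tbM[ij];
        if (M[ij] == 0.0 && from == 0 && !(i == bi && j == bj)) break;
        // consume the diagonal step
        ++len;
        if (query[i - 1] == subject[j - 1]) ++matches; else ++mism;
        qstart = i; sstart = j;
        --i; --j;
        if (from == 0) break;
        state = (from == 1) ? 0 : (from == 2 ? 1 : 2);
        lastgap = 0;
      } else if (state == 1) { // X: gap in subject, consume query
        ++len; ++gaps; if (lastgap != 'X') { ++gapopen; lastgap = 'X'; }
        qstart = i;
        unsigned char from = tbX[i * (n + 1) + j];
        --i;
        state = (from == 1) ? 0 : 1;
        if (state == 0) lastgap = 0;
      } else { // Y: gap in query, consume subject
        ++len; ++gaps; if (lastgap != 'Y') { ++gapopen; lastgap = 'Y'; }
        sstart = j;
        unsigned char from = tbY[i * (n + 1) + j];
        --j;
        state = (from == 1) ? 0 : 2;
        if (state == 0) lastgap = 0;
      }
    }
  }

  return List::create(_["score"] = best, _["qstart"] = qstart, _["qend"] = qend,
                      _["sstart"] = sstart, _["send"] = send, _["length"] = len,
                      _["matches"] = matches, _["mismatches"] = mism,
                      _["gapopen"] = gapopen, _["gaps"] = gaps);
}
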