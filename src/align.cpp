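#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment with affine gap runs.
//
// States: M = x_i aligned to y_j, X = x_i aligned to a gap (gap in query row),
// Y = gap in reference row aligned to y_j. A gap run of length L costs
// gap_open + (L - 1) * gap_extend. 'X' residues never score as a match.
//
// Traceback tie-breaking prefers gap states over match states (and gap-run
// extension over re-opening), which places co-optimal gap runs at the highest
// (most C-terminal) reference coordinates. End gaps are charged normally.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string ref, std::string query,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = ref.size(), m = query.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  const size_t W = m + 1;
  std::vector<double> Mv((n + 1) * W, NEG_INF), Xv((n + 1) * W, NEG_INF),
      Yv((n + 1) * W, NEG_INF);
  #define M(i, j) Mv[(size_t)(i) * W + (j)]
  #define X(i, j) Xv[(size_t)(i) * W + (j)]
  #define Y(i, j) Yv[(size_t)(i) * W + (j)]
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y(0, j) = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    const char ci = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char cj = query[j - 1];
      double s = (ci == cj && ci != 'X') ? match : mismatch;
      double best = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > best) best = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best) best = Y(i - 1, j - 1);
      if (best > NEG_INF) M(i, j) = best + s;

      double xo = M(i - 1, j) > Y(i - 1, j) ? M(i - 1, j) : Y(i - 1, j);
      double xv = (xo > NEG_INF) ? xo + gap_open : NEG_INF;
      double xe = (X(i - 1, j) > NEG_INF) ? X(i - 1, j) + gap_extend : NEG_INF;
      X(i, j) = xv > xe ? xv : xe;

      double yo = M(i, j - 1) > X(i, j - 1) ? M(i, j - 1) : X(i, j - 1);
      double yv = (yo > NEG_INF) ? yo + gap_open : NEG_INF;
      double ye = (Y(i, j - 1) > NEG_INF) ? Y(i, j - 1) + gap_extend : NEG_INF;
      Y(i, j) = yv > ye ? yv : ye;
    }
  }
  // Y(i,0)/X(0,j) stay -inf (a leading gap run in one row excludes the other).

  // Final state: prefer X, then Y, then M on ties (gap runs pushed C-terminal).
  double score = X(n, m);
  int state = 1; // 0 = M, 1 = X, 2 = Y
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }
  if (M(n, m) > score) { score = M(n, m); state = 0; }
  // re-apply preference on exact ties
  if (X(n, m) == score) state = 1;
  else if (Y(n, m) == score) state = 2;

  std::string ar, aq;
  ar.reserve(n + m); aq.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      // match/mismatch column; predecessor preference X > Y > M
      const char ci = ref[i - 1], cj = query[j - 1];
      double s = (ci == cj && ci != 'X') ? match : mismatch;
      double need = M(i, j) - s;
      ar.push_back(ci); aq.push_back(cj);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (X(i, j) == need) state = 1;
      else if (Y(i, j) == need) state = 2;
      else state = 0;
    } else if (state == 1) {
      // gap in query row; predecessor preference: extend (X) > M > Y
      double v = X(i, j);
      ar.push_back(ref[i - 1]); aq.push_back('-');
      --i;
      if (i == 0 && j == 0) break;
      if (X(i, j) != NEG_INF && X(i, j) + gap_extend == v) state = 1;
      else if (M(i, j) != NEG_INF && M(i, j) + gap_open == v) state = 0;
      else state = 2;
    } else {
      // gap in reference row; predecessor preference: extend (Y) > M > X
      double v = Y(i, j);
      ar.push_back('-'); aq.push_back(query[j - 1]);
      --j;
      if (i == 0 && j == 0) break;
      if (Y(i, j) != NEG_INF && Y(i, j) + gap_extend == v) state = 2;
      else if (M(i, j) != NEG_INF && M(i, j) + gap_open == v) state = 0;
      else state = 1;
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(aq.begin(), aq.end());

  #undef M
  #undef X
  #undef Y
  return List::create(_["aligned_ref"] = ar,
                      _["aligned_query"] = aq,
                      _["score"] = score);
}
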