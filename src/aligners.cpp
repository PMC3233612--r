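#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise aligners over integer-encoded sequences.
// Sequences arrive as 1-based indices into `submat` (a square scoring
// matrix); gap of length L costs gap_open + L * gap_extend (BLAST
// convention, so the first gap residue costs gap_open + gap_extend).
//
// The global aligner optimises (score, identities) lexicographically:
// among all score-optimal alignments it reports the maximum number of
// identical aligned residue pairs. Additivity of both components makes
// the lexicographic objective decomposable, so a standard Gotoh DP over
// (score, id) pairs is exact and independent of traceback order.

static const double NEG_INF = -1e300;

struct Cell {
  double s;
  int id;
};

static inline void take_best(Cell &dst, double s, int id) {
  if (s > dst.s || (s == dst.s && id > dst.id)) {
    dst.s = s;
    dst.id = id;
  }
}

// [[Rcpp::export]]
List nw_align_c(IntegerVector a, IntegerVector b, NumericMatrix submat,
                double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double open1 = gap_open + gap_extend; // cost of a length-1 gap

  std::vector<Cell> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<Cell> Mp(m + 1), Xp(m + 1), Yp(m + 1);

  Mp[0].s = 0.0; Mp[0].id = 0;
  Xp[0].s = NEG_INF; Xp[0].id = 0;
  Yp[0].s = NEG_INF; Yp[0].id = 0;
  for (int j = 1; j <= m; ++j) {
    Yp[j].s = -open1 - (j - 1) * gap_extend; Yp[j].id = 0; // gap in a
    Mp[j].s = NEG_INF; Mp[j].id = 0;
    Xp[j].s = NEG_INF; Xp[j].id = 0;
  }

  for (int i = 1; i <= n; ++i) {
    M[0].s = NEG_INF; M[0].id = 0;
    Y[0].s = NEG_INF; Y[0].id = 0;
    X[0].s = -open1 - (i - 1) * gap_extend; X[0].id = 0; // gap in b
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1] - 1;
      const double sub = submat(ai, bj);
      const int hit = (a[i - 1] == b[j - 1]) ? 1 : 0;
      // match/mismatch state from any state at (i-1, j-1)
      Cell best = {NEG_INF, 0};
      take_best(best, Mp[j - 1].s, Mp[j - 1].id);
      take_best(best, Xp[j - 1].s, Xp[j - 1].id);
      take_best(best, Yp[j - 1].s, Yp[j - 1].id);
      M[j].s = (best.s <= NEG_INF / 2) ? NEG_INF : best.s + sub;
      M[j].id = best.id + hit;
      // gap in b (consume a_i): from M or X above
      Cell bx = {NEG_INF, 0};
      take_best(bx, Mp[j].s - open1, Mp[j].id);
      take_best(bx, Xp[j].s - gap_extend, Xp[j].id);
      X[j] = bx;
      // gap in a (consume b_j): from M or Y to the left (current row)
      Cell by = {NEG_INF, 0};
      take_best(by, M[j - 1].s - open1, M[j - 1].id);
      take_best(by, Y[j - 1].s - gap_extend, Y[j - 1].id);
      Y[j] = by;
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }

  Cell fin = {NEG_INF, 0};
  take_best(fin, Mp[m].s, Mp[m].id);
  take_best(fin, Xp[m].s, Xp[m].id);
  take_best(fin, Yp[m].s, Yp[m].id);
  return List::create(_["score"] = fin.s, _["identities"] = fin.id);
}

// [[Rcpp::export]]
double sw_score_c(IntegerVector a, IntegerVector b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double open1 = gap_open + gap_extend;

  std::vector<double> M(m + 1, 0.0), X(m + 1, 0.0), Y(m + 1, 0.0);
  std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, 0.0), Yp(m + 1, 0.0);
  double best = 0.0;

  for (int i = 1; i <= n; ++i) {
    M[0] = X[0] = Y[0] = 0.0;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1] - 1;
      double diag = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      double mm = diag + submat(ai, bj);
      M[j] = mm > 0.0 ? mm : 0.0;
      double xx = std::max(Mp[j] - open1, Xp[j] - gap_extend);
      X[j] = xx > 0.0 ? xx : 0.0;
      double yy = std::max(M[j - 1] - open1, Y[j - 1] - gap_extend);
      Y[j] = yy > 0.0 ? yy : 0.0;
      if (M[j] > best) best = M[j];
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  return best;
}
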