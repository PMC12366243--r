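#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gotoh three-state global alignment with affine gap cost
// gap(k) = gap_open + k * gap_extend and free terminal gaps.
// States: M (aligned pair), IX (gap in b, consumes a), IY (gap in a, consumes b).
//
// The DP optimizes lexicographically: maximal score first, then maximal
// identical-position count among score-co-optimal alignments. This makes the
// reported identity well defined (and symmetric in the two sequences) even
// when many alignments share the optimal score. Remaining ties are broken
// deterministically with priority M > IX > IY.

static const double NEG_INF = -1e30;
static const double EPS = 1e-6;

struct Cell { double s; int id; };

static inline bool better(double s1, int i1, double s2, int i2) {
  if (s1 > s2 + EPS) return true;
  if (s1 < s2 - EPS) return false;
  return i1 > i2;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix subst,
                 double gap_open, double gap_extend, bool traceback,
                 int x_index) {
  const int la = a.size(), lb = b.size();
  const double go = gap_open + gap_extend;  // cost of the first gapped position
  const double ge = gap_extend;
  const int W = lb + 1;

  std::vector<double> Ms((la + 1) * W, NEG_INF), Xs((la + 1) * W, NEG_INF),
      Ys((la + 1) * W, NEG_INF);
  std::vector<int> Mi((la + 1) * W, 0), Xi((la + 1) * W, 0),
      Yi((la + 1) * W, 0);
#define AT(v, i, j) v[(i) * W + (j)]

  AT(Ms, 0, 0) = 0.0;
  for (int i = 1; i <= la; ++i) AT(Xs, i, 0) = 0.0;  // leading gaps free
  for (int j = 1; j <= lb; ++j) AT(Ys, 0, j) = 0.0;

  const int *ap = a.begin();
  const int *bp = b.begin();
  const int nsub = subst.nrow();
  const double *sub = subst.begin();

  for (int i = 1; i <= la; ++i) {
    const double *srow = sub + ap[i - 1];
    for (int j = 1; j <= lb; ++j) {
      const int bi = bp[j - 1];
      const int add = (ap[i - 1] == bi && ap[i - 1] != x_index) ? 1 : 0;
      // M: best predecessor at (i-1, j-1), priority M > IX > IY
      double ps = AT(Ms, i - 1, j - 1); int pi = AT(Mi, i - 1, j - 1);
      if (better(AT(Xs, i - 1, j - 1), AT(Xi, i - 1, j - 1), ps, pi)) {
        ps = AT(Xs, i - 1, j - 1); pi = AT(Xi, i - 1, j - 1);
      }
      if (better(AT(Ys, i - 1, j - 1), AT(Yi, i - 1, j - 1), ps, pi)) {
        ps = AT(Ys, i - 1, j - 1); pi = AT(Yi, i - 1, j - 1);
      }
      AT(Ms, i, j) = ps + srow[(size_t)bi * nsub];
      AT(Mi, i, j) = pi + add;

      // IX: gap in b
      double xs = AT(Ms, i - 1, j) - go; int xi = AT(Mi, i - 1, j);
      if (better(AT(Xs, i - 1, j) - ge, AT(Xi, i - 1, j), xs, xi)) {
        xs = AT(Xs, i - 1, j) - ge; xi = AT(Xi, i - 1, j);
      }
      if (better(AT(Ys, i - 1, j) - go, AT(Yi, i - 1, j), xs, xi)) {
        xs = AT(Ys, i - 1, j) - go; xi = AT(Yi, i - 1, j);
      }
      AT(Xs, i, j) = xs; AT(Xi, i, j) = xi;

      // IY: gap in a
      double ys = AT(Ms, i, j - 1) - go; int yi = AT(Mi, i, j - 1);
      if (better(AT(Ys, i, j - 1) - ge, AT(Yi, i, j - 1), ys, yi)) {
        ys = AT(Ys, i, j - 1) - ge; yi = AT(Yi, i, j - 1);
      }
      if (better(AT(Xs, i, j - 1) - go, AT(Xi, i, j - 1), ys, yi)) {
        ys = AT(Xs, i, j - 1) - go; yi = AT(Xi, i, j - 1);
      }
      AT(Ys, i, j) = ys; AT(Yi, i, j) = yi;
    }
  }

  // Termination: the alignment core may end anywhere on the last row or
  // column; the remaining suffix is a free terminal gap. Prefer the corner,
  // then larger i on the last column, then larger j on the last row; state
  // priority M > IX > IY.
  double best = NEG_INF; int best_id = -1;
  int ci = la, cj = lb, cs = 0;
  for (int pass = 0; pass < 3; ++pass) {
    int i0 = la, i1 = la, j0 = lb, j1 = lb;
    if (pass == 1) { i0 = la - 1; i1 = 0; }
    if (pass == 2) { j0 = lb - 1; j1 = 0; }
    for (int i = i0; i >= i1; --i) {
      for (int j = j0; j >= j1; --j) {
        const double vs[3] = { AT(Ms, i, j), AT(Xs, i, j), AT(Ys, i, j) };
        const int vi[3] = { AT(Mi, i, j), AT(Xi, i, j), AT(Yi, i, j) };
        for (int s = 0; s < 3; ++s)
          if (better(vs[s], vi[s], best, best_id)) {
            best = vs[s]; best_id = vi[s]; ci = i; cj = j; cs = s;
          }
      }
    }
  }

  if (!traceback)
    return List::create(_["score"] = best, _["n_identical"] = best_id,
                        _["path_a"] = IntegerVector(0),
                        _["path_b"] = IntegerVector(0));

  // indices into a/b per alignment column; 0 marks a gap
  std::vector<int> col_a, col_b;
  for (int i = la; i > ci; --i) { col_a.push_back(i); col_b.push_back(0); }
  for (int j = lb; j > cj; --j) { col_a.push_back(0); col_b.push_back(j); }

  int i = ci, j = cj, s = cs;
  while (i > 0 || j > 0) {
    if (s == 0) {  // M
      if (i == 0 || j == 0) stop("traceback error: M state at matrix border");
      col_a.push_back(i); col_b.push_back(j);
      const int add = (a[i - 1] == b[j - 1] && a[i - 1] != x_index) ? 1 : 0;
      const double ns = AT(Ms, i, j) - subst(a[i - 1], b[j - 1]);
      const int ni = AT(Mi, i, j) - add;
      --i; --j;
      if (std::abs(AT(Ms, i, j) - ns) < EPS && AT(Mi, i, j) == ni) s = 0;
      else if (std::abs(AT(Xs, i, j) - ns) < EPS && AT(Xi, i, j) == ni) s = 1;
      else if (std::abs(AT(Ys, i, j) - ns) < EPS && AT(Yi, i, j) == ni) s = 2;
      else stop("traceback error: no predecessor for M");
      if (i == 0 && j == 0) break;
      if (i == 0) s = 2;
      if (j == 0) s = 1;
    } else if (s == 1) {  // IX: gap in b
      col_a.push_back(i); col_b.push_back(0);
      if (j == 0) { --i; continue; }  // leading run, free
      const double ns = AT(Xs, i, j); const int ni = AT(Xi, i, j);
      --i;
      if (std::abs(AT(Ms, i, j) - (ns + go)) < EPS && AT(Mi, i, j) == ni) s = 0;
      else if (std::abs(AT(Xs, i, j) - (ns + ge)) < EPS && AT(Xi, i, j) == ni) s = 1;
      else if (std::abs(AT(Ys, i, j) - (ns + go)) < EPS && AT(Yi, i, j) == ni) s = 2;
      else stop("traceback error: no predecessor for IX");
      if (i == 0 && j > 0) s = 2;
    } else {  // IY: gap in a
      col_a.push_back(0); col_b.push_back(j);
      if (i == 0) { --j; continue; }
      const double ns = AT(Ys, i, j); const int ni = AT(Yi, i, j);
      --j;
      if (std::abs(AT(Ms, i, j) - (ns + go)) < EPS && AT(Mi, i, j) == ni) s = 0;
      else if (std::abs(AT(Ys, i, j) - (ns + ge)) < EPS && AT(Yi, i, j) == ni) s = 2;
      else if (std::abs(AT(Xs, i, j) - (ns + go)) < EPS && AT(Xi, i, j) == ni) s = 1;
      else stop("traceback error: no predecessor for IY");
      if (j == 0 && i > 0) s = 1;
    }
  }

  const int n = col_a.size();
  IntegerVector pa(n), pb(n);
  for (int k = 0; k < n; ++k) { pa[k] = col_a[n - 1 - k]; pb[k] = col_b[n - 1 - k]; }
  return List::create(_["score"] = best, _["n_identical"] = best_id,
                      _["path_a"] = pa, _["path_b"] = pb);
#undef AT
}
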