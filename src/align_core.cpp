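#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-matrix DP) with deterministic
// traceback. States: M (residue-residue column), X (gap in B: consumes A),
// Y (gap in A: consumes B).
//
// Objective is lexicographic: maximize score, then the number of identical
// residue columns, then minimize the number of alignment columns; residual
// ties break by move precedence M > X > Y (diagonal over gap-in-B over
// gap-in-A). The secondary objectives make the reported alignment — and
// hence percent identity — invariant under swapping the input sequences,
// which a score-only tie-break does not guarantee.
//
// Gap cost conventions for a gap of length L:
//   blast  : open + extend * L      (first gap column costs open + extend)
//   emboss : open + extend * (L-1)  (first gap column costs open)
//
// Sequences arrive as 1-based integer codes into the score matrix S.

static const double NEG_INF = -1e30;

struct Cell {
  double score;
  int ident;   // identical residue columns on the best path
  int cols;    // alignment columns on the best path
  signed char from;  // predecessor state: 0=M, 1=X, 2=Y, 3=path start, -1=unset
};

static inline bool better(double s1, int i1, int c1,
                          double s2, int i2, int c2) {
  if (s1 != s2) return s1 > s2;
  if (i1 != i2) return i1 > i2;
  return c1 < c2;
}

static inline bool better_cell(const Cell &a, const Cell &b) {
  return better(a.score, a.ident, a.cols, b.score, b.ident, b.cols);
}

// [[Rcpp::export(name = ".align_core")]]
List align_core(IntegerVector a, IntegerVector b, NumericMatrix S,
                double gap_open, double gap_extend,
                bool local, bool emboss) {
  const int n = a.size(), m = b.size();
  const double first = emboss ? gap_open : (gap_open + gap_extend);
  const double ext = gap_extend;
  const size_t sz = (size_t)(n + 1) * (m + 1);

  const Cell unset = {NEG_INF, 0, 0, -1};
  std::vector<Cell> M(sz, unset), X(sz, unset), Y(sz, unset);

  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  M[idx(0, 0)] = {0.0, 0, 0, 3};

  Cell best = {0.0, 0, 0, 3};
  int best_i = 0, best_j = 0;
  bool any_pos = false;

  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i > 0 && j > 0) {
        const double s = S(a[i - 1] - 1, b[j - 1] - 1);
        const int id_add = (a[i - 1] == b[j - 1]) ? 1 : 0;
        const Cell *prev[3] = {&M[idx(i - 1, j - 1)], &X[idx(i - 1, j - 1)],
                               &Y[idx(i - 1, j - 1)]};
        Cell cur = unset;
        for (int t = 0; t < 3; ++t) {
          if (prev[t]->from == -1) continue;
          Cell cand = {prev[t]->score + s, prev[t]->ident + id_add,
                       prev[t]->cols + 1, (signed char)t};
          if (cur.from == -1 || better_cell(cand, cur)) cur = cand;
        }
        if (local && (cur.from == -1 || cur.score < 0))
          cur = {0.0, 0, 0, 3};
        M[idx(i, j)] = cur;
      } else if (local) {
        M[idx(i, j)] = {0.0, 0, 0, 3};
      }
      if (i > 0) {
        const Cell *pm = &M[idx(i - 1, j)];
        const Cell *px = &X[idx(i - 1, j)];
        const Cell *py = &Y[idx(i - 1, j)];
        Cell cur = unset;
        if (pm->from != -1)
          cur = {pm->score - first, pm->ident, pm->cols + 1, 0};
        if (px->from != -1) {
          Cell cand = {px->score - ext, px->ident, px->cols + 1, 1};
          if (cur.from == -1 || better_cell(cand, cur)) cur = cand;
        }
        if (py->from != -1) {
          Cell cand = {py->score - first, py->ident, py->cols + 1, 2};
          if (cur.from == -1 || better_cell(cand, cur)) cur = cand;
        }
        X[idx(i, j)] = cur;
      }
      if (j > 0) {
        const Cell *pm = &M[idx(i, j - 1)];
        const Cell *px = &X[idx(i, j - 1)];
        const Cell *py = &Y[idx(i, j - 1)];
        Cell cur = unset;
        if (pm->from != -1)
          cur = {pm->score - first, pm->ident, pm->cols + 1, 0};
        if (px->from != -1) {
          Cell cand = {px->score - first, px->ident, px->cols + 1, 1};
          if (cur.from == -1 || better_cell(cand, cur)) cur = cand;
        }
        if (py->from != -1) {
          Cell cand = {py->score - ext, py->ident, py->cols + 1, 2};
          if (cur.from == -1 || better_cell(cand, cur)) cur = cand;
        }
        Y[idx(i, j)] = cur;
      }
      if (local) {
        const Cell &c = M[idx(i, j)];
        if (c.from != -1 && c.score > 0 && better_cell(c, best)) {
          best = c; best_i = i; best_j = j;
          any_pos = true;
        }
      }
    }
  }

  double score;
  int ci, cj, cs;
  if (local) {
    if (!any_pos) {
      return List::create(_["score"] = 0.0,
                          _["a_pos"] = IntegerVector(0),
                          _["b_pos"] = IntegerVector(0));
    }
    score = best.score; ci = best_i; cj = best_j; cs = 0;
  } else {
    const Cell *ends[3] = {&M[idx(n, m)], &X[idx(n, m)], &Y[idx(n, m)]};
    cs = 0;
    for (int t = 1; t < 3; ++t)
      if (ends[t]->from != -1 &&
          (ends[cs]->from == -1 || better_cell(*ends[t], *ends[cs])))
        cs = t;
    score = ends[cs]->score;
    ci = n; cj = m;
  }

  std::vector<int> ap, bp;  // 0 encodes a gap
  while (!(ci == 0 && cj == 0)) {
    signed char t;
    if (cs == 0) {
      t = M[idx(ci, cj)].from;
      if (t == 3) break;  // local path start (value 0), emit nothing here
      ap.push_back(ci); bp.push_back(cj);
      --ci; --cj;
    } else if (cs == 1) {
      t = X[idx(ci, cj)].from;
      ap.push_back(ci); bp.push_back(0);
      --ci;
    } else {
      t = Y[idx(ci, cj)].from;
      ap.push_back(0); bp.push_back(cj);
      --cj;
    }
    cs = t;
  }

  std::reverse(ap.begin(), ap.end());
  std::reverse(bp.begin(), bp.end());
  return List::create(_["score"] = score,
                      _["a_pos"] = IntegerVector(ap.begin(), ap.end()),
                      _["b_pos"] = IntegerVector(bp.begin(), bp.end()));
}
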