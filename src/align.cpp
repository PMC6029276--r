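#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Ends-free global nucleotide alignment with affine gaps and a lexicographic
// (score, matches) objective: among maximum-score alignments the one with the
// most identical aligned positions is reported, which makes the identity
// statistic deterministic. Scoring: match +1, mismatch -1, a gap of length L
// costs 2 + (L - 1). Leading and trailing gaps are free (overlap/dovetail
// semantics). 'N' (or any non-ACGT symbol) never counts as a match.

static const int NEG = -1000000000;
static const int GO = 2; // cost of a gap's first position
static const int GE = 1; // cost of each further position

struct Cell {
  int sc, mt, si, sj; // score, matches, origin (0-based, chars consumed before start)
  Cell() : sc(NEG), mt(0), si(0), sj(0) {}
};

static inline bool lex_gt(int sc1, int mt1, int sc2, int mt2) {
  return sc1 > sc2 || (sc1 == sc2 && mt1 > mt2);
}

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Rolling-row DP returning score/matches/spans only.
static void overlap_stats(const std::string &a, const std::string &b,
                          int &score, int &matches,
                          int &ai, int &ae, int &bi, int &be) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<Cell> pM(m + 1), pX(m + 1), pY(m + 1);
  std::vector<Cell> cM(m + 1), cX(m + 1), cY(m + 1);

  // best end: empty alignment baseline (score 0, 0 matches)
  int bsc = 0, bmt = 0, bsi = 0, bsj = 0, bei = 0, bej = 0;

  for (int i = 1; i <= n; ++i) {
    cM[0] = Cell(); cX[0] = Cell(); cY[0] = Cell();
    for (int j = 1; j <= m; ++j) {
      const char ca = a[i - 1], cb = b[j - 1];
      const bool hit = (ca == cb) && is_base(ca);
      const int s = hit ? 1 : -1;

      // M: align a_i with b_j
      Cell best;
      if (i - 1 == 0 || j - 1 == 0) { // free start on the boundary
        best.sc = 0; best.mt = 0; best.si = i - 1; best.sj = j - 1;
      }
      const Cell *preds[3] = { &pM[j - 1], &pX[j - 1], &pY[j - 1] };
      for (int t = 0; t < 3; ++t)
        if (preds[t]->sc > NEG && lex_gt(preds[t]->sc, preds[t]->mt, best.sc, best.mt))
          best = *preds[t];
      if (best.sc > NEG) {
        cM[j] = best;
        cM[j].sc += s;
        cM[j].mt += hit ? 1 : 0;
      } else cM[j] = Cell();

      // X: a_i vs gap (gap in b), predecessors in previous row, same j
      Cell x;
      if (pM[j].sc > NEG) { x = pM[j]; x.sc -= GO; }
      if (pX[j].sc > NEG && lex_gt(pX[j].sc - GE, pX[j].mt, x.sc, x.mt)) {
        x = pX[j]; x.sc -= GE;
      }
      cX[j] = x;

      // Y: gap vs b_j, predecessors in current row, j-1
      Cell y;
      if (cM[j - 1].sc > NEG) { y = cM[j - 1]; y.sc -= GO; }
      if (cY[j - 1].sc > NEG && lex_gt(cY[j - 1].sc - GE, cY[j - 1].mt, y.sc, y.mt)) {
        y = cY[j - 1]; y.sc -= GE;
      }
      cY[j] = y;

      // candidate end cells: last row or last column
      if (i == n || j == m) {
        const Cell *ends[3] = { &cM[j], &cX[j], &cY[j] };
        for (int t = 0; t < 3; ++t)
          if (ends[t]->sc > NEG && lex_gt(ends[t]->sc, ends[t]->mt, bsc, bmt)) {
            bsc = ends[t]->sc; bmt = ends[t]->mt;
            bsi = ends[t]->si; bsj = ends[t]->sj; bei = i; bej = j;
          }
      }
    }
    std::swap(pM, cM); std::swap(pX, cX); std::swap(pY, cY);
  }
  score = bsc; matches = bmt;
  ai = bsi; ae = bei; bi = bsj; be = bej;
  if (bsc == 0 && bmt == 0 && bei == 0 && bej == 0) { ai = ae = bi = be = 0; }
}

// Full-matrix DP with traceback, returning the aligned strings as well.
static void overlap_traceback(const std::string &a, const std::string &b,
                              int &score, int &matches,
                              int &ai, int &ae, int &bi, int &be,
                              std::string &outa, std::string &outb) {
  const int n = (int)a.size(), m = (int)b.size();
  const size_t W = (size_t)(m + 1);
  auto idx = [&](int i, int j) { return (size_t)i * W + (size_t)j; };
  std::vector<int> Ms((n + 1) * W, NEG), Mm((n + 1) * W, 0);
  std::vector<int> Xs((n + 1) * W, NEG), Xm((n + 1) * W, 0);
  std::vector<int> Ys((n + 1) * W, NEG), Ym((n + 1) * W, 0);
  // dir codes: M: 0 free start, 1 from M, 2 from X, 3 from Y; X: 1 M, 2 X; Y: 1 M, 3 Y
  std::vector<signed char> Md((n + 1) * W, -1), Xd((n + 1) * W, -1), Yd((n + 1) * W, -1);

  int bsc = 0, bmt = 0, bei = 0, bej = 0, bst = -1; // -1 = empty alignment

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const char ca = a[i - 1], cb = b[j - 1];
      const bool hit = (ca == cb) && is_base(ca);
      const int s = hit ? 1 : -1;
      const size_t q = idx(i, j), qd = idx(i - 1, j - 1);
      const size_t qu = idx(i - 1, j), ql = idx(i, j - 1);

      int bs = NEG, bm = 0; signed char bd = -1;
      if (i - 1 == 0 || j - 1 == 0) { bs = 0; bm = 0; bd = 0; }
      if (Ms[qd] > NEG && lex_gt(Ms[qd], Mm[qd], bs, bm)) { bs = Ms[qd]; bm = Mm[qd]; bd = 1; }
      if (Xs[qd] > NEG && lex_gt(Xs[qd], Xm[qd], bs, bm)) { bs = Xs[qd]; bm = Xm[qd]; bd = 2; }
      if (Ys[qd] > NEG && lex_gt(Ys[qd], Ym[qd], bs, bm)) { bs = Ys[qd]; bm = Ym[qd]; bd = 3; }
      if (bs > NEG) { Ms[q] = bs + s; Mm[q] = bm + (hit ? 1 : 0); Md[q] = bd; }

      int xs = NEG, xm = 0; signed char xd = -1;
      if (Ms[qu] > NEG) { xs = Ms[qu] - GO; xm = Mm[qu]; xd = 1; }
      if (Xs[qu] > NEG && lex_gt(Xs[qu] - GE, Xm[qu], xs, xm)) { xs = Xs[qu] - GE; xm = Xm[qu]; xd = 2; }
      if (xs > NEG) { Xs[q] = xs; Xm[q] = xm; Xd[q] = xd; }

      int ys = NEG, ym = 0; signed char yd = -1;
      if (Ms[ql] > NEG) { ys = Ms[ql] - GO; ym = Mm[ql]; yd = 1; }
      if (Ys[ql] > NEG && lex_gt(Ys[ql] - GE, Ym[ql], ys, ym)) { ys = Ys[ql] - GE; ym = Ym[ql]; yd = 3; }
      if (ys > NEG) { Ys[q] = ys; Ym[q] = ym; Yd[q] = yd; }

      if (i == n || j == m) {
        if (Ms[q] > NEG && lex_gt(Ms[q], Mm[q], bsc, bmt)) { bsc = Ms[q]; bmt = Mm[q]; bei = i; bej = j; bst = 0; }
        if (Xs[q] > NEG && lex_gt(Xs[q], Xm[q], bsc, bmt)) { bsc = Xs[q]; bmt = Xm[q]; bei = i; bej = j; bst = 1; }
        if (Ys[q] > NEG && lex_gt(Ys[q], Ym[q], bsc, bmt)) { bsc = Ys[q]; bmt = Ym[q]; bei = i; bej = j; bst = 2; }
      }
    }
  }

  score = bsc; matches = bmt;
  outa.clear(); outb.clear();
  if (bst < 0) { ai = ae = bi = be = 0; return; }

  int i = bei, j = bej, st = bst;
  std::string ra, rb;
  while (true) {
    const size_t q = idx(i, j);
    if (st == 0) { // M
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      const signed char d = Md[q];
      --i; --j;
      if (d == 0) break;
      st = (d == 1) ? 0 : (d == 2 ? 1 : 2);
    } else if (st == 1) { // X
      ra.push_back(a[i - 1]); rb.push_back('-');
      const signed char d = Xd[q];
      --i;
      st = (d == 1) ? 0 : 1;
    } else { // Y
      ra.push_back('-'); rb.push_back(b[j - 1]);
      const signed char d = Yd[q];
      --j;
      st = (d == 1) ? 0 : 2;
    }
  }
  ai = i; bi = j; ae = bei; be = bej;
  outa.assign(ra.rbegin(), ra.rend());
  outb.assign(rb.rbegin(), rb.rend());
}

// Fast kernel: identical objective/recurrences as overlap_stats but with the
// (score, matches) pair packed into one int64 (score * 2^20 + matches, which
// preserves lexicographic order because 0 <= matches < 2^20) and no span
// tracking. Used where only score and match count are needed.
// [[Rcpp::export]]
List overlap_matches_cpp(std::string a, std::string b) {
  if (a.empty() || b.empty())
    stop("overlap_align: empty sequence");
  const int n = (int)a.size(), m = (int)b.size();
  const int64_t SHIFT = 20;
  const int64_t ONEPT = ((int64_t)1 << SHIFT);
  const int64_t MATCH = ONEPT + 1;   // score +1, matches +1
  const int64_t MISS = -ONEPT;       // score -1
  const int64_t GOP = (int64_t)GO << SHIFT;
  const int64_t GEP = (int64_t)GE << SHIFT;
  const int64_t BAD = (int64_t)NEG << SHIFT;
  std::vector<int64_t> pM(m + 1, BAD), pX(m + 1, BAD), pY(m + 1, BAD);
  std::vector<int64_t> cM(m + 1), cX(m + 1), cY(m + 1);
  int64_t best = 0; // empty-alignment baseline
  for (int i = 1; i <= n; ++i) {
    cM[0] = BAD; cX[0] = BAD; cY[0] = BAD;
    const char ca = a[i - 1];
    const bool ca_base = is_base(ca);
    const int64_t freeStart = (i == 1) ? 0 : BAD;
    for (int j = 1; j <= m; ++j) {
      int64_t pre = (j == 1) ? 0 : freeStart;
      if (pM[j - 1] > pre) pre = pM[j - 1];
      if (pX[j - 1] > pre) pre = pX[j - 1];
      if (pY[j - 1] > pre) pre = pY[j - 1];
      cM[j] = pre + ((ca == b[j - 1] && ca_base) ? MATCH : MISS);
      int64_t x = pM[j] - GOP;
      const int64_t x2 = pX[j] - GEP;
      if (x2 > x) x = x2;
      cX[j] = x;
      int64_t y = cM[j - 1] - GOP;
      const int64_t y2 = cY[j - 1] - GEP;
      if (y2 > y) y = y2;
      cY[j] = y;
    }
    const int64_t endc = std::max(cM[m], std::max(cX[m], cY[m]));
    if (endc > best) best = endc;
    std::swap(pM, cM); std::swap(pX, cX); std::swap(pY, cY);
  }
  for (int j = 1; j <= m; ++j) { // pM now holds row n
    const int64_t endc = std::max(pM[j], std::max(pX[j], pY[j]));
    if (endc > best) best = endc;
  }
  const int64_t sc = best >> SHIFT; // floor division keeps matches in range
  const int64_t mt = best - (sc << SHIFT);
  return List::create(_["score"] = (int)sc, _["matches"] = (int)mt);
}

// [[Rcpp::export]]
List overlap_align_cpp(std::string a, std::string b, bool traceback = false) {
  if (a.empty() || b.empty())
    stop("overlap_align: empty sequence");
  int score, matches, ai, ae, bi, be;
  std::string outa, outb;
  if (traceback)
    overlap_traceback(a, b, score, matches, ai, ae, bi, be, outa, outb);
  else
    overlap_stats(a, b, score, matches, ai, ae, bi, be);
  return List::create(
    _["score"] = score, _["matches"] = matches,
    _["a_start"] = ai + 1, _["a_end"] = ae,
    _["b_start"] = bi + 1, _["b_end"] = be,
    _["aligned_a"] = outa, _["aligned_b"] = outb);
}
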