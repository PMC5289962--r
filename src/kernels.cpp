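#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e18;

// Banded affine-gap Smith-Waterman over pairs of sequences, returning the
// optimal local score plus path statistics (matches, aligned columns, spans)
// carried alongside the DP so no traceback matrix is needed. A gap of length
// k costs gap_open + k * gap_extend. Band half-width is
// |len_a - len_b| + band_extra; band_extra < 0 disables banding.
struct PathInfo { int m, c, si, sj; };

// [[Rcpp::export]]
DataFrame sw_stats_batch(CharacterVector a, CharacterVector b,
                         IntegerMatrix submat, int gap_open, int gap_extend,
                         int band_extra) {
  int n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  NumericVector score(n);
  IntegerVector matches(n), cols(n), span_a(n), span_b(n);
  const double goe = gap_open + gap_extend, ge = gap_extend;

  // local copy of the 128 x 128 substitution lookup
  static_assert(sizeof(int) == 4, "int size");
  std::vector<int> sub(128 * 128);
  for (int i = 0; i < 128; ++i)
    for (int j = 0; j < 128; ++j) sub[i * 128 + j] = submat(i, j);

  std::vector<double> Mp, Xp, Yp, Mc, Xc, Yc;
  std::vector<PathInfo> Mip, Xip, Yip, Mic, Xic, Yic;

  for (int p = 0; p < n; ++p) {
    const char *sa = CHAR(STRING_ELT(a, p));
    const char *sb = CHAR(STRING_ELT(b, p));
    int la = std::strlen(sa), lb = std::strlen(sb);
    int band = band_extra < 0 ? lb + la : std::abs(la - lb) + band_extra;
    int W = lb + 1;
    Mp.assign(W, NEG); Xp.assign(W, NEG); Yp.assign(W, NEG);
    Mc.assign(W, NEG); Xc.assign(W, NEG); Yc.assign(W, NEG);
    Mip.assign(W, PathInfo()); Xip.assign(W, PathInfo());
    Yip.assign(W, PathInfo()); Mic.assign(W, PathInfo());
    Xic.assign(W, PathInfo()); Yic.assign(W, PathInfo());
    double best = 0; PathInfo binf = PathInfo(); int bei = 0, bej = 0;

    for (int i = 1; i <= la; ++i) {
      int jlo = std::max(1, i - band), jhi = std::min(lb, i + band);
      int rhi = std::min(W, jhi + 2);   // next row peeks one column further
      std::fill(Mc.begin() + jlo - 1, Mc.begin() + rhi, NEG);
      std::fill(Xc.begin() + jlo - 1, Xc.begin() + rhi, NEG);
      std::fill(Yc.begin() + jlo - 1, Yc.begin() + rhi, NEG);
      const int ca = (unsigned char) sa[i - 1];
      const int *subrow = &sub[ca * 128];
      for (int j = jlo; j <= jhi; ++j) {
        const int cb = (unsigned char) sb[j - 1];
        const double s = subrow[cb];
        // M: diagonal predecessors or a fresh local start
        double base = Mp[j - 1]; int src = 0;
        if (Xp[j - 1] > base) { base = Xp[j - 1]; src = 1; }
        if (Yp[j - 1] > base) { base = Yp[j - 1]; src = 2; }
        double mval; PathInfo mi;
        if (base <= 0) {   // start a new alignment at (i-1, j-1)
          mval = s; mi.m = (ca == cb); mi.c = 1; mi.si = i - 1; mi.sj = j - 1;
        } else {
          mval = base + s;
          mi = (src == 0) ? Mip[j - 1] : (src == 1) ? Xip[j - 1] : Yip[j - 1];
          mi.m += (ca == cb); mi.c += 1;
        }
        if (mval < 0) mval = NEG;   // dead cell
        Mc[j] = mval; Mic[j] = mi;
        if (mval > best) { best = mval; binf = mi; bei = i; bej = j; }
        // X: gap in b (consume a), from the row above
        double xo = Mp[j] - goe, xe = Xp[j] - ge;
        if (xe >= xo) { Xc[j] = xe; Xic[j] = Xip[j]; }
        else          { Xc[j] = xo; Xic[j] = Mip[j]; }
        Xic[j].c += 1;
        // Y: gap in a (consume b), from the left in the current row
        double yo = Mc[j - 1] - goe, ye = Yc[j - 1] - ge;
        if (ye >= yo) { Yc[j] = ye; Yic[j] = Yic[j - 1]; }
        else          { Yc[j] = yo; Yic[j] = Mic[j - 1]; }
        Yic[j].c += 1;
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
      std::swap(Mip, Mic); std::swap(Xip, Xic); std::swap(Yip, Yic);
    }
    score[p] = best; matches[p] = binf.m; cols[p] = binf.c;
    span_a[p] = bei - binf.si; span_b[p] = bej - binf.sj;
  }
  return DataFrame::create(_["score"] = score, _["matches"] = matches,
                           _["aln_cols"] = cols, _["span_a"] = span_a,
                           _["span_b"] = span_b);
}

// Hamming distance with early exit; returns max_d + 1 when the bound is
// exceeded or the lengths differ (substitution-only distance).
// [[Rcpp::export]]
IntegerVector hamming_bounded(std::string query, CharacterVector refs,
                              int max_d) {
  int n = refs.size();
  IntegerVector out(n);
  int lq = query.size();
  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(refs, i));
    int lr = std::strlen(r);
    if (lr != lq) { out[i] = max_d + 1; continue; }
    int d = 0;
    for (int j = 0; j < lq && d <= max_d; ++j) d += (query[j] != r[j]);
    out[i] = d > max_d ? max_d + 1 : d;
  }
  return out;
}

// All-pairs Hamming distances between queries and references; -1 marks a
// length mismatch (substitution-only distance undefined).
// [[Rcpp::export]]
IntegerMatrix hamming_matrix(CharacterVector queries, CharacterVector refs) {
  int nq = queries.size(), nr = refs.size();
  IntegerMatrix out(nq, nr);
  std::vector<const char*> rp(nr);
  std::vector<int> rl(nr);
  for (int j = 0; j < nr; ++j) {
    rp[j] = CHAR(STRING_ELT(refs, j));
    rl[j] = std::strlen(rp[j]);
  }
  for (int i = 0; i < nq; ++i) {
    const char *q = CHAR(STRING_ELT(queries, i));
    int lq = std::strlen(q);
    for (int j = 0; j < nr; ++j) {
      if (rl[j] != lq) { out(i, j) = -1; continue; }
      int d = 0;
      for (int k = 0; k < lq; ++k) d += (q[k] != rp[j][k]);
      out(i, j) = d;
    }
  }
  return out;
}

// Overlap-merge of read pairs. r2 must already be reverse-complemented (and
// its qualities reversed). For each pair the suffix-prefix overlap with the
// best +1 match / -1 mismatch score among overlaps >= min_overlap is chosen
// (ties broken toward the longer overlap); pairs whose best overlap has a
// mismatch fraction above max_mm_frac, or no feasible overlap, are rejected.
// Consensus: agreeing bases keep max quality; conflicts take the
// higher-quality base with quality |q1 - q2|.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector r2rc,
                     List q1, List q2rc, int min_overlap,
                     double max_mm_frac) {
  int n = r1.size();
  CharacterVector merged(n);
  List mq(n);
  IntegerVector overlap(n), mism(n);
  LogicalVector ok(n);
  for (int p = 0; p < n; ++p) {
    const char *s1 = CHAR(STRING_ELT(r1, p));
    const char *s2 = CHAR(STRING_ELT(r2rc, p));
    int l1 = std::strlen(s1), l2 = std::strlen(s2);
    int omax = std::min(l1, l2);
    int best_o = -1, best_mm = 0, best_score = INT_MIN;
    for (int o = min_overlap; o <= omax; ++o) {
      int mm = 0;
      const char *t1 = s1 + l1 - o;
      for (int j = 0; j < o; ++j) mm += (t1[j] != s2[j]);
      int sc = o - 2 * mm;
      if (sc >= best_score) { best_score = sc; best_o = o; best_mm = mm; }
    }
    if (best_o < 0 || best_mm > max_mm_frac * best_o) {
      ok[p] = false; overlap[p] = best_o < 0 ? 0 : best_o;
      mism[p] = best_o < 0 ? 0 : best_mm;
      merged[p] = NA_STRING; mq[p] = R_NilValue;
      continue;
    }
    IntegerVector qa = q1[p], qb = q2rc[p];
    int L = l1 + l2 - best_o;
    std::string out(L, 'N');
    IntegerVector qo(L);
    for (int j = 0; j < l1 - best_o; ++j) { out[j] = s1[j]; qo[j] = qa[j]; }
    for (int j = 0; j < best_o; ++j) {
      int i1 = l1 - best_o + j;
      char c1 = s1[i1], c2 = s2[j];
      int v1 = qa[i1], v2 = qb[j];
      if (c1 == c2) { out[i1] = c1; qo[i1] = std::max(v1, v2); }
      else if (v1 >= v2) { out[i1] = c1; qo[i1] = v1 - v2; }
      else { out[i1] = c2; qo[i1] = v2 - v1; }
    }
    for (int j = best_o; j < l2; ++j) {
      out[l1 - best_o + j] = s2[j];
      qo[l1 - best_o + j] = qb[j];
    }
    merged[p] = out; mq[p] = qo; overlap[p] = best_o; mism[p] = best_mm;
    ok[p] = true;
  }
  return List::create(_["seq"] = merged, _["qual"] = mq,
                      _["overlap"] = overlap, _["mismatches"] = mism,
                      _["accepted"] = ok);
}
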