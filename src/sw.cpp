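// Exhaustive Smith-Waterman local alignment core for the translated search.
// Affine gaps: a gap of length L costs open + L * ext (BLAST convention, so
// open = 11, ext = 1 reproduces blastp/blastx default penalties).
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// NCBI BLOSUM62, alphabet ARNDCQEGHILKMFPSTWYVBZX* (24 letters).
static const char AA_ALPHA[] = "ARNDCQEGHILKMFPSTWYVBZX*";
static const int NAA = 24;
static const int BLOSUM62[NAA][NAA] = {
  // A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   B   Z   X   *
  {  4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0, -2, -1,  0, -4 }, // A
  { -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3, -1,  0, -1, -4 }, // R
  { -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,  3,  0, -1, -4 }, // N
  { -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,  4,  1, -1, -4 }, // D
  {  0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1, -3, -3, -2, -4 }, // C
  { -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,  0,  3, -1, -4 }, // Q
  { -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,  1,  4, -1, -4 }, // E
  {  0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3, -1, -2, -1, -4 }, // G
  { -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,  0,  0, -1, -4 }, // H
  { -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3, -3, -3, -1, -4 }, // I
  { -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1, -4, -3, -1, -4 }, // L
  { -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,  0,  1, -1, -4 }, // K
  { -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1, -3, -1, -1, -4 }, // M
  { -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1, -3, -3, -1, -4 }, // F
  { -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2, -2, -1, -2, -4 }, // P
  {  1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,  0,  0,  0, -4 }, // S
  {  0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0, -1, -1,  0, -4 }, // T
  { -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3, -4, -3, -2, -4 }, // W
  { -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1, -3, -2, -1, -4 }, // Y
  {  0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4, -3, -2, -1, -4 }, // V
  { -2, -1,  3,  4, -3,  0,  1, -1,  0, -3, -4,  0, -3, -3, -2,  0, -1, -4, -3, -3,  4,  1, -1, -4 }, // B
  { -1,  0,  0,  1, -3,  3,  4, -2,  0, -3, -3,  1, -1, -3, -1,  0, -1, -3, -2, -2,  1,  4, -1, -4 }, // Z
  {  0, -1, -1, -1, -2, -1, -1, -1, -1, -1, -1, -1, -1, -1, -2,  0,  0, -2, -1, -1, -1, -1, -1, -4 }, // X
  { -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4, -4,  1 }  // *
};
static const int XIDX = 22;

static inline void build_lookup(int *lut) {
  for (int i = 0; i < 256; ++i) lut[i] = XIDX; // unknown residues behave as X
  for (int i = 0; i < NAA; ++i) lut[(unsigned char)AA_ALPHA[i]] = i;
}

static void encode(const char *s, int len, const int *lut, std::vector<int> &out) {
  out.resize(len);
  for (int i = 0; i < len; ++i) out[i] = lut[(unsigned char)s[i]];
}

// Score-only SW over one fragment x one protein (linear memory). Work
// buffers are caller-provided so batch callers avoid reallocation.
static int sw_score_full(const std::vector<int> &q, const std::vector<int> &s,
                         int open, int ext,
                         std::vector<int> &Hbuf, std::vector<int> &Fbuf) {
  const int m = (int)q.size(), n = (int)s.size();
  if ((int)Hbuf.size() < n + 1) { Hbuf.resize(n + 1); Fbuf.resize(n + 1); }
  int *H = Hbuf.data(), *F = Fbuf.data();
  const int *sp = s.data();
  const int oe = open + ext;
  for (int j = 0; j <= n; ++j) { H[j] = 0; F[j] = 0; }
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int *row = BLOSUM62[q[i - 1]];
    int diag = 0, hprev = 0, e = 0;
    for (int j = 1; j <= n; ++j) {
      e -= ext;
      const int eo = hprev - oe;
      if (eo > e) e = eo;
      int f = F[j] - ext;
      const int fo = H[j] - oe;
      if (fo > f) f = fo;
      F[j] = f;
      int h = diag + row[sp[j - 1]];
      diag = H[j];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[j] = h;
      hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

struct AlnStats {
  int score, matches, cols, qs, qe, ss, se; // 0-based half-open spans
};

// Full SW with traceback for one pair. Deterministic tie policy in the
// traceback: diagonal > gap-in-query(E) > gap-in-subject(F).
static AlnStats sw_traceback(const std::vector<int> &q, const std::vector<int> &s,
                             int open, int ext) {
  const int m = (int)q.size(), n = (int)s.size();
  const int W = n + 1;
  std::vector<int> H((m + 1) * W, 0), E((m + 1) * W, 0), F((m + 1) * W, 0);
  const int NEG = -1000000;
  for (int j = 0; j <= n; ++j) { E[j] = NEG; F[j] = NEG; }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    E[i * W] = NEG; F[i * W] = NEG;
    const int *row = BLOSUM62[q[i - 1]];
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[i * W + j - 1] - open - ext, E[i * W + j - 1] - ext);
      int f = std::max(H[(i - 1) * W + j] - open - ext, F[(i - 1) * W + j] - ext);
      int h = H[(i - 1) * W + j - 1] + row[s[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[i * W + j] = e; F[i * W + j] = f; H[i * W + j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  AlnStats out; out.score = best;
  out.matches = 0; out.cols = 0;
  int i = bi, j = bj;
  out.qe = bi; out.se = bj;
  while (i > 0 && j > 0 && H[i * W + j] > 0) {
    int h = H[i * W + j];
    const int sc = BLOSUM62[q[i - 1]][s[j - 1]];
    if (h == H[(i - 1) * W + j - 1] + sc) {
      // X never counts as an identity
      if (q[i - 1] == s[j - 1] && q[i - 1] != XIDX) out.matches++;
      out.cols++; --i; --j;
    } else if (h == E[i * W + j]) {
      // gap consuming subject residues
      while (j > 0 && E[i * W + j] == E[i * W + j - 1] - ext &&
             E[i * W + j] != H[i * W + j - 1] - open - ext) {
        out.cols++; --j;
      }
      out.cols++; --j;
    } else { // F
      while (i > 0 && F[i * W + j] == F[(i - 1) * W + j] - ext &&
             F[i * W + j] != H[(i - 1) * W + j] - open - ext) {
        out.cols++; --i;
      }
      out.cols++; --i;
    }
  }
  out.qs = i; out.ss = j;
  return out;
}

// [[Rcpp::export(name = ".sw_pair_cpp")]]
List sw_pair_cpp(std::string a, std::string b, int gap_open, int gap_extend) {
  int lut[256]; build_lookup(lut);
  std::vector<int> q, s;
  encode(a.c_str(), (int)a.size(), lut, q);
  encode(b.c_str(), (int)b.size(), lut, s);
  AlnStats st = sw_traceback(q, s, gap_open, gap_extend);
  return List::create(_["score"] = st.score, _["matches"] = st.matches,
                      _["cols"] = st.cols, _["qs"] = st.qs, _["qe"] = st.qe,
                      _["ss"] = st.ss, _["se"] = st.se);
}

// Best hit per read over all fragments x all proteins.
// frags: peptide fragments, grouped so that fragments of one read are
//        contiguous; frag_read: 0-based read index per fragment (non-decreasing);
// prots: reference proteins, already sorted by accession.
// Ties on score are broken by higher identity (matches/cols), longer
// alignment, smaller protein index, then smaller fragment index.
// [[Rcpp::export(name = ".sw_best_hits_cpp")]]
DataFrame sw_best_hits_cpp(CharacterVector frags, IntegerVector frag_read,
                           CharacterVector prots, int gap_open, int gap_extend,
                           int score_floor) {
  int lut[256]; build_lookup(lut);
  const int nf = frags.size(), np = prots.size();
  std::vector< std::vector<int> > P(np);
  for (int p = 0; p < np; ++p) {
    const char *cp = CHAR(STRING_ELT(prots, p));
    encode(cp, (int)std::strlen(cp), lut, P[p]);
  }
  std::vector< std::vector<int> > Q(nf);
  for (int f = 0; f < nf; ++f) {
    const char *cf = CHAR(STRING_ELT(frags, f));
    encode(cf, (int)std::strlen(cf), lut, Q[f]);
  }

  std::vector<int> r_read, r_frag, r_prot, r_score, r_match, r_cols,
    r_qs, r_qe, r_ss, r_se;
  std::vector<int> Hbuf, Fbuf;

  int f0 = 0;
  // scores for the fragments of the current read
  while (f0 < nf) {
    int read = frag_read[f0];
    int f1 = f0;
    while (f1 < nf && frag_read[f1] == read) ++f1;
    int best = 0;
    std::vector< std::pair<int,int> > cand; // (frag, prot) achieving best
    for (int f = f0; f < f1; ++f) {
      for (int p = 0; p < np; ++p) {
        int sc = sw_score_full(Q[f], P[p], gap_open, gap_extend, Hbuf, Fbuf);
        if (sc > best) { best = sc; cand.clear(); cand.push_back({f, p}); }
        else if (sc == best && best > 0) cand.push_back({f, p});
      }
    }
    if (best >= score_floor && !cand.empty()) {
      // resolve ties with traceback statistics
      AlnStats bestSt; int bestF = -1, bestP = -1;
      for (size_t k = 0; k < cand.size(); ++k) {
        AlnStats st = sw_traceback(Q[cand[k].first], P[cand[k].second],
                                   gap_open, gap_extend);
        bool take = false;
        if (bestF < 0) take = true;
        else {
          long long lhs = (long long)st.matches * bestSt.cols;
          long long rhs = (long long)bestSt.matches * st.cols;
          if (lhs != rhs) take = lhs > rhs;
          else if (st.cols != bestSt.cols) take = st.cols > bestSt.cols;
          else if (cand[k].second != bestP) take = cand[k].second < bestP;
          else take = cand[k].first < bestF;
        }
        if (take) { bestSt = st; bestF = cand[k].first; bestP = cand[k].second; }
      }
      r_read.push_back(read); r_frag.push_back(bestF); r_prot.push_back(bestP);
      r_score.push_back(bestSt.score); r_match.push_back(bestSt.matches);
      r_cols.push_back(bestSt.cols);
      r_qs.push_back(bestSt.qs); r_qe.push_back(bestSt.qe);
      r_ss.push_back(bestSt.ss); r_se.push_back(bestSt.se);
    }
    f0 = f1;
    if ((f0 & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
    _["read"] = r_read, _["frag"] = r_frag, _["prot"] = r_prot,
    _["score"] = r_score, _["matches"] = r_match, _["cols"] = r_cols,
    _["qs"] = r_qs, _["qe"] = r_qe, _["ss"] = r_ss, _["se"] = r_se);
}

// All fragment x marker alignments passing score floor, identity and
// marker-coverage thresholds (marker-based quantification). Returns one row
// per passing (fragment, marker) pair.
// [[Rcpp::export(name = ".sw_vs_markers_cpp")]]
DataFrame sw_vs_markers_cpp(CharacterVector frags, CharacterVector markers,
                            int gap_open, int gap_extend, int score_floor,
                            double min_identity_frac, double min_marker_cover) {
  int lut[256]; build_lookup(lut);
  const int nf = frags.size(), nm = markers.size();
  std::vector< std::vector<int> > M(nm);
  for (int k = 0; k < nm; ++k) {
    const char *cm = CHAR(STRING_ELT(markers, k));
    encode(cm, (int)std::strlen(cm), lut, M[k]);
  }
  std::vector<int> r_frag, r_marker, r_score;
  std::vector<double> r_ident, r_cover;
  std::vector<int> q;
  for (int f = 0; f < nf; ++f) {
    const char *cf = CHAR(STRING_ELT(frags, f));
    encode(cf, (int)std::strlen(cf), lut, q);
    for (int k = 0; k < nm; ++k) {
      AlnStats st = sw_traceback(q, M[k], gap_open, gap_extend);
      if (st.score < score_floor || st.cols == 0) continue;
      double ident = (double)st.matches / st.cols;
      // coverage is judged against whichever is shorter, marker or
      // fragment: a short read cannot be asked to span a long marker
      double unit = (double)std::min(M[k].size(), q.size());
      double cover = (double)(st.se - st.ss) / unit;
      if (ident >= min_identity_frac && cover >= min_marker_cover) {
        r_frag.push_back(f + 1); r_marker.push_back(k + 1);
        r_score.push_back(st.score); r_ident.push_back(100.0 * ident);
        r_cover.push_back(cover);
      }
    }
    if ((f & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["frag"] = r_frag, _["marker"] = r_marker,
                           _["score"] = r_score, _["identity_pct"] = r_ident,
                           _["marker_cover"] = r_cover);
}

// Sliding-window background masking for marker discovery: position block
// [i, i+window) of the centroid is masked when some equal-length ungapped
// window of a background protein matches it at >= min_frac identity.
// [[Rcpp::export(name = ".mask_windows_cpp")]]
LogicalVector mask_windows_cpp(std::string centroid, CharacterVector background,
                               int window, double min_frac) {
  int lut[256]; build_lookup(lut);
  std::vector<int> c;
  encode(centroid.c_str(), (int)centroid.size(), lut, c);
  const int L = (int)c.size();
  const int w = std::min(window, L);
  LogicalVector mask(L, false);
  for (int b = 0; b < background.size(); ++b) {
    const char *cb = CHAR(STRING_ELT(background, b));
    std::vector<int> s;
    encode(cb, (int)std::strlen(cb), lut, s);
    const int n = (int)s.size();
    if (n < w) continue;
    for (int i = 0; i + w <= L; ++i) {
      if (w > 0) {
        bool hit = false;
        for (int j = 0; j + w <= n && !hit; ++j) {
          int id = 0;
          for (int k = 0; k < w; ++k)
            if (c[i + k] == s[j + k] && c[i + k] != XIDX) ++id;
          if ((double)id / w >= min_frac) hit = true;
        }
        if (hit) for (int k = 0; k < w; ++k) mask[i + k] = true;
      }
    }
  }
  return mask;
}
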