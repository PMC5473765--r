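#include <Rcpp.h>
using namespace Rcpp;

// Low-level sequence kernels shared by the detector, the mapper and the
// distance code. Sequences are plain C strings over {A,C,G,T,N,-}.

// [[Rcpp::export]]
IntegerVector hamming_count(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("vectors must have equal length");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const char *x = CHAR(STRING_ELT(a, i));
    const char *y = CHAR(STRING_ELT(b, i));
    R_xlen_t nx = LENGTH(STRING_ELT(a, i)), ny = LENGTH(STRING_ELT(b, i));
    if (nx != ny) stop("strings in pair %d differ in length", (int)(i + 1));
    int mm = 0;
    for (R_xlen_t j = 0; j < nx; ++j) if (x[j] != y[j]) ++mm;
    out[i] = mm;
  }
  return out;
}

// Ungapped x-drop extension of putative direct-repeat pairs.
// i1 < i2 are 0-based starts of a seed of length `len` on the same
// diagonal; extends left of the starts and right of the ends with
// +1/match, -penalty/mismatch, stopping when the running score falls
// `xdrop` below the best seen. The right end of the left copy is not
// allowed to reach i2 (repeat copies must not overlap).
// Returns a matrix with columns (left, right) of extension lengths.
// [[Rcpp::export]]
IntegerMatrix extend_repeat_batch(std::string genome, IntegerVector i1,
                                  IntegerVector i2, IntegerVector len,
                                  int mismatch_penalty = 3, int xdrop = 15) {
  int n = (int)genome.size();
  R_xlen_t m = i1.size();
  IntegerMatrix out(m, 2);
  for (R_xlen_t c = 0; c < m; ++c) {
    int a = i1[c], b = i2[c], l = len[c];
    // left extension
    int score = 0, best = 0, ext = 0;
    for (int s = 1; a - s >= 0; ++s) {
      char x = genome[a - s], y = genome[b - s];
      if (x == 'N' || y == 'N') break;
      score += (x == y) ? 1 : -mismatch_penalty;
      if (score > best) { best = score; ext = s; }
      if (best - score > xdrop) break;
    }
    out(c, 0) = ext;
    // right extension (from one past the seed end)
    score = 0; best = 0; ext = 0;
    for (int s = 0; ; ++s) {
      int p1 = a + l + s, p2 = b + l + s;
      if (p2 >= n || p1 >= b) break;
      char x = genome[p1], y = genome[p2];
      if (x == 'N' || y == 'N') break;
      score += (x == y) ? 1 : -mismatch_penalty;
      if (score > best) { best = score; ext = s + 1; }
      if (best - score > xdrop) break;
    }
    out(c, 1) = ext;
  }
  return out;
}

// Pairwise uncorrected distances over the gap-free shared columns of an
// alignment (rows equal length). Returns mismatch proportion and the
// number of shared (both non-gap) columns for every pair.
// [[Rcpp::export]]
List pdist_pairs(CharacterVector aln) {
  int n = aln.size();
  if (n < 2) stop("need at least two sequences");
  std::vector<const char*> s(n);
  int L = LENGTH(STRING_ELT(aln, 0));
  for (int i = 0; i < n; ++i) {
    s[i] = CHAR(STRING_ELT(aln, i));
    if (LENGTH(STRING_ELT(aln, i)) != L) stop("alignment rows differ in length");
  }
  NumericMatrix d(n, n);
  IntegerMatrix shared(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int mm = 0, ok = 0;
      for (int c = 0; c < L; ++c) {
        char x = s[i][c], y = s[j][c];
        if (x == '-' || y == '-' || x == '.' || y == '.') continue;
        ++ok;
        if (x != y) ++mm;
      }
      shared(i, j) = shared(j, i) = ok;
      d(i, j) = d(j, i) = ok > 0 ? (double)mm / ok : NA_REAL;
    }
  }
  return List::create(_["d"] = d, _["shared"] = shared);
}

// Mismatch count between a read and a window of a reference starting at
// 0-based `pos` (may be negative: the read then overhangs the left end).
// Only the overlapping span is compared; returns c(overlap, mismatches).
// [[Rcpp::export]]
IntegerMatrix overlap_mismatches(CharacterVector reads, CharacterVector refs,
                                 IntegerVector pos) {
  R_xlen_t n = reads.size();
  if (refs.size() != n || pos.size() != n) stop("length mismatch");
  IntegerMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *rd = CHAR(STRING_ELT(reads, i));
    const char *rf = CHAR(STRING_ELT(refs, i));
    int lrd = LENGTH(STRING_ELT(reads, i)), lrf = LENGTH(STRING_ELT(refs, i));
    int p = pos[i];
    int from = p < 0 ? -p : 0;            // first read base that overlaps
    int to = std::min(lrd, lrf - p);      // one past last overlapping base
    int ov = 0, mm = 0;
    for (int j = from; j < to; ++j) {
      ++ov;
      if (rd[j] != rf[p + j]) ++mm;
    }
    out(i, 0) = ov;
    out(i, 1) = mm;
  }
  return out;
}
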