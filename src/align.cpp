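// Free-end-gap (ends-free global) pairwise DNA alignment with affine gaps,
// fused with the gap-aware p-distance used throughout the package:
// terminal gaps are free/ignored, each internal gap run counts as one
// difference and one compared event, base-base columns count one event each.
// Scoring: match +1, mismatch -1, gap of length k costs -(2 + k)
// (open -2 plus extend -1 per residue).
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cctype>
using namespace Rcpp;

static const double NEG = -1e18;

static inline int enc_base(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  case 'U': return 3;
  default:  return 4; // ambiguous; always mismatches, never compared in p
  }
}

struct Aln {
  double score;
  int start_i, start_j, end_i, end_j; // 1-based inclusive core span
  std::string ops;                    // 'M','X' (consume a), 'Y' (consume b)
  bool empty;                         // no positive-scoring core found
};

// DP over states M (a[i] vs b[j]), X (a[i] vs gap), Y (gap vs b[j]).
// Free ends: zero-cost entry into M on the first row/column (the prefix of
// one sequence is a free terminal gap) and exit anywhere on the last
// row/column (free trailing gap in the other sequence). With a_global the
// first sequence must be aligned end to end (semi-global: a is a fragment
// of b; only b's overhangs are free), which prevents a short tag from
// matching an unrelated reference via a tiny high-identity core.
static Aln align_core(const std::vector<int>& ea, const std::vector<int>& eb,
                      bool a_global) {
  const int n = static_cast<int>(ea.size()), m = static_cast<int>(eb.size());
  Aln out; out.empty = true; out.score = 0.0;
  out.start_i = out.start_j = out.end_i = out.end_j = 0;
  if (n == 0 || m == 0) return out;
  const int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG), X((n + 1) * w, NEG), Y((n + 1) * w, NEG);
  std::vector<signed char> bM((n + 1) * w, 0), bX((n + 1) * w, 0), bY((n + 1) * w, 0);
  double best = NEG; int bi = 0, bj = 0, bst = 1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * w + j, pd = (i - 1) * w + (j - 1),
                up = (i - 1) * w + j, lf = i * w + (j - 1);
      const double s = (ea[i - 1] == eb[j - 1] && ea[i - 1] < 4) ? 1.0 : -1.0;
      // M: prefer continuing an alignment; a free start (code 0) is only
      // available on the first row/column and only when strictly better.
      double pv = M[pd]; signed char pb = 1;
      if (X[pd] > pv) { pv = X[pd]; pb = 2; }
      if (Y[pd] > pv) { pv = Y[pd]; pb = 3; }
      const bool can_start = a_global ? (i == 1) : (i == 1 || j == 1);
      if (can_start && 0.0 > pv) { pv = 0.0; pb = 0; }
      M[ij] = s + pv; bM[ij] = pb;
      // X: gap in b, consuming a
      double xv = M[up] - 3.0; signed char xb = 1;
      if (X[up] - 1.0 > xv) { xv = X[up] - 1.0; xb = 2; }
      if (Y[up] - 3.0 > xv) { xv = Y[up] - 3.0; xb = 3; }
      X[ij] = xv; bX[ij] = xb;
      // Y: gap in a, consuming b
      double yv = M[lf] - 3.0; signed char yb = 1;
      if (Y[lf] - 1.0 > yv) { yv = Y[lf] - 1.0; yb = 2; }
      if (X[lf] - 3.0 > yv) { yv = X[lf] - 3.0; yb = 3; }
      Y[ij] = yv; bY[ij] = yb;
      if (a_global ? (i == n) : (i == n || j == m)) { // eligible end cell
        if (M[ij] > best) { best = M[ij]; bi = i; bj = j; bst = 1; }
        if (X[ij] > best) { best = X[ij]; bi = i; bj = j; bst = 2; }
        if (Y[ij] > best) { best = Y[ij]; bi = i; bj = j; bst = 3; }
      }
    }
  }
  if (bi == 0) return out; // degenerate
  out.empty = false; out.score = best; out.end_i = bi; out.end_j = bj;
  // traceback (ops collected reversed)
  std::string rev;
  int i = bi, j = bj, st = bst; // 1=M,2=X,3=Y
  while (true) {
    if (st == 1) {
      rev.push_back('M');
      const signed char b = bM[i * w + j];
      --i; --j;
      if (b == 0) break;
      st = b;
    } else if (st == 2) {
      rev.push_back('X');
      st = bX[i * w + j];
      --i;
    } else {
      rev.push_back('Y');
      st = bY[i * w + j];
      --j;
    }
  }
  out.start_i = i + 1; out.start_j = j + 1;
  out.ops.assign(rev.rbegin(), rev.rend());
  return out;
}

// gap-aware p over the alignment core: returns NA if nothing comparable
static double p_from_ops(const Aln& a, const std::vector<int>& ea,
                         const std::vector<int>& eb) {
  if (a.empty) return NA_REAL;
  long events = 0, diffs = 0;
  int i = a.start_i - 1, j = a.start_j - 1;
  char prev = 0;
  for (char op : a.ops) {
    if (op == 'M') {
      if (ea[i] < 4 && eb[j] < 4) {
        ++events;
        if (ea[i] != eb[j]) ++diffs;
      }
      ++i; ++j;
    } else if (op == 'X') {
      if (prev != 'X') { ++events; ++diffs; }
      ++i;
    } else {
      if (prev != 'Y') { ++events; ++diffs; }
      ++j;
    }
    prev = op;
  }
  if (events == 0) return NA_REAL;
  return static_cast<double>(diffs) / static_cast<double>(events);
}

static std::vector<int> enc_seq(const std::string& s) {
  std::vector<int> e(s.size());
  for (size_t k = 0; k < s.size(); ++k) e[k] = enc_base(s[k]);
  return e;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_align_free_end")]]
List cpp_align_free_end(std::string a, std::string b, bool a_global) {
  std::vector<int> ea = enc_seq(a), eb = enc_seq(b);
  Aln al = align_core(ea, eb, a_global);
  if (al.empty) {
    // nothing alignable: represent as full mutual overhang
    std::string aa = a + std::string(b.size(), '-');
    std::string bb = std::string(a.size(), '-') + b;
    return List::create(_["a"] = aa, _["b"] = bb,
                        _["score"] = NA_REAL, _["p"] = NA_REAL);
  }
  std::string aa, bb;
  // skipped prefixes as terminal gaps: a's first, then b's
  aa += a.substr(0, al.start_i - 1);
  bb += std::string(al.start_i - 1, '-');
  aa += std::string(al.start_j - 1, '-');
  bb += b.substr(0, al.start_j - 1);
  int i = al.start_i - 1, j = al.start_j - 1;
  for (char op : al.ops) {
    if (op == 'M')      { aa += a[i++]; bb += b[j++]; }
    else if (op == 'X') { aa += a[i++]; bb += '-'; }
    else                { aa += '-';    bb += b[j++]; }
  }
  // skipped suffixes
  const int na = static_cast<int>(a.size()), nb = static_cast<int>(b.size());
  aa += a.substr(al.end_i);
  bb += std::string(na - al.end_i, '-');
  aa += std::string(nb - al.end_j, '-');
  bb += b.substr(al.end_j);
  return List::create(_["a"] = aa, _["b"] = bb,
                      _["score"] = al.score,
                      _["p"] = p_from_ops(al, ea, eb));
}

//' @noRd
// [[Rcpp::export(name = ".cpp_similarity_batch")]]
NumericVector cpp_similarity_batch(std::string tag, CharacterVector refs) {
  std::vector<int> et = enc_seq(tag);
  const int n = refs.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string r = as<std::string>(refs[k]);
    std::vector<int> er = enc_seq(r);
    Aln al = align_core(et, er, true);
    double p = p_from_ops(al, et, er);
    out[k] = ISNA(p) ? NA_REAL : 1.0 - p;
  }
  return out;
}
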