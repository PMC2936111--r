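// Gap-aware p-distance over pre-aligned rows, and deterministic
// furthest-neighbour (complete-linkage) agglomeration.
//
// Alignment encoding (done in R): 0 = gap, 1..4 = A/C/G/T, 5 = other.
// Rules: comparison is restricted to the column span where both rows are
// inside their non-terminal region; columns where both rows have a gap are
// skipped and do not interrupt gap runs; each maximal internal gap run in
// one row counts as one difference and one compared event; base-base
// columns count one event (a mismatch is one difference); columns with an
// ambiguous base are not compared.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static double p_pair_enc(const int* a, const int* b, int L) {
  int fa = -1, la = -1, fb = -1, lb = -1;
  for (int t = 0; t < L; ++t) {
    if (a[t] > 0) { if (fa < 0) fa = t; la = t; }
    if (b[t] > 0) { if (fb < 0) fb = t; lb = t; }
  }
  if (fa < 0 || fb < 0) return NA_REAL; // an all-gap row
  const int lo = std::max(fa, fb), hi = std::min(la, lb);
  long events = 0, diffs = 0;
  bool runA = false, runB = false;
  for (int t = lo; t <= hi; ++t) {
    const int x = a[t], y = b[t];
    if (x == 0 && y == 0) continue;      // shared gap column: ignored
    if (x == 0) {                        // internal gap in row a
      if (!runA) { ++events; ++diffs; runA = true; }
      runB = false;
    } else if (y == 0) {                 // internal gap in row b
      if (!runB) { ++events; ++diffs; runB = true; }
      runA = false;
    } else {
      runA = runB = false;
      if (x == 5 || y == 5) continue;    // ambiguous base: not compared
      ++events;
      if (x != y) ++diffs;
    }
  }
  if (events == 0) return NA_REAL;
  return static_cast<double>(diffs) / static_cast<double>(events);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_p_pair")]]
double cpp_p_pair(IntegerVector a, IntegerVector b) {
  if (a.size() != b.size()) stop("aligned rows must have equal length");
  return p_pair_enc(a.begin(), b.begin(), a.size());
}

//' @noRd
// [[Rcpp::export(name = ".cpp_p_matrix")]]
NumericMatrix cpp_p_matrix(IntegerMatrix enc, CharacterVector labels) {
  const int n = enc.nrow(), L = enc.ncol();
  // row-major copies for locality
  std::vector<int> rows(static_cast<size_t>(n) * L);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < L; ++t) rows[static_cast<size_t>(i) * L + t] = enc(i, t);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double p = p_pair_enc(&rows[static_cast<size_t>(i) * L],
                                  &rows[static_cast<size_t>(j) * L], L);
      if (ISNA(p))
        stop("incomparable pair: no shared comparable columns between '%s' and '%s'",
             as<std::string>(labels[i]).c_str(), as<std::string>(labels[j]).c_str());
      out(i, j) = out(j, i) = p;
    }
  }
  return out;
}

// ---- complete linkage ------------------------------------------------------

struct PairKey { double d; int r1, r2; };

static inline bool key_less(const PairKey& a, const PairKey& b) {
  if (a.d != b.d) return a.d < b.d;
  if (a.r1 != b.r1) return a.r1 < b.r1;
  return a.r2 < b.r2;
}

// rank: lexicographic rank (1-based) of each item's label; used for
// platform-independent tie-breaking at equal merge heights. A cluster's
// label is its lexicographically smallest member; tied merges are taken in
// lexicographic order of the (smaller label, larger label) pair.
//' @noRd
// [[Rcpp::export(name = ".cpp_complete_linkage")]]
List cpp_complete_linkage(NumericMatrix D, IntegerVector rank) {
  const int n = D.nrow();
  if (n != D.ncol()) stop("distance matrix must be square");
  IntegerMatrix merges(std::max(n - 1, 0), 2);
  NumericVector heights(std::max(n - 1, 0));
  if (n <= 1) return List::create(_["merges"] = merges, _["heights"] = heights);

  std::vector<double> d(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[static_cast<size_t>(i) * n + j] = D(i, j);
  std::vector<bool> active(n, true);
  std::vector<int> minrank(n), repidx(n);
  for (int i = 0; i < n; ++i) { minrank[i] = rank[i]; repidx[i] = i; }

  auto pkey = [&](int i, int j) {
    PairKey k;
    k.d = d[static_cast<size_t>(i) * n + j];
    k.r1 = std::min(minrank[i], minrank[j]);
    k.r2 = std::max(minrank[i], minrank[j]);
    return k;
  };
  std::vector<int> nnJ(n, -1);
  auto rescan = [&](int i) {
    int best = -1; PairKey bk{0.0, 0, 0};
    for (int j = 0; j < n; ++j) {
      if (j == i || !active[j]) continue;
      PairKey k = pkey(i, j);
      if (best < 0 || key_less(k, bk)) { best = j; bk = k; }
    }
    nnJ[i] = best;
  };
  for (int i = 0; i < n; ++i) rescan(i);

  for (int m = 0; m < n - 1; ++m) {
    int bi = -1; PairKey bk{0.0, 0, 0};
    for (int i = 0; i < n; ++i) {
      if (!active[i] || nnJ[i] < 0) continue;
      PairKey k = pkey(i, nnJ[i]);
      if (bi < 0 || key_less(k, bk)) { bi = i; bk = k; }
    }
    int a = bi, b = nnJ[bi];
    // keep the slot whose cluster label is lexicographically smaller
    int keep = (minrank[a] <= minrank[b]) ? a : b;
    int drop = (keep == a) ? b : a;
    merges(m, 0) = repidx[keep] + 1;
    merges(m, 1) = repidx[drop] + 1;
    heights[m] = bk.d;
    for (int j = 0; j < n; ++j) {
      if (!active[j] || j == keep || j == drop) continue;
      const double nd = std::max(d[static_cast<size_t>(keep) * n + j],
                                 d[static_cast<size_t>(drop) * n + j]);
      d[static_cast<size_t>(keep) * n + j] = nd;
      d[static_cast<size_t>(j) * n + keep] = nd;
    }
    active[drop] = false;
    // minrank[keep] already the smaller of the two
    for (int j = 0; j < n; ++j) {
      if (!active[j] || j == keep) continue;
      if (nnJ[j] == keep || nnJ[j] == drop) rescan(j);
      else {
        PairKey k = pkey(j, keep);
        if (key_less(k, pkey(j, nnJ[j]))) nnJ[j] = keep;
      }
    }
    rescan(keep);
  }
  return List::create(_["merges"] = merges, _["heights"] = heights);
}
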