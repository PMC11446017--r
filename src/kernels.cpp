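#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int BIG = INT_MAX / 4;

// Unit-cost edit distance via wavefront expansion: memory is O(d) per
// wavefront (diagonals), never O(|a|*|b|).
// [[Rcpp::export]]
int wfa_edit_cpp(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  const int NEG = -BIG;
  auto extend = [&](int i, int k) {
    int j = i - k;
    while (i < n && j < m && a[i] == b[j]) { ++i; ++j; }
    return i;
  };
  const int kfin = n - m;
  std::vector<int> prev(1);
  prev[0] = extend(0, 0);
  if (kfin == 0 && prev[0] >= n) return 0;
  const int dmax = n + m;
  for (int d = 1; d <= dmax; ++d) {
    std::vector<int> cur(2 * d + 1, NEG);
    for (int k = -d; k <= d; ++k) {
      int best = NEG;
      auto cand = [&](int i) {
        if (i <= NEG + 2) return;
        int j = i - k;
        if (i < 0 || j < 0 || i > n || j > m) return;
        if (i > best) best = i;
      };
      // mismatch (consumes both), gap consuming a, gap consuming b
      if (k >= -(d - 1) && k <= d - 1) cand(prev[k + d - 1] + 1);
      if (k - 1 >= -(d - 1) && k - 1 <= d - 1) cand(prev[k - 1 + d - 1] + 1);
      if (k + 1 >= -(d - 1) && k + 1 <= d - 1) cand(prev[k + 1 + d - 1]);
      if (best == NEG) continue;
      int i = extend(best, k);
      cur[k + d] = i;
      if (k == kfin && i >= n) return d;
    }
    prev.swap(cur);
  }
  return dmax;  // unreachable
}

static inline int min3(int a, int b, int c) {
  return std::min(a, std::min(b, c));
}

// Global affine-gap (Gotoh) alignment of query a against target b.
// A gap of length k costs open + k * extend. Returns optimal cost and,
// optionally, a run-length cigar over ops {=, X, I, D} where I consumes
// the query only and D consumes the target only. Backtracking tie order:
// match/mismatch > D > I, with gap extension preferred over gap opening,
// so results are deterministic.
// [[Rcpp::export]]
List gotoh_cpp(const std::string& a, const std::string& b,
               int mismatch, int gap_open, int gap_extend,
               bool traceback = true) {
  const int n = (int)a.size(), m = (int)b.size();
  const double cells = (double)(n + 1) * (double)(m + 1);
  if (cells > 4e7) stop("alignment problem too large: %d x %d", n, m);
  const size_t W = (size_t)m + 1;
  std::vector<int> M((size_t)(n + 1) * W, BIG), D((size_t)(n + 1) * W, BIG),
      I((size_t)(n + 1) * W, BIG);
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };
  M[at(0, 0)] = 0;
  for (int j = 1; j <= m; ++j) D[at(0, j)] = gap_open + j * gap_extend;
  for (int i = 1; i <= n; ++i) I[at(i, 0)] = gap_open + i * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int sub = (a[i - 1] == b[j - 1]) ? 0 : mismatch;
      M[at(i, j)] = min3(M[at(i - 1, j - 1)], D[at(i - 1, j - 1)],
                         I[at(i - 1, j - 1)]) + sub;
      D[at(i, j)] = std::min(
          std::min(M[at(i, j - 1)], I[at(i, j - 1)]) + gap_open + gap_extend,
          D[at(i, j - 1)] + gap_extend);
      I[at(i, j)] = std::min(
          std::min(M[at(i - 1, j)], D[at(i - 1, j)]) + gap_open + gap_extend,
          I[at(i - 1, j)] + gap_extend);
    }
  }
  const int cost = min3(M[at(n, m)], D[at(n, m)], I[at(n, m)]);
  if (!traceback) return List::create(_["cost"] = cost, _["cigar"] = "");

  std::string ops;
  ops.reserve((size_t)(n + m));
  int i = n, j = m;
  char state;
  if (M[at(i, j)] == cost) state = 'M';
  else if (D[at(i, j)] == cost) state = 'D';
  else state = 'I';
  while (i > 0 || j > 0) {
    if (state == 'M') {
      const int sub = (a[i - 1] == b[j - 1]) ? 0 : mismatch;
      ops.push_back(sub == 0 ? '=' : 'X');
      const int need = M[at(i, j)] - sub;
      --i; --j;
      if (M[at(i, j)] == need) state = 'M';
      else if (D[at(i, j)] == need) state = 'D';
      else state = 'I';
    } else if (state == 'D') {
      ops.push_back('D');
      const int cur = D[at(i, j)];
      --j;
      if (D[at(i, j)] + gap_extend == cur) state = 'D';
      else if (M[at(i, j)] + gap_open + gap_extend == cur) state = 'M';
      else state = 'I';
    } else {
      ops.push_back('I');
      const int cur = I[at(i, j)];
      --i;
      if (I[at(i, j)] + gap_extend == cur) state = 'I';
      else if (M[at(i, j)] + gap_open + gap_extend == cur) state = 'M';
      else state = 'D';
    }
    if (i == 0 && j > 0) state = 'D';
    if (j == 0 && i > 0) state = 'I';
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p);
    cig.push_back(ops[p]);
    p = q;
  }
  return List::create(_["cost"] = cost, _["cigar"] = cig);
}

// Reach-extension feasibility. Query = hap + ext, target = span + ext.
// For each extension length t in 0..|ext|, asks whether some end-to-end
// affine alignment of hap+ext[0:t] vs span+ext[0:t] whose final operation
// is a scored difference (mismatch or gap) costs <= budget. Returns the
// largest feasible t, or -1 if none. The caller doubles |ext| while the
// largest feasible t hits the window edge.
// [[Rcpp::export]]
int reach_extend_cpp(const std::string& hap, const std::string& span,
                     const std::string& ext, int mismatch, int gap_open,
                     int gap_extend, int budget) {
  const std::string q = hap + ext;
  const std::string t = span + ext;
  const int n = (int)q.size(), m = (int)t.size();
  const double cells = (double)(n + 1) * (double)(m + 1);
  if (cells > 4e7) stop("reach problem too large: %d x %d", n, m);
  const size_t W = (size_t)m + 1;
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };
  // states by final operation: Mm (match), Mx (mismatch), D (consumes
  // target), I (consumes query)
  std::vector<int> Mm((size_t)(n + 1) * W, BIG), Mx((size_t)(n + 1) * W, BIG),
      D((size_t)(n + 1) * W, BIG), I((size_t)(n + 1) * W, BIG);
  Mm[at(0, 0)] = 0;
  for (int j = 1; j <= m; ++j) D[at(0, j)] = gap_open + j * gap_extend;
  for (int i = 1; i <= n; ++i) I[at(i, 0)] = gap_open + i * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int diagmin =
          std::min(std::min(Mm[at(i - 1, j - 1)], Mx[at(i - 1, j - 1)]),
                   std::min(D[at(i - 1, j - 1)], I[at(i - 1, j - 1)]));
      if (q[i - 1] == t[j - 1]) {
        Mm[at(i, j)] = diagmin;
      } else if (diagmin < BIG) {
        Mx[at(i, j)] = diagmin + mismatch;
      }
      const int dop = min3(Mm[at(i, j - 1)], Mx[at(i, j - 1)], I[at(i, j - 1)]);
      D[at(i, j)] = std::min(
          dop >= BIG ? BIG : dop + gap_open + gap_extend,
          D[at(i, j - 1)] >= BIG ? BIG : D[at(i, j - 1)] + gap_extend);
      const int iop = min3(Mm[at(i - 1, j)], Mx[at(i - 1, j)], D[at(i - 1, j)]);
      I[at(i, j)] = std::min(
          iop >= BIG ? BIG : iop + gap_open + gap_extend,
          I[at(i - 1, j)] >= BIG ? BIG : I[at(i - 1, j)] + gap_extend);
    }
  }
  const int nh = (int)hap.size(), ns = (int)span.size();
  int emax = -1;
  for (int tt = 0; tt <= (int)ext.size(); ++tt) {
    const int i = nh + tt, j = ns + tt;
    const int best = min3(Mx[at(i, j)], D[at(i, j)], I[at(i, j)]);
    if (best <= budget) emax = tt;
  }
  return emax;
}
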