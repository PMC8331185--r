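#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Gestalt (Ratcliff-Obershelp) sequence similarity: ratio = 2M / T where M
// is the total number of matched tokens found by recursively locating the
// longest common contiguous block and recursing on both flanks, and T is the
// sum of the two sequence lengths. Tie-break for equally long blocks:
// earliest start in the first sequence, then earliest start in the second.
// No junk heuristics. Two independent implementations of the block search
// are provided: a rolling dynamic-programming scan (production) and a naive
// start-anchored brute force (reference oracle used by the tests).

struct Block { int ai, bi, len; };

// -- production block search: DP over block *ends* ---------------------------
static Block longest_block_dp(const std::vector<int>& a, int alo, int ahi,
                              const std::vector<int>& b, int blo, int bhi) {
  Block best{alo, blo, 0};
  int nb = bhi - blo;
  std::vector<int> prev(nb + 1, 0), cur(nb + 1, 0);
  for (int i = alo; i < ahi; ++i) {
    for (int j = blo; j < bhi; ++j) {
      int jj = j - blo + 1;
      if (a[i] == b[j]) {
        cur[jj] = prev[jj - 1] + 1;
        int len = cur[jj];
        int ai = i - len + 1, bi = j - len + 1;
        if (len > best.len ||
            (len == best.len && len > 0 &&
             (ai < best.ai || (ai == best.ai && bi < best.bi)))) {
          best = {ai, bi, len};
        }
      } else {
        cur[jj] = 0;
      }
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), 0);
  }
  return best;
}

// -- reference block search: scan every start pair ---------------------------
static Block longest_block_brute(const std::vector<int>& a, int alo, int ahi,
                                 const std::vector<int>& b, int blo, int bhi) {
  Block best{alo, blo, 0};
  for (int ai = alo; ai < ahi; ++ai) {
    for (int bi = blo; bi < bhi; ++bi) {
      int k = 0;
      while (ai + k < ahi && bi + k < bhi && a[ai + k] == b[bi + k]) ++k;
      if (k > best.len) best = {ai, bi, k};  // ascending scan => earliest ties
    }
  }
  return best;
}

template <Block (*FindBlock)(const std::vector<int>&, int, int,
                             const std::vector<int>&, int, int)>
static int match_total(const std::vector<int>& a, int alo, int ahi,
                       const std::vector<int>& b, int blo, int bhi) {
  if (alo >= ahi || blo >= bhi) return 0;
  Block blk = FindBlock(a, alo, ahi, b, blo, bhi);
  if (blk.len == 0) return 0;
  return blk.len +
    match_total<FindBlock>(a, alo, blk.ai, b, blo, blk.bi) +
    match_total<FindBlock>(a, blk.ai + blk.len, ahi,
                           b, blk.bi + blk.len, bhi);
}

static std::vector<int> to_vec(const IntegerVector& x) {
  return std::vector<int>(x.begin(), x.end());
}

// [[Rcpp::export(name = ".gestalt_ratio_ints")]]
double gestalt_ratio_ints(IntegerVector a, IntegerVector b) {
  if (a.size() == 0 || b.size() == 0)
    stop("gestalt ratio undefined for empty sequences");
  std::vector<int> va = to_vec(a), vb = to_vec(b);
  int m = match_total<longest_block_dp>(va, 0, va.size(), vb, 0, vb.size());
  return 2.0 * m / (va.size() + vb.size());
}

// [[Rcpp::export(name = ".gestalt_ratio_brute_ints")]]
double gestalt_ratio_brute_ints(IntegerVector a, IntegerVector b) {
  if (a.size() == 0 || b.size() == 0)
    stop("gestalt ratio undefined for empty sequences");
  std::vector<int> va = to_vec(a), vb = to_vec(b);
  int m = match_total<longest_block_brute>(va, 0, va.size(),
                                           vb, 0, vb.size());
  return 2.0 * m / (va.size() + vb.size());
}

// [[Rcpp::export(name = ".gestalt_many_ints")]]
NumericVector gestalt_many_ints(List a, List b) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> va = to_vec(a[i]), vb = to_vec(b[i]);
    if (va.empty() || vb.empty())
      stop("gestalt ratio undefined for empty sequences");
    int m = match_total<longest_block_dp>(va, 0, va.size(),
                                          vb, 0, vb.size());
    out[i] = 2.0 * m / (va.size() + vb.size());
  }
  return out;
}

// Exhaustive production-vs-reference comparison over every ordered pair of
// token sequences with lengths 1..max_len on an alphabet of n_tokens.
// Returns (n_pairs, n_mismatch, max_abs_diff).
// [[Rcpp::export(name = ".gestalt_selfcheck")]]
NumericVector gestalt_selfcheck(int max_len, int n_tokens) {
  std::vector<std::vector<int>> seqs;
  for (int len = 1; len <= max_len; ++len) {
    std::vector<int> idx(len, 0);
    while (true) {
      seqs.push_back(idx);
      int pos = len - 1;
      while (pos >= 0 && idx[pos] == n_tokens - 1) { idx[pos] = 0; --pos; }
      if (pos < 0) break;
      ++idx[pos];
    }
  }
  double n_pairs = 0, n_mismatch = 0, max_diff = 0;
  for (size_t i = 0; i < seqs.size(); ++i) {
    for (size_t j = 0; j < seqs.size(); ++j) {
      const std::vector<int>& va = seqs[i];
      const std::vector<int>& vb = seqs[j];
      int m1 = match_total<longest_block_dp>(va, 0, va.size(),
                                             vb, 0, vb.size());
      int m2 = match_total<longest_block_brute>(va, 0, va.size(),
                                                vb, 0, vb.size());
      double r1 = 2.0 * m1 / (va.size() + vb.size());
      double r2 = 2.0 * m2 / (va.size() + vb.size());
      double d = std::abs(r1 - r2);
      if (d > 0) { n_mismatch += 1; if (d > max_diff) max_diff = d; }
      n_pairs += 1;
    }
    Rcpp::checkUserInterrupt();
  }
  return NumericVector::create(n_pairs, n_mismatch, max_diff);
}
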