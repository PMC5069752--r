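// Gestalt (Ratcliff-Obershelp) sequence similarity.
//
// Recursively locates the longest contiguous matching block between two
// strings, then matches the regions to the left and to the right of it.
// The ratio is 2*M/(|a|+|b|) where M is the summed length of all matching
// blocks.  Tie-breaking on equally long blocks prefers the block starting
// earliest in `a`, then earliest in `b`, so results are deterministic and
// order-sensitive in (a, b).

#include <Rcpp.h>
#include <array>
#include <string>
#include <vector>

namespace {

struct Block {
  int ai, bi, size;
};

// Longest matching block of a[alo, ahi) vs b[blo, bhi).
// Dynamic program over end positions: j2len[j] holds the length of the
// longest common suffix of a[..i] and b[..j]; only strictly longer blocks
// displace the incumbent, which yields the earliest-in-a tie-break.
Block longest_match(const std::string &a, const std::string &b,
                    int alo, int ahi, int blo, int bhi) {
  Block best = {alo, blo, 0};
  std::vector<int> j2len(bhi, 0), newj2len(bhi, 0);
  for (int i = alo; i < ahi; ++i) {
    std::fill(newj2len.begin() + blo, newj2len.end(), 0);
    for (int j = blo; j < bhi; ++j) {
      if (b[j] != a[i]) continue;
      int k = (j > blo) ? j2len[j - 1] + 1 : 1;
      newj2len[j] = k;
      if (k > best.size) {
        best.ai = i - k + 1;
        best.bi = j - k + 1;
        best.size = k;
      }
    }
    j2len.swap(newj2len);
  }
  return best;
}

// Total length of all matching blocks (the M in 2*M/(|a|+|b|)).
int total_matched(const std::string &a, const std::string &b) {
  int m = 0;
  std::vector<std::array<int, 4>> queue;
  queue.push_back({0, (int)a.size(), 0, (int)b.size()});
  while (!queue.empty()) {
    auto q = queue.back();
    queue.pop_back();
    Block blk = longest_match(a, b, q[0], q[1], q[2], q[3]);
    if (blk.size == 0) continue;
    m += blk.size;
    if (q[0] < blk.ai && q[2] < blk.bi)
      queue.push_back({q[0], blk.ai, q[2], blk.bi});
    if (blk.ai + blk.size < q[1] && blk.bi + blk.size < q[3])
      queue.push_back({blk.ai + blk.size, q[1], blk.bi + blk.size, q[3]});
  }
  return m;
}

double ratio_one(const std::string &a, const std::string &b) {
  double denom = (double)a.size() + (double)b.size();
  if (denom == 0.0) Rcpp::stop("cannot compare two empty strings");
  return 2.0 * total_matched(a, b) / denom;
}

}  // namespace

// [[Rcpp::export]]
double gestalt_ratio_cpp(std::string a, std::string b) {
  return ratio_one(a, b);
}

// Ratio of one query against many candidates (the hot path of correction).
// [[Rcpp::export]]
Rcpp::NumericVector gestalt_ratios_cpp(std::string a,
                                       Rcpp::CharacterVector b) {
  int n = b.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = ratio_one(a, Rcpp::as<std::string>(b[i]));
  }
  return out;
}
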