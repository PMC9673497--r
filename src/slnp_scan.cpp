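#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Full-space scan of the degenerate nucleotide pattern (SLNP) space.
//
// Input: per-class presence of every exact k-mer in every sequence
// (4^L x n logical matrices). A degenerate pattern is present in a sequence
// iff any exact k-mer in its expansion is present, so per-k-mer sequence
// bitsets let each pattern's per-class presence count be an OR + popcount.
// Only patterns exceeding the frequency-difference cutoff are materialised.

namespace {

struct ScanState {
  int L;
  int n_pos, n_neg, wp, wn;
  std::vector<uint64_t> pos_bits, neg_bits;  // [kmer * words]
  std::vector<uint64_t> acc_pos, acc_neg;
  double min_freq_diff;
  const std::vector<std::vector<int>>* subsets;
  std::vector<int> choice;  // subset index per position
  std::vector<int> masks_out;
  std::vector<int> a_out, c_out;
};

void or_expansions(ScanState& st, int depth, int prefix) {
  if (depth == st.L) {
    const uint64_t* pb = &st.pos_bits[(size_t)prefix * st.wp];
    const uint64_t* nb = &st.neg_bits[(size_t)prefix * st.wn];
    for (int w = 0; w < st.wp; ++w) st.acc_pos[w] |= pb[w];
    for (int w = 0; w < st.wn; ++w) st.acc_neg[w] |= nb[w];
    return;
  }
  const std::vector<int>& bases = (*st.subsets)[st.choice[depth]];
  for (size_t b = 0; b < bases.size(); ++b)
    or_expansions(st, depth + 1, prefix * 4 + bases[b]);
}

void enumerate(ScanState& st, int depth) {
  const int n_sub = 15;
  const bool is_end = (depth == 0) || (depth == st.L - 1);
  const int lim = is_end ? 14 : n_sub;  // last subset (index 14) = full set
  for (int s = 0; s < lim; ++s) {
    st.choice[depth] = s;
    if (depth < st.L - 1) {
      enumerate(st, depth + 1);
    } else {
      std::fill(st.acc_pos.begin(), st.acc_pos.end(), 0ULL);
      std::fill(st.acc_neg.begin(), st.acc_neg.end(), 0ULL);
      or_expansions(st, 0, 0);
      int a = 0, c = 0;
      for (int w = 0; w < st.wp; ++w)
        a += __builtin_popcountll(st.acc_pos[w]);
      for (int w = 0; w < st.wn; ++w)
        c += __builtin_popcountll(st.acc_neg[w]);
      double diff = (double)a / st.n_pos - (double)c / st.n_neg;
      if (diff > st.min_freq_diff) {
        for (int d = 0; d < st.L; ++d) st.masks_out.push_back(st.choice[d]);
        st.a_out.push_back(a);
        st.c_out.push_back(c);
      }
    }
  }
}

}  // namespace

// masks in canonical order (size, then alphabetical); bit A=1,C=2,G=4,T=8
static const int SUBSET_MASKS[15] = {1, 2, 4, 8, 3, 5, 9, 6, 10, 12,
                                     7, 11, 13, 14, 15};

// [[Rcpp::export]]
List slnp_scan_cpp(LogicalMatrix pos, LogicalMatrix neg, int L,
                   double min_freq_diff) {
  int K = pos.nrow();
  if (neg.nrow() != K) stop("k-mer dimension mismatch");
  int expectK = 1;
  for (int i = 0; i < L; ++i) expectK *= 4;
  if (K != expectK) stop("presence matrix rows must equal 4^L");

  // base indices (A=0,C=1,G=2,T=3) per subset
  std::vector<std::vector<int>> subsets(15);
  for (int s = 0; s < 15; ++s)
    for (int b = 0; b < 4; ++b)
      if (SUBSET_MASKS[s] & (1 << b)) subsets[s].push_back(b);

  ScanState st;
  st.L = L;
  st.n_pos = pos.ncol();
  st.n_neg = neg.ncol();
  st.wp = (st.n_pos + 63) / 64;
  st.wn = (st.n_neg + 63) / 64;
  st.pos_bits.assign((size_t)K * st.wp, 0ULL);
  st.neg_bits.assign((size_t)K * st.wn, 0ULL);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < st.n_pos; ++j)
      if (pos(k, j)) st.pos_bits[(size_t)k * st.wp + j / 64] |= 1ULL << (j % 64);
    for (int j = 0; j < st.n_neg; ++j)
      if (neg(k, j)) st.neg_bits[(size_t)k * st.wn + j / 64] |= 1ULL << (j % 64);
  }
  st.acc_pos.assign(st.wp, 0ULL);
  st.acc_neg.assign(st.wn, 0ULL);
  st.min_freq_diff = min_freq_diff;
  st.subsets = &subsets;
  st.choice.assign(L, 0);

  enumerate(st, 0);

  int n_hit = st.a_out.size();
  IntegerMatrix masks(n_hit, L);
  for (int i = 0; i < n_hit; ++i)
    for (int d = 0; d < L; ++d)
      masks(i, d) = SUBSET_MASKS[st.masks_out[(size_t)i * L + d]];
  return List::create(_["masks"] = masks,
                      _["a"] = IntegerVector(st.a_out.begin(), st.a_out.end()),
                      _["c"] = IntegerVector(st.c_out.begin(), st.c_out.end()));
}
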