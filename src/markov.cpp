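#include <Rcpp.h>
using namespace Rcpp;

// Sample a nucleotide sequence (integer-coded 0..3) from an order-r Markov
// chain. `cum` is a 4^r x 4 matrix of cumulative transition probabilities
// (rows indexed by the base-4 code of the length-r context), `init` the
// integer codes of the first r bases, and `u` pre-drawn uniforms of length
// (len - r) so that randomness stays under R's RNG.
// [[Rcpp::export]]
IntegerVector markov_chain_sample(int len, NumericMatrix cum,
                                  IntegerVector init, NumericVector u) {
  int r = init.size();
  if (r < 1) stop("markov order must be >= 1");
  if (len < r) stop("len must be >= markov order");
  if (u.size() < len - r) stop("not enough uniform draws");
  IntegerVector out(len);
  int ctx = 0;
  for (int i = 0; i < r; ++i) {
    out[i] = init[i];
    ctx = ctx * 4 + init[i];
  }
  int keep = cum.nrow() / 4; // 4^(r-1): modulus that drops the oldest base
  for (int i = r; i < len; ++i) {
    double ui = u[i - r];
    int b = 0;
    while (b < 3 && ui > cum(ctx, b)) ++b;
    out[i] = b;
    ctx = (ctx % keep) * 4 + b;
  }
  return out;
}

// Count mismatches of `pat` (codes) aligned at each start position of `subj`
// (codes); returns an integer vector of length (ns - np + 1). Used by the
// spacer matcher's exhaustive interior scan.
// [[Rcpp::export]]
IntegerVector hamming_scan(IntegerVector subj, IntegerVector pat) {
  int ns = subj.size(), np = pat.size();
  if (np > ns) return IntegerVector(0);
  IntegerVector out(ns - np + 1);
  for (int s = 0; s <= ns - np; ++s) {
    int mm = 0;
    for (int j = 0; j < np; ++j) if (subj[s + j] != pat[j]) ++mm;
    out[s] = mm;
  }
  return out;
}
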