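#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Count barcode carriers among cases and controls by a full scan.
// geno: n x p integer matrix of codes {1,2,3}; is_case: length-n logical;
// snps: 1-based column indices; genos: matching genotype codes.
// Returns c(tp, fp) = (cases matching, controls matching).
// [[Rcpp::export]]
IntegerVector match_counts_cpp(const IntegerMatrix& geno,
                               const LogicalVector& is_case,
                               const IntegerVector& snps,
                               const IntegerVector& genos) {
  const int n = geno.nrow(), m = snps.size();
  if (is_case.size() != n) stop("label length does not match genotype rows");
  for (int j = 0; j < m; ++j) {
    if (snps[j] < 1 || snps[j] > geno.ncol())
      stop("barcode SNP index out of range: %d", snps[j]);
  }
  int tp = 0, fp = 0;
  for (int i = 0; i < n; ++i) {
    bool hit = true;
    for (int j = 0; j < m; ++j) {
      if (geno(i, snps[j] - 1) != genos[j]) { hit = false; break; }
    }
    if (hit) { if (is_case[i]) ++tp; else ++fp; }
  }
  return IntegerVector::create(tp, fp);
}

// Bitset cache for fast repeated fitness evaluation: one packed indicator
// per (SNP, genotype) and group; a barcode's carrier counts are then
// AND-reductions with popcount.
struct MaskCache {
  int n_snps, n_words;
  // index [snp * 3 + (geno - 1)]
  std::vector<std::vector<uint64_t>> case_mask, ctrl_mask;
};

static void count_masked(const MaskCache& mc, const IntegerVector& snps,
                         const IntegerVector& genos, int* tp, int* fp) {
  const int m = snps.size(), w = mc.n_words;
  std::vector<uint64_t> acc_case(mc.case_mask[(snps[0] - 1) * 3 + genos[0] - 1]);
  std::vector<uint64_t> acc_ctrl(mc.ctrl_mask[(snps[0] - 1) * 3 + genos[0] - 1]);
  for (int j = 1; j < m; ++j) {
    const std::vector<uint64_t>& ca = mc.case_mask[(snps[j] - 1) * 3 + genos[j] - 1];
    const std::vector<uint64_t>& ct = mc.ctrl_mask[(snps[j] - 1) * 3 + genos[j] - 1];
    for (int k = 0; k < w; ++k) { acc_case[k] &= ca[k]; acc_ctrl[k] &= ct[k]; }
  }
  long tpc = 0, fpc = 0;
  for (int k = 0; k < w; ++k) {
    tpc += __builtin_popcountll(acc_case[k]);
    fpc += __builtin_popcountll(acc_ctrl[k]);
  }
  *tp = (int)tpc; *fp = (int)fpc;
}

// [[Rcpp::export]]
SEXP build_mask_cache(const IntegerMatrix& geno, const LogicalVector& is_case) {
  const int n = geno.nrow(), p = geno.ncol();
  MaskCache* mc = new MaskCache();
  mc->n_snps = p;
  mc->n_words = (n + 63) / 64;
  mc->case_mask.assign(p * 3, std::vector<uint64_t>(mc->n_words, 0));
  mc->ctrl_mask.assign(p * 3, std::vector<uint64_t>(mc->n_words, 0));
  for (int s = 0; s < p; ++s) {
    for (int i = 0; i < n; ++i) {
      int g = geno(i, s);
      if (g < 1 || g > 3) stop("genotype codes must be 1, 2 or 3");
      std::vector<uint64_t>& mask =
        is_case[i] ? mc->case_mask[s * 3 + g - 1] : mc->ctrl_mask[s * 3 + g - 1];
      mask[i >> 6] |= (uint64_t)1 << (i & 63);
    }
  }
  XPtr<MaskCache> ptr(mc, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector masked_counts_cpp(SEXP cache, const IntegerVector& snps,
                                const IntegerVector& genos) {
  XPtr<MaskCache> mc(cache);
  const int m = snps.size();
  for (int j = 0; j < m; ++j) {
    if (snps[j] < 1 || snps[j] > mc->n_snps)
      stop("barcode SNP index out of range: %d", snps[j]);
    if (genos[j] < 1 || genos[j] > 3) stop("genotype codes must be 1, 2 or 3");
  }
  int tp, fp;
  count_masked(*mc, snps, genos, &tp, &fp);
  return IntegerVector::create(tp, fp);
}

// Fitness (controls matching minus cases matching) of a block of genotype
// assignments (rows of `codes`) on one fixed SNP combination.
// [[Rcpp::export]]
IntegerVector masked_block_fitness_cpp(SEXP cache, const IntegerVector& snps,
                                       const IntegerMatrix& codes) {
  XPtr<MaskCache> mc(cache);
  const int g = codes.nrow(), m = snps.size();
  if (codes.ncol() != m) stop("genotype block width does not match SNP count");
  IntegerVector fit(g);
  IntegerVector row(m);
  for (int r = 0; r < g; ++r) {
    for (int j = 0; j < m; ++j) row[j] = codes(r, j);
    int tp, fp;
    count_masked(*mc, snps, row, &tp, &fp);
    fit[r] = fp - tp;
  }
  return fit;
}
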