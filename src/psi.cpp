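#include <Rcpp.h>
using namespace Rcpp;

// Longest contiguous run of identical alleles between two haplotypes
// (already restricted to the focal individual's heterozygous sites, in
// order), scored as the sum of per-site MAF-weighted terms. w0[k] / w1[k]
// are the dampened term values for a match on allele 0 / 1 at site k.
// Ties in run length are broken by the larger score, then by leftmost
// start (the scan keeps the first run unless a later one is strictly
// better).
static double psi_run(const int* x, const int* y, int L,
                      const double* w0, const double* w1) {
  int best_len = 0, run_len = 0;
  double best_sum = 0.0, run_sum = 0.0;
  for (int k = 0; k < L; ++k) {
    if (x[k] == y[k]) {
      ++run_len;
      run_sum += x[k] == 1 ? w1[k] : w0[k];
      if (run_len > best_len || (run_len == best_len && run_sum > best_sum)) {
        best_len = run_len;
        best_sum = run_sum;
      }
    } else {
      run_len = 0;
      run_sum = 0.0;
    }
  }
  return best_sum;
}

// [[Rcpp::export(name = ".psi_window_cpp")]]
double psi_window_cpp(IntegerVector x, IntegerVector y,
                      NumericVector w0, NumericVector w1) {
  int L = x.size();
  if (y.size() != L || w0.size() != L || w1.size() != L)
    stop("psi_window: length mismatch");
  if (L == 0) return 0.0;
  return psi_run(&x[0], &y[0], L, &w0[0], &w1[0]);
}

// For one window compute the psi-star values of both focal haplotype slots
// against every partner: the larger of the psi values against the
// partner's two haplotypes, raised to `power`. hap_t holds the window's
// focal-heterozygous sites as rows and one haplotype per column (sites x
// 2n), so each haplotype is contiguous in memory; column indices are
// 0-based.
// [[Rcpp::export(name = ".psi_star_window_cpp")]]
NumericMatrix psi_star_window_cpp(IntegerMatrix hap_t,
                                  int focalA, int focalB,
                                  IntegerVector partnerA,
                                  IntegerVector partnerB,
                                  NumericVector w0, NumericVector w1,
                                  double power) {
  int L = hap_t.nrow(), P = partnerA.size();
  if (partnerB.size() != P) stop("partner index length mismatch");
  if (w0.size() != L || w1.size() != L) stop("weight length mismatch");
  NumericMatrix out(2, P);
  if (L == 0) return out;
  const int* base = &hap_t(0, 0);
  const int* fa = base + (R_xlen_t)L * focalA;
  const int* fb = base + (R_xlen_t)L * focalB;
  const double* pw0 = &w0[0];
  const double* pw1 = &w1[0];
  for (int j = 0; j < P; ++j) {
    const int* pa = base + (R_xlen_t)L * partnerA[j];
    const int* pb = base + (R_xlen_t)L * partnerB[j];
    double sAA = psi_run(fa, pa, L, pw0, pw1);
    double sAB = psi_run(fa, pb, L, pw0, pw1);
    double sBA = psi_run(fb, pa, L, pw0, pw1);
    double sBB = psi_run(fb, pb, L, pw0, pw1);
    out(0, j) = std::pow(std::max(sAA, sAB), power);
    out(1, j) = std::pow(std::max(sBA, sBB), power);
  }
  return out;
}
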