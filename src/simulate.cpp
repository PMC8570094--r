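// Forward-in-time breeding simulator internals: founder haplotype pools,
// meiosis with per-chromosome Poisson crossovers, and batched gamete
// production.  All randomness comes from R's RNG so set.seed() governs
// reproducibility end to end.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// chromStart[k] .. chromStart[k+1]-1 are the loci of chromosome k (0-based)
std::vector<int> chromStarts(const IntegerVector &chromSnps) {
  std::vector<int> s(chromSnps.size() + 1, 0);
  for (int k = 0; k < chromSnps.size(); ++k) s[k + 1] = s[k] + chromSnps[k];
  return s;
}

// Write one recombined gamete of the parent haplotypes (rows r1, r2 of H)
// into row `out` of G.  Crossover count per chromosome ~ Poisson(rate),
// positions uniform over internal locus boundaries, starting phase fair.
void meiosisInto(const RawMatrix &H, int r1, int r2, RawMatrix &G, int out,
                 const std::vector<int> &starts, double rate) {
  int nChrom = (int)starts.size() - 1;
  for (int k = 0; k < nChrom; ++k) {
    int lo = starts[k], hi = starts[k + 1];  // [lo, hi)
    int L = hi - lo;
    int phase = (unif_rand() < 0.5) ? 0 : 1;
    int ncx = (int)R::rpois(rate);
    if (L <= 1) ncx = 0;
    std::vector<int> cuts(ncx);
    for (int t = 0; t < ncx; ++t)
      cuts[t] = 1 + (int)(unif_rand() * (L - 1));  // boundary before locus cut
    std::sort(cuts.begin(), cuts.end());
    int cur = phase, cidx = 0;
    for (int l = 0; l < L; ++l) {
      while (cidx < ncx && cuts[cidx] == l) { cur ^= 1; ++cidx; }
      G(out, lo + l) = (cur == 0) ? H(r1, lo + l) : H(r2, lo + l);
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".founder_haplotypes")]]
RawMatrix founder_haplotypes(int nFounders, IntegerVector chromSnps,
                             int poolSize, double flipRate, double recombRate) {
  std::vector<int> starts = chromStarts(chromSnps);
  int m = starts.back(), nChrom = (int)chromSnps.size();
  // ancestral haplotype pool, one pool per chromosome
  // pool[k] has poolSize haplotypes of that chromosome's length
  std::vector<std::vector<std::vector<uint8_t> > > pool(nChrom);
  for (int k = 0; k < nChrom; ++k) {
    int L = chromSnps[k];
    std::vector<uint8_t> anc(L);
    for (int l = 0; l < L; ++l) anc[l] = (unif_rand() < 0.5) ? 1 : 0;
    pool[k].assign(poolSize, anc);
    for (int pIdx = 0; pIdx < poolSize; ++pIdx)
      for (int l = 0; l < L; ++l)
        if (unif_rand() < flipRate) pool[k][pIdx][l] ^= 1;
  }
  // each founder gamete: recombine two pool haplotypes once per chromosome
  RawMatrix H(2 * nFounders, m);
  for (int g = 0; g < 2 * nFounders; ++g) {
    for (int k = 0; k < nChrom; ++k) {
      int lo = starts[k];
      int L = chromSnps[k];
      int a = (int)(unif_rand() * poolSize);
      int b = (int)(unif_rand() * poolSize);
      if (a >= poolSize) a = poolSize - 1;
      if (b >= poolSize) b = poolSize - 1;
      int phase = (unif_rand() < 0.5) ? 0 : 1;
      int ncx = (L > 1) ? (int)R::rpois(recombRate) : 0;
      std::vector<int> cuts(ncx);
      for (int t = 0; t < ncx; ++t) cuts[t] = 1 + (int)(unif_rand() * (L - 1));
      std::sort(cuts.begin(), cuts.end());
      int cur = phase, cidx = 0;
      for (int l = 0; l < L; ++l) {
        while (cidx < ncx && cuts[cidx] == l) { cur ^= 1; ++cidx; }
        H(g, lo + l) = (cur == 0) ? pool[k][a][l] : pool[k][b][l];
      }
    }
  }
  return H;
}

// [[Rcpp::export(name = ".meiosis_gamete")]]
RawVector meiosis_gamete(RawVector hap1, RawVector hap2,
                         IntegerVector chromSnps, double recombRate) {
  if (hap1.size() != hap2.size())
    stop("parental haplotypes differ in length");
  std::vector<int> starts = chromStarts(chromSnps);
  if (starts.back() != hap1.size())
    stop("chromosome map does not match haplotype length");
  RawMatrix H(2, hap1.size());
  for (int l = 0; l < hap1.size(); ++l) {
    H(0, l) = hap1[l];
    H(1, l) = hap2[l];
  }
  RawMatrix G(1, hap1.size());
  meiosisInto(H, 0, 1, G, 0, starts, recombRate);
  return G(0, _);
}

// Produce haplotypes for a batch of offspring.  H holds the parents'
// gametes (2 rows per animal); sireRow/damRow give, per offspring, the row
// index (0-based) of each parent's FIRST haplotype row.
// [[Rcpp::export(name = ".make_offspring")]]
RawMatrix make_offspring(RawMatrix H, IntegerVector sireRow,
                         IntegerVector damRow, IntegerVector chromSnps,
                         double recombRate) {
  int nOff = sireRow.size();
  std::vector<int> starts = chromStarts(chromSnps);
  if (starts.back() != H.ncol()) stop("chromosome map mismatch");
  RawMatrix G(2 * nOff, H.ncol());
  for (int o = 0; o < nOff; ++o) {
    meiosisInto(H, sireRow[o], sireRow[o] + 1, G, 2 * o, starts, recombRate);
    meiosisInto(H, damRow[o], damRow[o] + 1, G, 2 * o + 1, starts, recombRate);
  }
  return G;
}

// Allele dosage (0/1/2) of each animal at the given loci (0-based).
// [[Rcpp::export(name = ".dosage_at")]]
IntegerMatrix dosage_at(RawMatrix H, IntegerVector loci) {
  int n = H.nrow() / 2, q = loci.size();
  IntegerMatrix D(n, q);
  for (int j = 0; j < n; ++j)
    for (int t = 0; t < q; ++t)
      D(j, t) = (int)H(2 * j, loci[t]) + (int)H(2 * j + 1, loci[t]);
  return D;
}
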