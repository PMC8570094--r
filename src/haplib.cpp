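// Haplotype library construction: per-block deduplication of observed
// block haplotypes, greedy leader clustering with a Hamming mismatch
// budget, and assembly of the animal-by-haplotype carriage triplets.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

int hammingCapped(const std::string &a, const std::string &b, int cap) {
  int d = 0;
  for (size_t l = 0; l < a.size(); ++l) {
    if (a[l] != b[l] && ++d > cap) return d;
  }
  return d;
}

struct BlockClusters {
  std::vector<std::string> reps;
  std::vector<int> counts;          // occurrences among 2n gametes
  std::vector<int> gameteCluster;   // per gamete, 0-based cluster index
};

// Greedy leader clustering of one block's observed haplotypes: distinct
// strings are processed in descending raw-count order (ties broken by
// lexicographic order); each joins the first cluster whose representative
// is within `maxMismatch` differing sites, else founds a new cluster.
BlockClusters clusterBlock(const std::vector<std::string> &gametes,
                           int maxMismatch) {
  std::unordered_map<std::string, int> countOf;
  for (const auto &s : gametes) ++countOf[s];
  std::vector<std::pair<std::string, int> > distinct(countOf.begin(),
                                                     countOf.end());
  std::sort(distinct.begin(), distinct.end(),
            [](const std::pair<std::string, int> &a,
               const std::pair<std::string, int> &b) {
              if (a.second != b.second) return a.second > b.second;
              return a.first < b.first;
            });
  BlockClusters out;
  std::unordered_map<std::string, int> clusterOf;
  for (const auto &dv : distinct) {
    int assigned = -1;
    for (size_t c = 0; c < out.reps.size(); ++c) {
      if (hammingCapped(dv.first, out.reps[c], maxMismatch) <= maxMismatch) {
        assigned = (int)c;
        break;
      }
    }
    if (assigned < 0) {
      assigned = (int)out.reps.size();
      out.reps.push_back(dv.first);
      out.counts.push_back(0);
    }
    out.counts[assigned] += dv.second;
    clusterOf[dv.first] = assigned;
  }
  out.gameteCluster.reserve(gametes.size());
  for (const auto &s : gametes) out.gameteCluster.push_back(clusterOf[s]);
  return out;
}

}  // namespace

// Cluster the raw haplotypes of a single block (exported for direct use
// and testing).  `gametes` are allele strings over {0,1} of equal length.
// [[Rcpp::export(name = ".cluster_block")]]
List cluster_block(CharacterVector gametes, int maxMismatch) {
  std::vector<std::string> g(gametes.size());
  size_t L = 0;
  for (int i = 0; i < gametes.size(); ++i) {
    g[i] = as<std::string>(gametes[i]);
    if (i == 0) L = g[i].size();
    if (g[i].size() != L) stop("block haplotypes differ in length");
  }
  BlockClusters bc = clusterBlock(g, maxMismatch);
  return List::create(_["representatives"] = wrap(bc.reps),
                      _["counts"] = wrap(bc.counts),
                      _["assignment"] = IntegerVector(bc.gameteCluster.begin(),
                                                      bc.gameteCluster.end()));
}

// Build the whole library from the gamete matrix (2n x m raw 0/1).
// blockStart/blockEnd are 0-based half-open column ranges; maxMismatch is
// per block (floor(tolerance * block length)).  Returns per-block cluster
// tables plus (haplotype, animal) incidence triplets (1-based).
// [[Rcpp::export(name = ".build_library")]]
List build_library(RawMatrix H, IntegerVector blockStart,
                   IntegerVector blockEnd, IntegerVector maxMismatch) {
  int nG = H.nrow();
  if (nG % 2 != 0) stop("haplotype matrix must have two rows per animal");
  int n = nG / 2, nB = blockStart.size();
  for (int g = 0; g < nG; ++g)
    for (int l = 0; l < H.ncol(); ++l)
      if (H(g, l) > 1) stop("alleles must be 0/1");

  std::vector<int> blockOf, clusterCount;
  std::vector<std::string> reps;
  std::vector<int> counts;
  std::vector<int> triI, triJ;
  int offset = 0;
  for (int bIdx = 0; bIdx < nB; ++bIdx) {
    int lo = blockStart[bIdx], hi = blockEnd[bIdx];
    std::vector<std::string> gametes(nG);
    for (int g = 0; g < nG; ++g) {
      std::string s(hi - lo, '0');
      for (int l = lo; l < hi; ++l) s[l - lo] = H(g, l) ? '1' : '0';
      gametes[g] = std::move(s);
    }
    BlockClusters bc = clusterBlock(gametes, maxMismatch[bIdx]);
    for (size_t c = 0; c < bc.reps.size(); ++c) {
      blockOf.push_back(bIdx + 1);
      reps.push_back(bc.reps[c]);
      counts.push_back(bc.counts[c]);
    }
    for (int j = 0; j < n; ++j) {
      int c1 = bc.gameteCluster[2 * j], c2 = bc.gameteCluster[2 * j + 1];
      triI.push_back(offset + c1 + 1);
      triJ.push_back(j + 1);
      if (c2 != c1) {
        triI.push_back(offset + c2 + 1);
        triJ.push_back(j + 1);
      }
    }
    clusterCount.push_back((int)bc.reps.size());
    offset += (int)bc.reps.size();
  }
  return List::create(
      _["block_id"] = wrap(blockOf), _["representative"] = wrap(reps),
      _["count"] = wrap(counts), _["clusters_per_block"] = wrap(clusterCount),
      _["tri_i"] = wrap(triI), _["tri_j"] = wrap(triJ));
}
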