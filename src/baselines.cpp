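// Iterative baseline selection schemes, kept in C++ because run-to-coverage
// on a population of thousands of animals performs thousands of
// weight-update sweeps over the incidence structure.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

std::vector<std::vector<int> > colsFromRows(const List &rowIdx, int nC) {
  std::vector<std::vector<int> > cols(nC);
  for (int i = 0; i < rowIdx.size(); ++i) {
    IntegerVector r = rowIdx[i];
    for (int j : r) cols[j].push_back(i);
  }
  return cols;
}

}  // namespace

// IWS-style selection: animal weights are sums of inverse frequencies of
// the uncovered haplotypes they carry; one animal per round (ties to the
// lower column index), its haplotype rows then count as covered.
// budget < 0 means run until all rows are covered.
// [[Rcpp::export(name = ".iws_run")]]
List iws_run(List rowIdx, int nC, NumericVector h, int budget) {
  int nR = rowIdx.size();
  std::vector<std::vector<int> > cols = colsFromRows(rowIdx, nC);
  std::vector<double> w(nC, 0.0);
  std::vector<int8_t> covered(nR, 0), taken(nC, 0);
  std::vector<std::vector<int> > rows(nR);
  for (int i = 0; i < nR; ++i) {
    IntegerVector r = rowIdx[i];
    rows[i].assign(r.begin(), r.end());
    for (int j : rows[i]) w[j] += 1.0 / h[i];
  }
  int uncovered = nR;
  std::vector<int> picks;
  std::vector<double> pickWeight;
  while (uncovered > 0 && (budget < 0 || (int)picks.size() < budget)) {
    // weights within a relative 1e-9 of the maximum count as tied and the
    // lowest column index wins, so that independent recomputations of the
    // same weights (in any summation order) select identically
    double wmax = 0.0;
    for (int j = 0; j < nC; ++j)
      if (!taken[j] && w[j] > wmax) wmax = w[j];
    if (wmax <= 1e-12) break;  // nothing uncovered is carried
    double thr = wmax - 1e-9 * std::max(1.0, wmax);
    int best = -1;
    double bw = 0.0;
    for (int j = 0; j < nC; ++j)
      if (!taken[j] && w[j] >= thr) { best = j; bw = w[j]; break; }
    taken[best] = 1;
    picks.push_back(best + 1);
    pickWeight.push_back(bw);
    for (int i : cols[best]) {
      if (covered[i]) continue;
      covered[i] = 1;
      --uncovered;
      for (int j : rows[i]) w[j] -= 1.0 / h[i];
    }
  }
  return List::create(_["selected"] = wrap(picks),
                      _["weights"] = wrap(pickWeight),
                      _["uncovered"] = uncovered);
}

// Greedy set cover: repeatedly take the animal carrying the most uncovered
// haplotypes (ties to the lower column index) until all are covered.
// [[Rcpp::export(name = ".greedy_cover_run")]]
List greedy_cover_run(List rowIdx, int nC) {
  int nR = rowIdx.size();
  std::vector<std::vector<int> > cols = colsFromRows(rowIdx, nC);
  std::vector<std::vector<int> > rows(nR);
  std::vector<int> gain(nC, 0);
  for (int i = 0; i < nR; ++i) {
    IntegerVector r = rowIdx[i];
    if (r.size() == 0) stop("haplotype row %d has no carrier", i + 1);
    rows[i].assign(r.begin(), r.end());
    for (int j : rows[i]) ++gain[j];
  }
  std::vector<int8_t> covered(nR, 0), taken(nC, 0);
  int uncovered = nR;
  std::vector<int> picks;
  while (uncovered > 0) {
    int best = -1, bg = 0;
    for (int j = 0; j < nC; ++j)
      if (!taken[j] && gain[j] > bg) { bg = gain[j]; best = j; }
    if (best < 0) stop("uncoverable rows remain");
    taken[best] = 1;
    picks.push_back(best + 1);
    for (int i : cols[best]) {
      if (covered[i]) continue;
      covered[i] = 1;
      --uncovered;
      for (int j : rows[i]) --gain[j];
    }
  }
  return List::create(_["selected"] = wrap(picks));
}

// Walk columns in the given order (1-based) and report how many are needed
// before every row is covered (0 if the full order never covers them all),
// plus the running coverage after each pick.
// [[Rcpp::export(name = ".coverage_prefix")]]
List coverage_prefix(List rowIdx, int nC, IntegerVector order) {
  int nR = rowIdx.size();
  std::vector<std::vector<int> > cols = colsFromRows(rowIdx, nC);
  std::vector<int8_t> covered(nR, 0);
  int uncovered = nR, needed = 0;
  IntegerVector coveredAfter(order.size());
  for (int t = 0; t < order.size(); ++t) {
    int j = order[t] - 1;
    for (int i : cols[j])
      if (!covered[i]) { covered[i] = 1; --uncovered; }
    coveredAfter[t] = nR - uncovered;
    if (uncovered == 0 && needed == 0) needed = t + 1;
  }
  return List::create(_["needed"] = needed, _["covered_after"] = coveredAfter);
}
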