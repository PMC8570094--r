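// Exact 0-1 branch-and-bound solvers for the two selection programs:
//   min-cover:  min 1'x  s.t. A x >= b, x binary
//   budget:     max c'x  s.t. 1'x <= n_max, A x <= r_max (row-wise), x binary
// A is a sparse binary haplotype-by-animal incidence matrix, passed as
// row-wise index lists.  Both solvers carry an optimality certificate:
// `proven` is true only when the search tree was exhausted.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct CoverInstance {
  int nR = 0, nC = 0;
  std::vector<std::vector<int> > rows;  // row -> column indices
  std::vector<std::vector<int> > cols;  // column -> row indices
  std::vector<int> b;                   // per-row coverage requirement
};

// ---- state shared by the min-cover search -------------------------------

struct CoverState {
  const CoverInstance *inst;
  std::vector<int8_t> colState;  // 0 free, 1 included, -1 excluded
  std::vector<int> d;            // residual demand per row (b_i - included)
  std::vector<int> freeCnt;      // free columns per row
  std::vector<int> removedRow;   // 1 if row dropped by root dominance
  int includedCount = 0;
  // trail for backtracking: positive j => col j was included, ~j => excluded
  std::vector<int> trail;

  explicit CoverState(const CoverInstance &I)
      : inst(&I), colState(I.nC, 0), d(I.b), freeCnt(I.nR, 0),
        removedRow(I.nR, 0) {
    for (int i = 0; i < I.nR; ++i) freeCnt[i] = (int)I.rows[i].size();
  }

  bool rowActive(int i) const { return !removedRow[i] && d[i] > 0; }

  void includeCol(int j, bool record = true) {
    colState[j] = 1;
    ++includedCount;
    for (int i : inst->cols[j]) { --freeCnt[i]; --d[i]; }
    if (record) trail.push_back(j + 1);
  }
  void excludeCol(int j, bool record = true) {
    colState[j] = -1;
    for (int i : inst->cols[j]) --freeCnt[i];
    if (record) trail.push_back(-(j + 1));
  }
  void undoTo(size_t mark) {
    while (trail.size() > mark) {
      int t = trail.back();
      trail.pop_back();
      if (t > 0) {
        int j = t - 1;
        colState[j] = 0;
        --includedCount;
        for (int i : inst->cols[j]) { ++freeCnt[i]; ++d[i]; }
      } else {
        int j = -t - 1;
        colState[j] = 0;
        for (int i : inst->cols[j]) ++freeCnt[i];
      }
    }
  }

  // Unit propagation over rows touched by recent moves.  Returns false on
  // infeasibility (some active row cannot meet its demand).
  bool propagate(std::vector<int> &pending) {
    while (!pending.empty()) {
      int i = pending.back();
      pending.pop_back();
      if (!rowActive(i)) continue;
      if (freeCnt[i] < d[i]) return false;
      if (freeCnt[i] == d[i]) {
        // every remaining carrier of this haplotype must be selected
        std::vector<int> toInc;
        for (int j : inst->rows[i])
          if (colState[j] == 0) toInc.push_back(j);
        for (int j : toInc) {
          if (colState[j] != 0) continue;
          includeCol(j);
          for (int r : inst->cols[j]) pending.push_back(r);
        }
      }
    }
    return true;
  }
};

// Greedy primal cover of the residual problem; returns completion columns
// (on top of currently included ones) or empty+fail if infeasible.
bool greedyComplete(CoverState &st, std::vector<int> &picked) {
  const CoverInstance &I = *st.inst;
  std::vector<int> dd(st.d);
  std::vector<int> gain(I.nC, 0);
  std::vector<int8_t> used(I.nC, 0);
  long active = 0;
  for (int i = 0; i < I.nR; ++i)
    if (st.rowActive(i) && dd[i] > 0) {
      ++active;
      for (int j : I.rows[i])
        if (st.colState[j] == 0) ++gain[j];
    }
  while (active > 0) {
    int best = -1, bestGain = 0;
    for (int j = 0; j < I.nC; ++j)
      if (st.colState[j] == 0 && !used[j] && gain[j] > bestGain) {
        best = j;
        bestGain = gain[j];
      }
    if (best < 0) return false;
    used[best] = 1;
    picked.push_back(best);
    for (int i : I.cols[best]) {
      if (st.removedRow[i] || dd[i] <= 0) continue;
      --dd[i];
      if (dd[i] == 0) {
        --active;
        for (int j : I.rows[i])
          if (st.colState[j] == 0 && !used[j]) --gain[j];
      }
    }
  }
  // prune redundant picks: walk backwards keeping a running coverage count
  std::vector<int> cov(I.nR, 0);
  for (int j : picked)
    for (int i : I.cols[j]) ++cov[i];
  for (size_t k = picked.size(); k-- > 0;) {
    int j = picked[k];
    bool redundant = true;
    for (int i : I.cols[j])
      if (st.rowActive(i) && cov[i] - 1 < st.d[i]) { redundant = false; break; }
    if (redundant) {
      for (int i : I.cols[j]) --cov[i];
      picked[k] = -1;
    }
  }
  picked.erase(std::remove(picked.begin(), picked.end(), -1), picked.end());
  return true;
}

// Dual-feasible greedy lower bound on the residual cover size: build y >= 0
// with sum_i a_ij y_i <= 1 for every free column; then sum_i d_i y_i is a
// valid LP lower bound.
double dualBound(const CoverState &st) {
  const CoverInstance &I = *st.inst;
  std::vector<double> slack(I.nC, 1.0);
  std::vector<int> order;
  order.reserve(I.nR);
  for (int i = 0; i < I.nR; ++i)
    if (st.rowActive(i)) order.push_back(i);
  std::sort(order.begin(), order.end(), [&](int a, int bb) {
    if (st.freeCnt[a] != st.freeCnt[bb]) return st.freeCnt[a] < st.freeCnt[bb];
    return a < bb;
  });
  double lb = 0.0;
  for (int i : order) {
    double y = 1.0;
    for (int j : I.rows[i])
      if (st.colState[j] == 0) y = std::min(y, slack[j]);
    if (y <= 0.0) continue;
    lb += (double)st.d[i] * y;
    for (int j : I.rows[i])
      if (st.colState[j] == 0) slack[j] -= y;
  }
  return lb;
}

struct CoverSearch {
  CoverState *st;
  long nodeLimit, nodes = 0;
  bool proven = true;
  int incumbentVal;
  std::vector<int8_t> incumbent;  // colState snapshot of best solution

  void saveIncumbent(const std::vector<int> &extra) {
    incumbent.assign(st->colState.begin(), st->colState.end());
    for (int j : extra) incumbent[j] = 1;
  }

  void dfs() {
    if (++nodes > nodeLimit) { proven = false; return; }
    if (nodes % 4096 == 0) Rcpp::checkUserInterrupt();
    const CoverInstance &I = *st->inst;
    // bound
    double lb = dualBound(*st);
    if (st->includedCount + (int)std::ceil(lb - 1e-9) >= incumbentVal) return;
    // pick branching row: active row with fewest free columns
    int bestRow = -1, bestFree = INT32_MAX;
    for (int i = 0; i < I.nR; ++i)
      if (st->rowActive(i) && st->freeCnt[i] < bestFree) {
        bestFree = st->freeCnt[i];
        bestRow = i;
      }
    if (bestRow < 0) {  // feasible: all demands met
      if (st->includedCount < incumbentVal) {
        incumbentVal = st->includedCount;
        saveIncumbent(std::vector<int>());
      }
      return;
    }
    // periodically try to tighten the incumbent by greedy completion
    if (nodes % 64 == 1) {
      std::vector<int> extra;
      if (greedyComplete(*st, extra)) {
        int val = st->includedCount + (int)extra.size();
        if (val < incumbentVal) {
          incumbentVal = val;
          saveIncumbent(extra);
        }
      }
      if (st->includedCount + (int)std::ceil(lb - 1e-9) >= incumbentVal)
        return;
    }
    // branch: one child per free column that can cover bestRow, excluding
    // previously tried ones (exhaustive disjunction)
    std::vector<int> cands;
    for (int j : I.rows[bestRow])
      if (st->colState[j] == 0) cands.push_back(j);
    // order by descending residual coverage
    std::vector<int> cov(cands.size(), 0);
    for (size_t k = 0; k < cands.size(); ++k)
      for (int i : I.cols[cands[k]])
        if (st->rowActive(i)) ++cov[k];
    std::vector<size_t> idx(cands.size());
    for (size_t k = 0; k < idx.size(); ++k) idx[k] = k;
    std::sort(idx.begin(), idx.end(), [&](size_t a, size_t bb) {
      if (cov[a] != cov[bb]) return cov[a] > cov[bb];
      return cands[a] < cands[bb];
    });
    size_t outerMark = st->trail.size();
    for (size_t t = 0; t < idx.size(); ++t) {
      int j = cands[idx[t]];
      if (st->colState[j] == -1) continue;  // this disjunct already infeasible
      if (st->colState[j] == 1) {
        // a propagation forced j in: this disjunct IS the current state and
        // all later ones (which exclude j) are infeasible
        dfs();
        break;
      }
      size_t mark = st->trail.size();
      std::vector<int> pending;
      st->includeCol(j);
      for (int r : I.cols[j]) pending.push_back(r);
      bool ok = st->propagate(pending);
      if (ok && st->includedCount < incumbentVal) dfs();
      st->undoTo(mark);
      if (!proven && nodes > nodeLimit) break;
      // exclude j for remaining children of this disjunction
      std::vector<int> pend2;
      st->excludeCol(j);
      for (int r : I.cols[j]) pend2.push_back(r);
      if (!st->propagate(pend2)) break;  // no child with j excluded is feasible
    }
    st->undoTo(outerMark);
  }
};

CoverInstance buildInstance(const List &rowIdx, int nC,
                            const IntegerVector &b) {
  CoverInstance I;
  I.nR = rowIdx.size();
  I.nC = nC;
  I.rows.resize(I.nR);
  I.cols.resize(nC);
  I.b.assign(b.begin(), b.end());
  for (int i = 0; i < I.nR; ++i) {
    IntegerVector r = rowIdx[i];
    I.rows[i].assign(r.begin(), r.end());
    for (int j : I.rows[i]) I.cols[j].push_back(i);
  }
  return I;
}

// Root reductions for b-covering, iterated to a fixpoint:
//   (a) demand forcing (freeCnt == d => include all free carriers),
//   (b) row dominance: free-support(i) subset of free-support(k) with
//       d_i >= d_k  =>  row k is implied and dropped,
//   (c) column dominance (only among rows with demand 1): if the active
//       rowset of free column j is a subset of free column l's, some
//       optimal solution avoids j, so j is excluded.
// Returns false on infeasibility.
bool rootReduce(const CoverInstance &I, CoverState &st) {
  {
    std::vector<int> pending;
    for (int i = 0; i < I.nR; ++i)
      if (st.rowActive(i)) pending.push_back(i);
    if (!st.propagate(pending)) return false;
  }
  bool changed = true;
  while (changed) {
    changed = false;
    // --- filtered adjacency over the live submatrix
    std::vector<std::vector<int> > rowsF(I.nR), colsF(I.nC);
    for (int i = 0; i < I.nR; ++i) {
      if (!st.rowActive(i)) continue;
      for (int j : I.rows[i])
        if (st.colState[j] == 0) {
          rowsF[i].push_back(j);
          colsF[j].push_back(i);
        }
    }
    // --- row dominance via the least-degree pivot column of each row
    std::vector<int> order;
    for (int i = 0; i < I.nR; ++i)
      if (st.rowActive(i)) order.push_back(i);
    std::sort(order.begin(), order.end(), [&](int a, int c) {
      return rowsF[a].size() < rowsF[c].size();
    });
    std::vector<int8_t> mark(I.nC, 0);
    for (int i : order) {
      if (st.removedRow[i] || !st.rowActive(i)) continue;
      for (int j : rowsF[i]) mark[j] = 1;
      int pivot = rowsF[i][0];
      for (int j : rowsF[i])
        if (colsF[j].size() < colsF[pivot].size()) pivot = j;
      for (int k : colsF[pivot]) {
        if (k == i || st.removedRow[k] || !st.rowActive(k)) continue;
        if (rowsF[k].size() < rowsF[i].size() || st.d[i] < st.d[k]) continue;
        size_t hit = 0;
        for (int j : rowsF[k])
          if (mark[j]) ++hit;
        if (hit == rowsF[i].size() &&
            (rowsF[k].size() > rowsF[i].size() || k > i)) {
          st.removedRow[k] = 1;
          changed = true;
        }
      }
      for (int j : rowsF[i]) mark[j] = 0;
    }
    // --- rebuild column rowsets after row removals
    for (int j = 0; j < I.nC; ++j) colsF[j].clear();
    for (int i = 0; i < I.nR; ++i) {
      if (!st.rowActive(i)) continue;
      for (int j : rowsF[i])
        if (st.colState[j] == 0) colsF[j].push_back(i);
    }
    // --- column dominance (safe only when dominated rows all have d == 1)
    std::vector<int> corder;
    for (int j = 0; j < I.nC; ++j) {
      if (st.colState[j] != 0) continue;
      if (colsF[j].empty()) {  // covers nothing active
        st.excludeCol(j, false);
        changed = true;
        continue;
      }
      corder.push_back(j);
    }
    std::sort(corder.begin(), corder.end(), [&](int a, int c) {
      return colsF[a].size() < colsF[c].size();
    });
    std::vector<int8_t> rmark(I.nR, 0);
    for (int j : corder) {
      if (st.colState[j] != 0) continue;
      bool allUnit = true;
      for (int i : colsF[j])
        if (st.d[i] != 1) { allUnit = false; break; }
      if (!allUnit) continue;
      for (int i : colsF[j]) rmark[i] = 1;
      int pivot = colsF[j][0];
      for (int i : colsF[j])
        if (rowsF[i].size() < rowsF[pivot].size()) pivot = i;
      for (int l : rowsF[pivot]) {
        if (l == j || st.colState[l] != 0) continue;
        if (colsF[l].size() < colsF[j].size()) continue;
        size_t hit = 0;
        for (int i : colsF[l])
          if (rmark[i]) ++hit;
        if (hit == colsF[j].size() &&
            (colsF[l].size() > colsF[j].size() || l > j)) {
          st.excludeCol(j, false);
          changed = true;
          break;
        }
      }
      for (int i : colsF[j]) rmark[i] = 0;
    }
    // --- re-propagate demand forcing after exclusions
    std::vector<int> pending;
    for (int i = 0; i < I.nR; ++i)
      if (st.rowActive(i)) pending.push_back(i);
    size_t before = st.trail.size();
    if (!st.propagate(pending)) return false;
    if (st.trail.size() != before) changed = true;
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".bb_min_cover")]]
List bb_min_cover(List rowIdx, int nC, IntegerVector b, IntegerVector forced,
                  double nodeLimit) {
  CoverInstance I = buildInstance(rowIdx, nC, b);
  for (int i = 0; i < I.nR; ++i) {
    if (I.rows[i].empty())
      stop("haplotype row %d has no carrier: covering is infeasible", i + 1);
    if (I.b[i] > (int)I.rows[i].size())
      stop("row %d requires coverage %d but has only %d carriers", i + 1,
           I.b[i], (int)I.rows[i].size());
  }
  CoverState st(I);
  // forced columns first
  std::vector<int> pending;
  for (int f : forced) {
    if (st.colState[f] == 0) {
      st.includeCol(f, false);
      for (int r : I.cols[f]) pending.push_back(r);
    }
  }
  if (!st.propagate(pending))
    stop("problem infeasible after applying forced selections");
  if (!rootReduce(I, st)) stop("problem infeasible at root");
  st.trail.clear();  // root fixings are permanent

  CoverSearch search;
  search.st = &st;
  search.nodeLimit = (long)nodeLimit;
  // initial incumbent from greedy
  std::vector<int> extra;
  if (!greedyComplete(st, extra)) stop("greedy completion failed: infeasible");
  search.incumbentVal = st.includedCount + (int)extra.size();
  search.saveIncumbent(extra);
  search.dfs();

  std::vector<int> sel;
  for (int j = 0; j < I.nC; ++j)
    if (search.incumbent[j] == 1) sel.push_back(j + 1);
  return List::create(_["selected"] = wrap(sel),
                      _["objective"] = (double)search.incumbentVal,
                      _["proven_optimal"] = search.proven,
                      _["nodes"] = (double)search.nodes);
}

// ---- budgeted maximum-coverage solver -----------------------------------

namespace {

struct BudgetSearch {
  int nC, nMax;
  const std::vector<std::vector<int> > *cols;  // col -> rows
  std::vector<int> rmax;                       // per-row cap
  std::vector<double> c;                       // weights, in original col order
  std::vector<int> order;                      // free cols sorted by c desc
  std::vector<double> suffix;                  // suffix[k] = sum of top (nMax)
  std::vector<int> usage;
  std::vector<int8_t> chosen;
  std::vector<int> current;
  std::vector<int> best;
  double bestVal = -1.0, baseVal = 0.0;
  long nodeLimit, nodes = 0;
  bool proven = true;

  bool canTake(int j) const {
    for (int i : (*cols)[j])
      if (usage[i] + 1 > rmax[i]) return false;
    return true;
  }
  void take(int j) {
    for (int i : (*cols)[j]) ++usage[i];
    current.push_back(j);
  }
  void drop(int j) {
    for (int i : (*cols)[j]) --usage[i];
    current.pop_back();
  }

  double upperBound(size_t k, int slots, double val) const {
    double ub = val;
    for (size_t t = k; t < order.size() && slots > 0; ++t, --slots)
      ub += c[order[t]];
    return ub;
  }

  void record(double val) {
    if (val > bestVal + 1e-12) {
      bestVal = val;
      best = current;
    }
  }

  void dfs(size_t k, int slots, double val) {
    if (++nodes > nodeLimit) { proven = false; return; }
    if (nodes % 8192 == 0) Rcpp::checkUserInterrupt();
    record(val);
    if (slots == 0 || k >= order.size()) return;
    if (upperBound(k, slots, val) <= bestVal + 1e-12) return;
    int j = order[k];
    if (canTake(j)) {
      take(j);
      dfs(k + 1, slots - 1, val + c[j]);
      drop(j);
    }
    if (!proven) return;
    dfs(k + 1, slots, val);
  }
};

}  // namespace

// [[Rcpp::export(name = ".bb_budget")]]
List bb_budget(List rowIdx, int nC, NumericVector c, int nMax,
               IntegerVector rmax, IntegerVector forced, double nodeLimit) {
  int nR = rowIdx.size();
  std::vector<std::vector<int> > cols(nC);
  for (int i = 0; i < nR; ++i) {
    IntegerVector r = rowIdx[i];
    for (int j : r) cols[j].push_back(i);
  }
  BudgetSearch S;
  S.nC = nC;
  S.cols = &cols;
  S.rmax.assign(rmax.begin(), rmax.end());
  S.c.assign(c.begin(), c.end());
  S.usage.assign(nR, 0);
  S.chosen.assign(nC, 0);
  S.nodeLimit = (long)nodeLimit;

  // forced selections consume budget and row caps up front
  double forcedVal = 0.0;
  std::vector<int8_t> isForced(nC, 0);
  for (int f : forced) {
    if (isForced[f]) continue;
    isForced[f] = 1;
    if (!S.canTake(f))
      stop("forced animal %d violates a redundancy cap", f + 1);
    S.take(f);
    forcedVal += S.c[f];
  }
  if ((int)S.current.size() > nMax)
    stop("forced set larger than the budget n_max");
  int slots = nMax - (int)S.current.size();

  for (int j = 0; j < nC; ++j)
    if (!isForced[j]) S.order.push_back(j);
  std::sort(S.order.begin(), S.order.end(), [&](int a, int bb) {
    if (S.c[a] != S.c[bb]) return S.c[a] > S.c[bb];
    return a < bb;
  });
  S.bestVal = -1.0;
  S.nMax = nMax;
  S.dfs(0, slots, forcedVal);

  std::vector<int> sel;
  for (int j : S.best) sel.push_back(j + 1);
  std::sort(sel.begin(), sel.end());
  return List::create(_["selected"] = wrap(sel), _["objective"] = S.bestVal,
                      _["proven_optimal"] = S.proven,
                      _["nodes"] = (double)S.nodes);
}
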