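---
title: "Allocating sequencing resources with exact integer programming"
author: "seqpick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allocating sequencing resources with exact integer programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqpick)
```

## The problem

Livestock breeding programs routinely genotype whole populations with
low-density SNP arrays, but can afford to whole-genome sequence only a
small subset of animals. If every haplotype segregating in the population
is carried by at least one sequenced animal, sequence variants can in
principle be imputed into every other animal from the array data. The
practical question is therefore *which* animals to sequence:

1. What is the smallest set of animals that jointly carries every
   haplotype in the population?
2. Given a fixed budget of `n_max` animals, which selection carries the
   largest share of the *common* haplotypes?

Both questions are set-cover-type problems over a binary incidence
structure and are solved here exactly, with optimality certificates, by
branch and bound.

## The haplotype library

Phased genotypes (two allele vectors per animal) are cut into
non-overlapping blocks of `block_length` consecutive SNPs per chromosome
(default 100; a final shorter block takes the remainder, and blocks never
span chromosomes). Within a block, observed haplotypes that differ at no
more than `floor(mismatch * L)` sites are merged by greedy leader
clustering: distinct raw haplotypes are processed in descending raw-count
order (ties broken lexicographically), each joining the first cluster
whose representative is within the mismatch budget, else founding a new
cluster. The default tolerance of 10% is inclusive: at `L = 100`, a
10-site difference merges and an 11-site difference does not.

Two numerical conventions matter downstream:

* **Frequencies use gametes as denominator.** A haplotype observed `k`
  times among the `2n` phased gametes has frequency `k / (2n)`. The 1%
  *common* threshold is also inclusive: frequency 0.010 is retained,
  0.009 is excluded.
* **Carriage is binary.** The incidence matrix `A` has `a[i, j] = 1` when
  animal `j` carries haplotype `i` on at least one chromosome copy;
  homozygous carriers still contribute 1. Clustering order is fixed, so
  the library is deterministic; raising the tolerance can only decrease
  the number of clusters.

Unphased or missing genotypes are rejected rather than imputed: the
method presumes a phased low-density haplotype library as input.

## The two integer programs

With `x_j` indicating selection of animal `j`:

**Minimum cover.** Minimize `sum_j x_j` subject to `A x >= b`, `x`
binary. The default `b = 1` requires every haplotype to have a selected
carrier; raising `b_i` on rare rows demands multiple distinct carriers
(useful when redundant coverage of rare haplotypes is wanted for
imputation), and a `forced_in` set supports animals whose sequence
already exists.

**Budgeted coverage.** With haplotype frequencies `h`, each animal gets
weight `c_j = sum_i h_i a_ij` — the summed frequencies of the haplotypes
it carries. Maximize `sum_j c_j x_j` subject to `sum_j x_j <= n_max` and,
per haplotype, `sum_j a_ij x_j <= r_max_i`. The redundancy cap `r_max`
prevents spending the budget on many carriers of the same common
haplotype.

Both are solved by an exact 0-1 branch and bound implemented in the
package (there is no external MILP dependency). The covering solver first
reduces the instance at the root — demand propagation (a haplotype with
exactly as many remaining carriers as its residual demand forces them all
in), duplicate and subset row dominance, and column dominance among
unit-demand rows — iterated to a fixpoint, then searches with a
dual-feasible greedy lower bound and row-disjunction branching. The
budget solver orders animals by weight and prunes with a top-`k` suffix
bound. Each result carries `proven_optimal`: a node-budget exhaustion
returns the incumbent with `proven_optimal = FALSE` and a warning, never
a silent approximation. On breeding-population instances the root
reductions typically solve the covering problem almost entirely; all
solutions are re-verifiable with `validate_result()`, which recomputes
coverage and objective from the raw matrix.

## The batched iterative heuristic

Solving the budgeted program for `n_max = 100` with a small `r_max` in
one shot is slow at population scale, so `iterative_budget_select()`
selects `batch = 2` animals per round (with `r_max = 2`): each round
recomputes the weights on the surviving submatrix, solves the two-animal
program exactly, then deletes the selected animals and every haplotype
row they carry. Frequencies `h` are never recomputed — later-round
weights simply omit the already-covered rows. With `batch = r_max = 2`
the cap cannot bind inside a round (two animals cover a row at most
twice); diversity across rounds is enforced by row removal instead. The
cap binds, and the solver works, whenever `batch > r_max`. Odd budgets
end with a one-animal round; `batch = 1` reproduces a
single-animal-updating scheme, and `batch = total_budget` is the exact
one-shot solve.

At desk scales the 100-animal budget can outlive the common rows: once
every common haplotype is covered, remaining picks continue on the
excluded sub-1% rows when those are supplied (`rare =`,
`on_exhaust = "rare"`), preferring the most frequent of them; the
alternative `"stop"` ends the selection early. Both modes are logged per
round.

Ties among equally optimal selections are solver-order dependent; only
the objective value is contractual, and tests compare objectives, never
supports.

## Baseline schemes

* **AHAP1**: rank once by the same static weights `c = h'A`, no
  updating; ties go to the lower animal index. Selection uses both
  homozygous and heterozygous carriage (homozygote-only variants are out
  of scope).
* **IWS**: one animal per round, weighted by the sum of *inverse*
  frequencies `1/h_i` over the not-yet-covered rows it carries, so
  carriers of rare haplotypes dominate; covered rows are then removed.
  The exact published weighting differs between implementations, so the
  rule here is the simplest one reproducing the documented behavior, and
  weights within a relative 1e-9 count as tied (lowest index wins) so
  that independent recomputations select identically. Because the
  rare-haplotype preference has nothing to act on after a 1% filter, the
  experiment driver runs IWS on the unfiltered library while the
  frequency-seeking methods select on the common submatrix; coverage is
  always reported on both denominators.
* **Greedy set cover** (largest uncovered carriage per pick) and uniform
  random selection complete the comparison set; greedy is the classical
  approximation whose cover can strictly exceed the certified minimum.

## The breeding simulator

`simulate_scenario()` emulates a closed dairy-cattle nucleus with
discrete generations: 1,000 founders of equal sex ratio; each generation
the 25 males with the highest true breeding values (truncation
selection, ties to the smaller id) are mated to 500 dams to produce
1,000 offspring of equal sex ratio; scenarios 1-5 run 5/10/15/30/50
generations, giving cumulative populations of 6,000 to 51,000 animals. A
quantitative trait is controlled by 150 QTL (15 per chromosome, evenly
spaced among the SNPs) with standard-normal effects; selection acts on
the true breeding value, i.e. heritability is 1 — the selection methods
only consume the haplotype structure, so environmental noise would add
nothing but runtime. Each offspring draws a uniformly random (sire, dam)
pair, and meiosis produces per-chromosome mosaics with
Poisson(1)-distributed crossovers (a 1-Morgan chromosome), uniform
crossover positions and fair starting phase.

Founder haplotypes come from a per-chromosome pool: a random ancestral
haplotype is mutated at per-locus rate `founder_flip_rate` to produce
`founder_pool_size` pool members, and every founder gamete recombines
two random pool members once. This is a deliberately simple stand-in for
a coalescent founder model: it preserves block-level haplotype sharing —
the only feature the selection methods consume — but not site-frequency
spectra, linkage-disequilibrium decay or mutation. The defaults (pool 40,
flip rate 0.115) were calibrated so that a scenario-1 population yields
a haplotype library of the magnitude reported for coalescent-founder
cattle simulations (~270 merged haplotypes and ~30 common haplotypes per
100-SNP block); absolute library sizes remain approximate by
construction, so tests assert comparative behavior (method orderings,
coverage bands, certified optimality) rather than absolute haplotype
counts.

All randomness flows through R's RNG: a `seed` in the configuration (or
`seed_base + replicate` in `run_experiment()`) makes populations
bit-reproducible.

## Problem sizes used by the tests and the acceptance script

The package's own benchmark runs use scenario-1 populations of 6,000
animals with 10 chromosomes of 200 SNPs (20 blocks of 100 SNPs) — the
full breeding design at a reduced marker density, chosen so a complete
simulate/build/select/benchmark cycle runs in seconds while the
incidence matrix keeps realistic per-block cluster counts. Unit tests
use still smaller populations (hundreds of animals) and 50 random
instances small enough (`n <= 15`) for exhaustive subset enumeration,
against which both solvers are checked exactly.

## Known limitations

* The founder model is not coalescent; absolute haplotype counts and
  minimum-cover sizes are comparable across methods within a simulation
  but not directly to populations with coalescent founders.
* The covering solver's optimality certificate depends on closing the
  search tree; a pathological instance can exhaust the node budget, in
  which case the result is explicitly flagged as uncertified.
* Statistical phasing, imputation accuracy, pedigree-based selection
  criteria and overlapping generations are out of scope.
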