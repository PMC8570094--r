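# seqpick

Optimal allocation of whole-genome sequencing resources in genotyped
livestock populations.

Breeding programs genotype whole populations with low-density SNP arrays
but can afford to sequence only a few animals. If every haplotype in the
population is carried by at least one sequenced animal, sequence can be
imputed into everyone else — so the choice of animals is a covering
problem. seqpick builds a haplotype library from phased SNP data and
selects animals by **exact integer linear programming**, with baseline
heuristics and a breeding-population simulator for benchmarking.

## The model

Let `x_j ∈ {0,1}` indicate selection of animal `j` (of `n`), and let
`A` be the `p × n` binary incidence matrix with `a_ij = 1` iff animal
`j` carries haplotype `i` on at least one chromosome copy. Haplotypes
are 100-SNP block haplotypes, merged at a 10% mismatch tolerance, with
frequencies `h_i` computed over the `2n` observed gametes.

**Minimum cover** — the fewest animals carrying every haplotype:

    min Σ_j x_j    s.t.  A x ≥ b,  x binary        (default b = 1)

**Budgeted coverage** — with per-animal weights `c = hᵀA`, the best
fixed-size selection of common-haplotype carriers:

    max Σ_j c_j x_j   s.t.  Σ_j x_j ≤ n_max,
                            Σ_j a_ij x_j ≤ r_max  (per haplotype row)

Both are solved by a built-in exact 0-1 branch-and-bound solver that
returns an optimality certificate (`proven_optimal`). For large budgets
the one-shot program is slow, so `iterative_budget_select()` picks
`batch = 2` animals per round under `r_max = 2`, removes them and the
haplotype rows they cover, and repeats — each round an exact solve.
Baselines: `ahap1_select()` (static frequency weights, no updating),
`iws_select()` (inverse-frequency weights, one animal at a time),
`greedy_cover()` and `random_select()`.

## Worked example

Simulate a 6,000-animal breeding population (1,000 founders plus five
generations of truncation selection: 25 top sires × 500 dams → 1,000
offspring each), build its haplotype library, and select 100 animals:

```r
library(seqpick)

pop <- simulate_scenario(1, seed = 42, snps_per_chromosome = 200)
#> phased_pop: 6000 animals, 2000 SNPs on 10 chromosomes; generations 0-5

lib <- build_library(pop, block_length = 100, mismatch = 0.10)
#> hap_library: 5389 haplotypes in 20 blocks over 6000 animals

M  <- build_incidence(lib)            # 5389 x 6000 sparse 0/1 matrix
Mc <- filter_common(M, 0.01)          # 612 haplotypes with frequency >= 1%

sel <- iterative_budget_select(Mc, total_budget = 100, batch = 2, r_max = 2,
                               rare = filter_rare(M, 0.01))
coverage_report(sel$selected, M, Mc)[c("prop_common", "prop_all")]
#> $prop_common
#> [1] 1
#> $prop_all
#> [1] 0.2373
```

The 100 selected animals carry every common haplotype
(`prop_common = 1.00`) but only 24% of all haplotypes — most of the
library is rare variation that a 100-animal budget cannot reach. The
minimum number of animals needed to carry *everything* is certified
exactly:

```r
solve_min_cover(M)
#> selection_result [min_cover]: 1980 animals, objective 1980 (proven optimal)
```

Every result can be re-verified independently of the solver with
`validate_result()`, and `run_experiment()` drives replicated
simulate/build/select comparisons across methods. A command-line front
end for shell pipelines ships in `inst/cli/seqpick.R`
(`simulate`, `build-lib`, `select`, `baseline`, `experiment`).

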