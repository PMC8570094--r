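Package: seqpick
Title: Optimal Allocation of Sequencing Resources in Genotyped Livestock
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects animals for whole-genome sequencing from a phased,
    array-genotyped population so that the haplotype diversity of the
    population is captured as efficiently as possible. Builds a
    haplotype library from phased SNP data (fixed-length blocks with
    mismatch-tolerant merging), then solves two exact integer linear
    programs with a built-in branch-and-bound solver: the minimum set of
    animals carrying every haplotype in the library, and a fixed budget
    of animals maximizing frequency-weighted haplotype coverage under a
    per-haplotype redundancy cap, together with a batched iterative
    variant of the latter. Baseline selection schemes (AHAP1, IWS,
    greedy set cover, random) and a forward-in-time breeding simulator
    with truncation selection of sires are included for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
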