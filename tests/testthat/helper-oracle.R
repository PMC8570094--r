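# Brute-force oracles and fixture builders shared across tests.
# The oracles enumerate all 2^n animal subsets (n <= ~15) with vectorized
# recursive doubling, independently of the branch-and-bound code paths.

# per-subset coverage counts: 2^n x p matrix, subset s counts carriers per row
subset_counts <- function(A) {
  n <- ncol(A)
  p <- nrow(A)
  cnt <- matrix(0L, nrow = 2^n, ncol = p)
  for (j in seq_len(n)) {
    block <- 2^(j - 1)
    idx <- which(bitwAnd(0:(2^n - 1), block) > 0)
    cnt[idx, ] <- cnt[idx - block, , drop = FALSE] +
      matrix(A[, j], nrow = length(idx), ncol = p, byrow = TRUE)
  }
  cnt
}

subset_sizes <- function(n) {
  s <- 0:(2^n - 1)
  rowSums(sapply(seq_len(n), function(j) bitwAnd(s, 2^(j - 1)) > 0))
}

subset_objectives <- function(cvec) {
  n <- length(cvec)
  s <- 0:(2^n - 1)
  obj <- numeric(2^n)
  for (j in seq_len(n)) obj <- obj + cvec[j] * (bitwAnd(s, 2^(j - 1)) > 0)
  obj
}

# exhaustive minimum-cover size subject to per-row demand b
oracle_min_cover <- function(A, b = 1L) {
  cnt <- subset_counts(A)
  bmat <- matrix(rep_len(b, nrow(A)), nrow = nrow(cnt), ncol = nrow(A),
                 byrow = TRUE)
  feas <- rowSums(cnt >= bmat) == nrow(A)
  min(subset_sizes(ncol(A))[feas])
}

# exhaustive budgeted maximum under the per-row redundancy cap
oracle_budget <- function(A, cvec, n_max, r_max = 2L) {
  cnt <- subset_counts(A)
  rmat <- matrix(rep_len(r_max, nrow(A)), nrow = nrow(cnt), ncol = nrow(A),
                 byrow = TRUE)
  feas <- subset_sizes(ncol(A)) <= n_max & rowSums(cnt <= rmat) == nrow(A)
  max(subset_objectives(cvec)[feas])
}

# random binary incidence with no empty rows
random_incidence_matrix <- function(n, p, density = 0.3) {
  repeat {
    A <- matrix(rbinom(n * p, 1, density), nrow = p)
    if (all(rowSums(A) >= 1)) return(A)
  }
}

# wrap a dense 0/1 matrix as a hap_incidence (h defaults to carriage/2n)
as_incidence <- function(A, h = NULL, ids = as.character(seq_len(ncol(A)))) {
  if (is.null(h)) h <- rowSums(A) / (2 * ncol(A))
  As <- methods::as(Matrix::Matrix(A, sparse = TRUE), "dgCMatrix")
  colnames(As) <- ids
  seqpick:::new_incidence(As, h, ids, seq_len(nrow(A)), 0)
}

# small, fast breeding population used by many tests
small_scenario_pop <- function(seed = 5, generations_scenario = 1) {
  simulate_scenario(generations_scenario, seed = seed, n_founders = 80,
                    n_sires = 5, n_dams = 30, offspring_per_gen = 80,
                    n_chromosomes = 3, snps_per_chromosome = 200,
                    n_qtl = 30)
}
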