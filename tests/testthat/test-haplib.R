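make_map <- function(chrom_snps) {
  data.frame(chrom = rep(paste0("chr", seq_along(chrom_snps)), chrom_snps),
             pos = unlist(lapply(chrom_snps, seq_len)))
}

test_that("blocks tile chromosomes with remainder handling", {
  b <- define_blocks(make_map(rep(1000L, 10)), 100)
  expect_equal(nrow(b), 100)
  expect_true(all(b$end - b$start == 100))

  b2 <- define_blocks(make_map(250L), 100)
  expect_equal(b2$end - b2$start, c(100, 100, 50))

  b3 <- define_blocks(make_map(c(80L, 60L)), 100)
  expect_equal(nrow(b3), 2)           # one block per chromosome
  expect_equal(b3$start, c(0, 80))    # blocks never span chromosomes
  expect_equal(b3$end, c(80, 140))

  expect_error(define_blocks(data.frame(chrom = character(0),
                                        pos = integer(0))), "empty")
})

test_that("mismatch merging has an inclusive 10% boundary", {
  base <- paste(rep("0", 100), collapse = "")
  flip_at <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    v[seq_len(k)] <- "1"
    paste(v, collapse = "")
  }
  # 10 of 100 differing sites merge into one cluster
  cl10 <- cluster_haplotypes(c(base, flip_at(base, 10)), mismatch = 0.10)
  expect_equal(nrow(cl10), 1)
  expect_equal(cl10$count, 2)
  # 11 of 100 do not
  cl11 <- cluster_haplotypes(c(base, flip_at(base, 11)), mismatch = 0.10)
  expect_equal(nrow(cl11), 2)
  # tolerance zero is exact deduplication
  set.seed(2)
  haps <- replicate(40, paste(sample(0:1, 25, TRUE), collapse = ""))
  cl0 <- cluster_haplotypes(haps, mismatch = 0)
  expect_equal(nrow(cl0), length(unique(haps)))
  expect_error(cluster_haplotypes(c("0101", "011"), 0.1), "length")
})

test_that("clusters are processed in descending count order", {
  haps <- c(rep("1111", 5), rep("0000", 2), "1110")
  cl <- cluster_haplotypes(haps, mismatch = 0.25)  # up to 1 differing site
  expect_equal(cl$representative[1], "1111")       # most frequent leads
  expect_equal(cl$count, c(6, 2))                  # "1110" joins the leader
  expect_equal(sum(cl$count), length(haps))
})

test_that("raising the tolerance never increases the cluster count", {
  set.seed(8)
  haps <- replicate(60, paste(sample(0:1, 50, TRUE,
                                     prob = c(0.8, 0.2)), collapse = ""))
  sizes <- vapply(c(0, 0.05, 0.1, 0.2, 0.3),
                  function(tol) nrow(cluster_haplotypes(haps, tol)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("incidence is carriage (binary), frequencies sum to 1 per block", {
  # one animal, one block of 4 SNPs
  H <- matrix(as.raw(c(1, 1, 0, 0,
                       1, 1, 0, 0)), nrow = 2, byrow = TRUE)
  lib <- build_library(H, block_length = 4, mismatch = 0,
                       snp_map = make_map(4L))
  M <- build_incidence(lib)
  expect_equal(nrow(M$A), 1)              # homozygous: one haplotype
  expect_equal(as.numeric(M$A[1, 1]), 1)  # a_ij = 1, not 2
  expect_equal(M$h, 1.0)

  H2 <- matrix(as.raw(c(1, 1, 0, 0,
                        0, 0, 1, 1)), nrow = 2, byrow = TRUE)
  M2 <- build_incidence(build_library(H2, block_length = 4, mismatch = 0,
                                      snp_map = make_map(4L)))
  expect_equal(M2$h, c(0.5, 0.5))
  expect_equal(sum(M2$h), 1)              # one block: frequencies normalize
})

test_that("library structure holds on a simulated population", {
  pop <- small_scenario_pop(seed = 3)
  lib <- build_library(pop, block_length = 100, mismatch = 0.10)
  M <- build_incidence(lib)
  n <- n_animals(pop)
  n_blocks <- nrow(lib$blocks)
  # per-block count conservation: counts sum to 2n in every block
  per_block <- tapply(lib$haplotypes$count, lib$haplotypes$block_id, sum)
  expect_true(all(per_block == 2 * n))
  # haplotype ids dense, frequencies in (0, 1]
  expect_equal(lib$haplotypes$hap_id, seq_len(lib$p))
  expect_true(all(lib$haplotypes$frequency > 0 &
                  lib$haplotypes$frequency <= 1))
  # every row nonzero; columns carry between n_blocks and 2 n_blocks entries
  expect_true(all(Matrix::rowSums(M$A) >= 1))
  cs <- Matrix::colSums(M$A)
  expect_true(all(cs >= n_blocks & cs <= 2 * n_blocks))
  # tolerance 0 agrees with exact string deduplication per block
  lib0 <- build_library(pop, block_length = 100, mismatch = 0)
  H <- pop$haplotypes
  blocks <- define_blocks(pop$snp_map, 100)
  exact <- sum(vapply(seq_len(nrow(blocks)), function(b) {
    sub <- H[, (blocks$start[b] + 1):blocks$end[b], drop = FALSE]
    length(unique(apply(sub, 1, function(r)
      paste0(as.integer(r), collapse = ""))))
  }, numeric(1)))
  expect_equal(lib0$p, exact)
})

test_that("the 1% frequency filter excludes strictly-below haplotypes", {
  A <- diag(3)
  M <- as_incidence(A, h = c(0.009, 0.010, 0.500))
  Mf <- filter_common(M, 0.01)
  expect_equal(nrow(Mf$A), 2)
  expect_equal(Mf$haplotype_ids, c(2L, 3L))   # 0.010 retained, 0.009 dropped
  expect_equal(ncol(Mf$A), 3)                 # animal columns preserved
  # min_freq = 0 is the identity
  M0 <- filter_common(M, 0)
  expect_equal(nrow(M0$A), 3)
  expect_error(filter_common(M, 0.9), "empty problem")
})

test_that("alleles outside {0,1} are rejected", {
  H <- matrix(2L, nrow = 2, ncol = 4)
  expect_error(build_library(H, block_length = 4, snp_map = make_map(4L)),
               "0/1")
})
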