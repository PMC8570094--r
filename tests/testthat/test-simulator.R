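test_that("founders have the configured size, sex ratio and dimensions", {
  cfg <- sim_config(n_founders = 100, n_chromosomes = 2,
                    snps_per_chromosome = 50, n_qtl = 10, n_sires = 5,
                    n_dams = 20, offspring_per_gen = 50, seed = 3)
  pop <- simulate_founders(cfg)
  expect_equal(n_animals(pop), 100)
  expect_equal(sum(pop$sex == "M"), 50)
  expect_equal(sum(pop$sex == "F"), 50)
  expect_equal(n_loci(pop), 100)
  expect_equal(nrow(pop$haplotypes), 200)
  expect_true(all(pop$generation == 0L))
  expect_true(all(is.na(pop$sire)))
})

test_that("a degenerate founder pool of size one gives identical animals", {
  cfg <- sim_config(n_founders = 2, n_sires = 1, n_dams = 1,
                    offspring_per_gen = 2, n_chromosomes = 1,
                    snps_per_chromosome = 4, n_qtl = 1,
                    founder_pool_size = 1, seed = 9)
  pop <- simulate_founders(cfg)
  h <- apply(pop$haplotypes, 1, function(r) paste0(as.integer(r),
                                                   collapse = ""))
  expect_length(unique(h), 1L)
})

test_that("simulation is bit-reproducible given the seed", {
  cfg <- sim_config(n_founders = 40, n_sires = 4, n_dams = 15,
                    offspring_per_gen = 40, n_chromosomes = 2,
                    snps_per_chromosome = 60, n_qtl = 10,
                    n_generations = 2, seed = 123)
  p1 <- simulate_founders(cfg)
  p1 <- advance_generation(advance_generation(p1))
  p2 <- simulate_founders(cfg)
  p2 <- advance_generation(advance_generation(p2))
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$bv, p2$bv)
  expect_identical(p1$sire, p2$sire)
})

test_that("breeding values are dosage-weighted sums of QTL effects", {
  H <- matrix(as.raw(c(0, 0,
                       0, 0,
                       1, 1,
                       1, 0)), nrow = 4, ncol = 2, byrow = TRUE)
  pop <- seqpick:::new_phased_pop(
    ids = 1:2, sex = c("M", "F"), generation = c(0L, 0L),
    sire = c(NA_integer_, NA_integer_), dam = c(NA_integer_, NA_integer_),
    haplotypes = H,
    snp_map = data.frame(chrom = "chr1", pos = 1:2),
    qtl = data.frame(locus = 1:2, effect = c(0.5, -1.0)))
  bv <- breeding_values(pop)
  expect_equal(bv[1], 0.0)                 # all-zero genotype
  expect_equal(bv[2], 2 * 0.5 + 1 * -1.0)  # dosages (2, 1)
  # heterozygote at a single unit-effect QTL scores exactly 1
  bv2 <- breeding_values(pop, qtl = data.frame(locus = 2, effect = 1.0))
  expect_equal(bv2, c(0.0, 1.0))
  expect_error(breeding_values(pop, qtl = data.frame(locus = 5, effect = 1)),
               "out of range")
})

test_that("meiosis respects parental identity and zero recombination", {
  set.seed(42)
  chrom <- c(30L, 30L)
  h <- rbinom(60, 1, 0.5)
  expect_equal(meiosis(h, h, chrom, recombination_rate = 2), h)
  h2 <- rbinom(60, 1, 0.5)
  g <- meiosis(h, h2, chrom, recombination_rate = 0)
  for (k in 1:2) {
    seg <- (k - 1) * 30 + 1:30
    expect_true(identical(g[seg], h[seg]) || identical(g[seg], h2[seg]))
  }
})

test_that("each parental allele is transmitted about half the time", {
  set.seed(7)
  chrom <- 40L
  h1 <- rep(1L, 40)
  h0 <- rep(0L, 40)
  n_meioses <- 400
  share <- rowMeans(vapply(seq_len(n_meioses), function(i)
    meiosis(h1, h0, chrom, recombination_rate = 1), integer(40)))
  # binomial 99.9% band around 0.5 for 400 draws
  band <- 3.3 * sqrt(0.25 / n_meioses)
  expect_true(all(abs(share - 0.5) < band + 0.05))
  expect_lt(abs(mean(share) - 0.5), 0.05)
})

test_that("truncation selection picks the top sires and records pedigree", {
  set.seed(11)
  pop <- small_scenario_pop(seed = 21)
  cfg <- pop$config
  founders <- which(pop$generation == 0L)
  males <- founders[pop$sex[founders] == "M"]
  expected_sires <- pop$ids[males[order(-pop$bv[males],
                                        pop$ids[males])][1:cfg$n_sires]]
  gen1 <- which(pop$generation == 1L)
  expect_equal(length(gen1), cfg$offspring_per_gen)
  expect_equal(sum(pop$sex[gen1] == "M"),
               round(cfg$offspring_per_gen * cfg$sex_ratio))
  expect_true(all(pop$sire[gen1] %in% expected_sires))
  expect_true(all(pop$dam[gen1] %in% pop$ids[founders][
    pop$sex[founders] == "F"]))
})

test_that("offspring haplotypes are mosaics of their parents'", {
  pop <- small_scenario_pop(seed = 31)
  gen1 <- which(pop$generation == 1L)[1:10]
  for (j in gen1) {
    kid <- animal_haplotypes(pop, pop$ids[j])
    sire <- animal_haplotypes(pop, pop$sire[j])
    dam <- animal_haplotypes(pop, pop$dam[j])
    # gamete 1 from the sire, gamete 2 from the dam, locus by locus
    expect_true(all(kid[1, ] == sire[1, ] | kid[1, ] == sire[2, ]))
    expect_true(all(kid[2, ] == dam[1, ] | kid[2, ] == dam[2, ]))
  }
})

test_that("cumulative scenario sizes follow founders + g x offspring", {
  # scenario 1 runs 5 generations: founders + 5 x offspring_per_gen
  pop <- simulate_scenario(1, seed = 41, n_founders = 80, n_sires = 5,
                           n_dams = 30, offspring_per_gen = 80,
                           n_chromosomes = 2, snps_per_chromosome = 40,
                           n_qtl = 10)
  expect_equal(n_animals(pop), 80 + 5 * 80)
  expect_equal(max(pop$generation), 5L)
  expect_equal(as.integer(table(pop$generation)), rep(80L, 6))
})

test_that("directional selection raises mean breeding value", {
  deltas <- vapply(1:5, function(s) {
    pop <- simulate_scenario(1, seed = 100 + s, n_founders = 80, n_sires = 5,
                             n_dams = 30, offspring_per_gen = 80,
                             n_chromosomes = 2, snps_per_chromosome = 40,
                             n_qtl = 20)
    means <- tapply(pop$bv, pop$generation, mean)
    means[length(means)] - means[1]
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_founders = 0), "positive count")
  expect_error(sim_config(n_sires = 600, n_founders = 1000), "n_sires")
  expect_error(sim_config(sex_ratio = 1.2), "sex_ratio")
  expect_error(sim_config(n_qtl = 1e6), "n_qtl")
})
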