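#' Simulation configuration for the breeding-population generator
#'
#' Defines a closed nucleus breeding scheme with discrete generations:
#' `n_founders` base animals of (near-)equal sex ratio, after which each
#' generation the `n_sires` males with the highest true breeding values are
#' mated to `n_dams` dams to produce `offspring_per_gen` offspring. A
#' quantitative trait is controlled by `n_qtl` loci (a subset of the SNPs,
#' spread equally over chromosomes) with effects drawn from a standard
#' normal distribution.
#'
#' Founder haplotypes are drawn from a per-chromosome pool of
#' `founder_pool_size` haplotypes, each obtained by mutating a random
#' ancestral haplotype at per-locus rate `founder_flip_rate`; every founder
#' gamete recombines two pool haplotypes once. This preserves block-level
#' haplotype sharing, which is what the downstream selection methods
#' consume, without a coalescent founder model.
#'
#' @param n_founders number of base animals (default 1000).
#' @param sex_ratio fraction of males (default 0.5).
#' @param n_generations number of discrete generations to simulate.
#' @param n_sires sires selected per generation by truncation on breeding
#'   value (default 25).
#' @param n_dams dams used per generation (default 500).
#' @param offspring_per_gen offspring produced per generation (default 1000).
#' @param n_chromosomes number of chromosomes (default 10).
#' @param snps_per_chromosome SNPs per chromosome (default 1000).
#' @param n_qtl number of QTL, spread equally over chromosomes (default 150).
#' @param recombination_rate expected crossovers per chromosome per meiosis
#'   (default 1, i.e. a 1-Morgan chromosome).
#' @param founder_pool_size founder haplotype pool size per chromosome.
#' @param founder_flip_rate per-locus mutation rate of pool haplotypes
#'   relative to the ancestral haplotype.
#' @param seed optional integer seed; when set, simulation functions that
#'   receive this config seed R's RNG before drawing.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 1000L, sex_ratio = 0.5,
                       n_generations = 5L, n_sires = 25L, n_dams = 500L,
                       offspring_per_gen = 1000L, n_chromosomes = 10L,
                       snps_per_chromosome = 1000L, n_qtl = 150L,
                       recombination_rate = 1, founder_pool_size = 40L,
                       founder_flip_rate = 0.115, seed = NULL) {
  cfg <- list(
    n_founders = as.integer(n_founders), sex_ratio = sex_ratio,
    n_generations = as.integer(n_generations), n_sires = as.integer(n_sires),
    n_dams = as.integer(n_dams),
    offspring_per_gen = as.integer(offspring_per_gen),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    n_qtl = as.integer(n_qtl), recombination_rate = recombination_rate,
    founder_pool_size = as.integer(founder_pool_size),
    founder_flip_rate = founder_flip_rate,
    seed = if (is.null(seed)) NULL else as.integer(seed))
  counts <- c("n_founders", "n_generations", "n_sires", "n_dams",
              "offspring_per_gen", "n_chromosomes", "snps_per_chromosome",
              "founder_pool_size")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("config field '", f, "' must be a positive count")
  }
  if (sex_ratio <= 0 || sex_ratio >= 1) stop("sex_ratio must be in (0, 1)")
  if (cfg$n_qtl < 0L ||
      cfg$n_qtl > cfg$n_chromosomes * cfg$snps_per_chromosome)
    stop("n_qtl must fit within the simulated SNPs")
  if (recombination_rate < 0) stop("recombination_rate must be >= 0")
  if (founder_flip_rate < 0 || founder_flip_rate > 1)
    stop("founder_flip_rate must be a probability")
  n_off_m <- round(cfg$offspring_per_gen * sex_ratio)
  if (cfg$n_sires > n_off_m || cfg$n_sires > round(cfg$n_founders * sex_ratio))
    stop("n_sires exceeds the number of males per generation")
  if (cfg$n_dams > cfg$offspring_per_gen - n_off_m ||
      cfg$n_dams > cfg$n_founders - round(cfg$n_founders * sex_ratio))
    stop("n_dams exceeds the number of females per generation")
  structure(cfg, class = "sim_config")
}

snp_map_from_config <- function(config) {
  data.frame(
    chrom = rep(paste0("chr", seq_len(config$n_chromosomes)),
                each = config$snps_per_chromosome),
    pos = rep(seq_len(config$snps_per_chromosome), config$n_chromosomes),
    stringsAsFactors = FALSE)
}

qtl_from_config <- function(config) {
  per_chrom <- rep(config$n_qtl %/% config$n_chromosomes,
                   config$n_chromosomes)
  extra <- config$n_qtl %% config$n_chromosomes
  if (extra > 0L) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  loci <- integer(0)
  for (k in seq_len(config$n_chromosomes)) {
    if (per_chrom[k] == 0L) next
    # evenly spaced positions within the chromosome
    within <- unique(round(seq(1L, config$snps_per_chromosome,
                               length.out = per_chrom[k])))
    loci <- c(loci, (k - 1L) * config$snps_per_chromosome + within)
  }
  data.frame(locus = as.integer(loci),
             effect = rnorm(length(loci)))
}

new_phased_pop <- function(ids, sex, generation, sire, dam, haplotypes,
                           snp_map, qtl = NULL, bv = NULL,
                           config = NULL) {
  structure(list(ids = as.integer(ids), sex = sex,
                 generation = as.integer(generation),
                 sire = as.integer(sire), dam = as.integer(dam),
                 haplotypes = haplotypes, snp_map = snp_map, qtl = qtl,
                 bv = bv, config = config),
            class = "phased_pop")
}

#' Number of animals / loci in a phased population
#' @param pop a `phased_pop`.
#' @return integer count.
#' @export
n_animals <- function(pop) length(pop$ids)

#' @rdname n_animals
#' @export
n_loci <- function(pop) ncol(pop$haplotypes)

#' @export
print.phased_pop <- function(x, ...) {
  cat("phased_pop:", n_animals(x), "animals,", n_loci(x), "SNPs on",
      length(unique(x$snp_map$chrom)), "chromosomes;",
      "generations", paste(range(x$generation), collapse = "-"), "\n")
  invisible(x)
}

#' Extract the two phased haplotypes of one animal
#'
#' @param pop a `phased_pop`.
#' @param id animal id.
#' @return 2 x m integer matrix of 0/1 alleles.
#' @export
animal_haplotypes <- function(pop, id) {
  j <- match(id, pop$ids)
  if (is.na(j)) stop("unknown animal id: ", id)
  rows <- c(2L * j - 1L, 2L * j)
  matrix(as.integer(pop$haplotypes[rows, , drop = FALSE]), nrow = 2L)
}

#' Simulate the founder generation
#'
#' Generates `n_founders` animals of (near-)equal sex ratio whose gametes
#' are drawn from the per-chromosome founder haplotype pool (see
#' [sim_config()]), and samples the QTL effects of the simulated trait.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `phased_pop` of generation 0.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  chrom_snps <- rep(config$snps_per_chromosome, config$n_chromosomes)
  H <- .founder_haplotypes(config$n_founders, chrom_snps,
                           config$founder_pool_size, config$founder_flip_rate,
                           config$recombination_rate)
  n <- config$n_founders
  n_male <- round(n * config$sex_ratio)
  sex <- c(rep("M", n_male), rep("F", n - n_male))
  qtl <- qtl_from_config(config)
  pop <- new_phased_pop(ids = seq_len(n), sex = sex,
                        generation = rep(0L, n), sire = rep(NA_integer_, n),
                        dam = rep(NA_integer_, n), haplotypes = H,
                        snp_map = snp_map_from_config(config), qtl = qtl,
                        config = config)
  pop$bv <- breeding_values(pop)
  pop
}

#' True breeding values from QTL dosages
#'
#' The breeding value of an animal is the sum over QTL of its allele dosage
#' (0/1/2) times the QTL effect.
#'
#' @param pop a `phased_pop` carrying a `qtl` table.
#' @param qtl optional QTL table (`locus`, `effect`) overriding `pop$qtl`.
#' @return numeric vector, one value per animal in `pop$ids` order.
#' @export
breeding_values <- function(pop, qtl = NULL) {
  qtl <- if (is.null(qtl)) pop$qtl else qtl
  if (is.null(qtl)) stop("population has no QTL table")
  if (any(qtl$locus < 1L) || any(qtl$locus > n_loci(pop)))
    stop("QTL position out of range")
  D <- .dosage_at(pop$haplotypes, as.integer(qtl$locus) - 1L)
  as.numeric(D %*% qtl$effect)
}

#' Meiosis: one recombined gamete from two parental haplotypes
#'
#' Produces a per-chromosome mosaic of the two parental haplotypes with a
#' Poisson(`recombination_rate`) crossover count per chromosome, uniform
#' crossover positions and a fair random starting phase. Crossovers never
#' span chromosome boundaries.
#'
#' @param hap1,hap2 integer (or raw) 0/1 vectors of equal length m.
#' @param chrom_snps integer vector of SNP counts per chromosome summing
#'   to m.
#' @param recombination_rate expected crossovers per chromosome.
#' @return integer 0/1 vector of length m.
#' @export
meiosis <- function(hap1, hap2, chrom_snps, recombination_rate = 1) {
  r1 <- if (is.raw(hap1)) hap1 else as.raw(hap1)
  r2 <- if (is.raw(hap2)) hap2 else as.raw(hap2)
  as.integer(.meiosis_gamete(r1, r2, as.integer(chrom_snps),
                             recombination_rate))
}

#' Advance a population by one generation of truncation selection
#'
#' Sires are the `n_sires` males of the newest generation with the highest
#' breeding values (ties broken by smaller id); dams are `n_dams` females of
#' that generation (smallest ids). Each offspring receives a uniformly
#' random (sire, dam) pair and one recombined gamete from each parent;
#' pedigree, sex, generation and breeding value are recorded.
#'
#' @param pop cumulative `phased_pop`.
#' @param config a [sim_config()]; defaults to the one stored in `pop`.
#' @return the cumulative `phased_pop` including the new generation.
#' @export
advance_generation <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "phased_pop"), inherits(config, "sim_config"))
  g <- max(pop$generation)
  cur <- which(pop$generation == g)
  males <- cur[pop$sex[cur] == "M"]
  females <- cur[pop$sex[cur] == "F"]
  if (length(males) < config$n_sires)
    stop("generation ", g, " has fewer than n_sires males")
  if (length(females) < config$n_dams)
    stop("generation ", g, " has fewer than n_dams females")
  ord <- males[order(-pop$bv[males], pop$ids[males])]
  sires <- ord[seq_len(config$n_sires)]
  dams <- females[order(pop$ids[females])][seq_len(config$n_dams)]

  n_off <- config$offspring_per_gen
  sire_pick <- sires[sample.int(length(sires), n_off, replace = TRUE)]
  dam_pick <- dams[sample.int(length(dams), n_off, replace = TRUE)]
  chrom_snps <- as.integer(table(factor(pop$snp_map$chrom,
                                        levels = unique(pop$snp_map$chrom))))
  G <- .make_offspring(pop$haplotypes, 2L * (sire_pick - 1L),
                       2L * (dam_pick - 1L), chrom_snps,
                       config$recombination_rate)
  n_male <- round(n_off * config$sex_ratio)
  new_ids <- max(pop$ids) + seq_len(n_off)
  off <- new_phased_pop(
    ids = c(pop$ids, new_ids),
    sex = c(pop$sex, c(rep("M", n_male), rep("F", n_off - n_male))),
    generation = c(pop$generation, rep(g + 1L, n_off)),
    sire = c(pop$sire, pop$ids[sire_pick]),
    dam = c(pop$dam, pop$ids[dam_pick]),
    haplotypes = rbind(pop$haplotypes, G),
    snp_map = pop$snp_map, qtl = pop$qtl, config = config)
  D <- .dosage_at(G, as.integer(pop$qtl$locus) - 1L)
  off$bv <- c(pop$bv, as.numeric(D %*% pop$qtl$effect))
  off
}

#' Simulate one of the five benchmark population scenarios
#'
#' The scenarios share the breeding design (1,000 founders, 25 sires x 500
#' dams, 1,000 offspring per generation) and differ only in depth: 5, 10,
#' 15, 30 or 50 generations, giving cumulative populations of 6,000 /
#' 11,000 / 16,000 / 31,000 / 51,000 animals.
#'
#' @param scenario integer 1..5.
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()] (e.g.
#'   `snps_per_chromosome`).
#' @return cumulative `phased_pop` of all generations including founders.
#' @export
simulate_scenario <- function(scenario, seed = NULL, ...) {
  if (!scenario %in% 1:5) stop("scenario must be in 1..5")
  gens <- c(5L, 10L, 15L, 30L, 50L)[scenario]
  config <- sim_config(n_generations = gens, seed = seed, ...)
  pop <- simulate_founders(config)
  for (g in seq_len(gens)) pop <- advance_generation(pop, config)
  pop
}
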