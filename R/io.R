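#' Write / read the plain haplotype-matrix TSV
#'
#' One row per observed gamete: `animal_id`, `hap` (1 or 2) and the allele
#' string over \{0,1\}. The SNP map travels in a separate two-column file
#' (see [write_snp_map()]) so the TSV stays a pure genotype exchange
#' format.
#'
#' @param pop a `phased_pop` (or any object with `ids` and a raw/integer
#'   haplotype matrix with two rows per animal).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_hap_tsv <- function(pop, file) {
  H <- pop$haplotypes
  n <- length(pop$ids)
  alle <- vapply(seq_len(2L * n), function(r)
    paste0(as.integer(H[r, ]), collapse = ""), character(1))
  df <- data.frame(animal_id = rep(pop$ids, each = 2L),
                   hap = rep(1:2, n), alleles = alle)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_hap_tsv
#' @param snp_map SNP map data.frame (`chrom`, `pos`) matching the allele
#'   string length.
#' @return for the reader, a `phased_pop` (pedigree/sex/breeding values
#'   absent).
#' @export
read_hap_tsv <- function(file, snp_map) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = c("integer", "integer", "character"))
  if (nrow(df) %% 2L != 0L) stop("expected two haplotype rows per animal")
  ids <- df$animal_id[df$hap == 1L]
  if (!identical(df$animal_id[df$hap == 2L], ids))
    stop("haplotype rows are not paired per animal")
  m <- nchar(df$alleles[1L])
  if (m != nrow(snp_map)) stop("snp_map does not match allele string length")
  H <- matrix(as.raw(0L), nrow = nrow(df), ncol = m)
  for (r in seq_len(nrow(df))) {
    v <- as.integer(strsplit(df$alleles[r], "")[[1L]])
    if (any(!v %in% 0:1)) stop("alleles must be 0/1")
    H[r, ] <- as.raw(v)
  }
  n <- length(ids)
  new_phased_pop(ids = ids, sex = rep(NA_character_, n),
                 generation = rep(NA_integer_, n),
                 sire = rep(NA_integer_, n), dam = rep(NA_integer_, n),
                 haplotypes = H, snp_map = snp_map)
}

#' Write / read the SNP map
#' @param pop a `phased_pop` (writer) or path (reader).
#' @param file path.
#' @export
write_snp_map <- function(pop, file) {
  utils::write.csv(pop$snp_map, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_snp_map
#' @export
read_snp_map <- function(file) {
  utils::read.csv(file, colClasses = c("character", "integer"))
}

#' Write a pedigree CSV (animal, sire, dam, sex, generation)
#' @param pop a `phased_pop`.
#' @param file output path.
#' @export
write_pedigree <- function(pop, file) {
  utils::write.csv(
    data.frame(animal = pop$ids, sire = pop$sire, dam = pop$dam,
               sex = pop$sex, generation = pop$generation),
    file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a minimal phased VCF of a simulated population
#'
#' Contigs are the chromosome names of the SNP map, positions are the
#' within-chromosome SNP indices, REF/ALT are placeholder alleles A/G and
#' genotypes are phased `0|1`-style GT fields.
#'
#' @param pop a `phased_pop`.
#' @param file output path (plain text `.vcf`).
#' @export
write_phased_vcf <- function(pop, file) {
  n <- length(pop$ids)
  m <- n_loci(pop)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ch in unique(pop$snp_map$chrom))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       sum(pop$snp_map$chrom == ch) + 1L), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", as.character(pop$ids)),
                   collapse = "\t"), con)
  H <- pop$haplotypes
  a1 <- matrix(as.integer(H[seq(1L, 2L * n, by = 2L), , drop = FALSE]),
               nrow = n)
  a2 <- matrix(as.integer(H[seq(2L, 2L * n, by = 2L), , drop = FALSE]),
               nrow = n)
  gt <- matrix(paste0(a1, "|", a2), nrow = n)  # n x m
  lines <- vapply(seq_len(m), function(l) {
    paste(c(pop$snp_map$chrom[l], pop$snp_map$pos[l], ".", "A", "G", ".",
            "PASS", ".", "GT", gt[, l]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(file)
}

#' Read a phased VCF into a population object
#'
#' Requires the vcfR package. Genotypes must be phased (`|` separator) and
#' biallelic; unphased (`/`) or missing genotypes are an error, since the
#' haplotype library presumes fully phased input.
#'
#' @param file path to a VCF.
#' @return a `phased_pop` (pedigree/sex absent).
#' @export
read_phased_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt) || any(grepl("/", gt, fixed = TRUE)))
    stop("unphased or missing genotypes: phased `|` GT fields are required")
  samples <- colnames(gt)
  m <- nrow(gt)
  n <- length(samples)
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = m)
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = m)
  if (any(!a1 %in% 0:1) || any(!a2 %in% 0:1))
    stop("only biallelic 0/1 alleles are supported")
  H <- matrix(as.raw(0L), nrow = 2L * n, ncol = m)
  H[seq(1L, 2L * n, by = 2L), ] <- as.raw(t(a1))
  H[seq(2L, 2L * n, by = 2L), ] <- as.raw(t(a2))
  snp_map <- data.frame(chrom = as.character(v@fix[, "CHROM"]),
                        pos = as.integer(v@fix[, "POS"]),
                        stringsAsFactors = FALSE)
  ids <- suppressWarnings(as.integer(samples))
  if (anyNA(ids)) ids <- seq_len(n)
  new_phased_pop(ids = ids, sex = rep(NA_character_, n),
                 generation = rep(NA_integer_, n),
                 sire = rep(NA_integer_, n), dam = rep(NA_integer_, n),
                 haplotypes = H, snp_map = snp_map)
}

#' Write / read the incidence matrix in Matrix Market form
#'
#' The sparse pattern goes to `<prefix>.mtx`; row (haplotype id +
#' frequency) and column (animal id) sidecars go to `<prefix>.rows.tsv`
#' and `<prefix>.cols.tsv`.
#'
#' @param M a `hap_incidence`.
#' @param prefix path prefix.
#' @export
write_incidence_mtx <- function(M, prefix) {
  writeMM(M$A, paste0(prefix, ".mtx"))
  utils::write.table(
    data.frame(haplotype_id = M$haplotype_ids, frequency = M$h),
    paste0(prefix, ".rows.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(data.frame(animal_id = M$animal_ids),
                     paste0(prefix, ".cols.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_incidence_mtx
#' @export
read_incidence_mtx <- function(prefix) {
  A <- methods::as(readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  A <- methods::as(A, "dMatrix")
  rows <- utils::read.table(paste0(prefix, ".rows.tsv"), header = TRUE,
                            sep = "\t")
  cols <- utils::read.table(paste0(prefix, ".cols.tsv"), header = TRUE,
                            sep = "\t", colClasses = "character")
  dimnames(A) <- list(NULL, cols$animal_id)
  new_incidence(A = A, h = rows$frequency, animal_ids = cols$animal_id,
                haplotype_ids = rows$haplotype_id, min_freq = 0)
}

#' Write / read the haplotype library as JSON
#' @param library a `hap_library`.
#' @param file path.
#' @export
write_library_json <- function(library, file) {
  jsonlite::write_json(
    list(block_length = library$block_length, mismatch = library$mismatch,
         n_animals = library$n_animals, p = library$p,
         animal_ids = library$animal_ids, blocks = library$blocks,
         haplotypes = library$haplotypes, carriage = library$carriage),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_library_json
#' @export
read_library_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(blocks = as.data.frame(x$blocks),
                 haplotypes = as.data.frame(x$haplotypes),
                 p = x$p, n_animals = x$n_animals,
                 animal_ids = x$animal_ids,
                 block_length = x$block_length, mismatch = x$mismatch,
                 carriage = as.data.frame(x$carriage)),
            class = "hap_library")
}

#' Write a selection as CSV (+ optional JSON report)
#'
#' @param result a `selection_result`.
#' @param file CSV path; columns `animal_id`, `round`, `c_weight`.
#' @param report optional JSON path for objective/coverage/round log.
#' @export
write_selection <- function(result, file, report = NULL) {
  k <- length(result$selected)
  rnd <- if (!is.null(result$rounds))
    rep(result$rounds$round, result$rounds$n_selected) else rep(1L, k)
  w <- if (!is.null(result$weights)) result$weights else rep(NA_real_, k)
  utils::write.csv(
    data.frame(animal_id = result$selected, round = rnd[seq_len(k)],
               c_weight = w),
    file, row.names = FALSE, quote = FALSE)
  if (!is.null(report)) {
    jsonlite::write_json(
      list(method = result$method, objective = result$objective,
           n_selected = k, proven_optimal = result$proven_optimal,
           prop_all = result$prop_all, prop_common = result$prop_common,
           rounds = result$rounds),
      report, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(file)
}
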