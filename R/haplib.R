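#' Tile chromosomes into haplotype blocks
#'
#' Blocks are consecutive, non-overlapping windows of `block_length` SNPs
#' within each chromosome (a final shorter block takes the remainder);
#' blocks never span chromosomes. Coordinates are 0-based half-open global
#' column indices into the concatenated SNP map.
#'
#' @param snp_map data.frame with columns `chrom` and `pos`, sorted by
#'   (chromosome, position).
#' @param block_length SNPs per block (default 100).
#' @return data.frame with columns `block_id`, `chrom`, `start`, `end`.
#' @export
define_blocks <- function(snp_map, block_length = 100L) {
  if (is.null(snp_map) || nrow(snp_map) == 0L) stop("empty SNP map")
  block_length <- as.integer(block_length)
  if (block_length < 1L) stop("block_length must be >= 1")
  chroms <- unique(snp_map$chrom)
  if (is.unsorted(match(snp_map$chrom, chroms)) ||
      any(unlist(tapply(snp_map$pos, factor(snp_map$chrom, levels = chroms),
                        is.unsorted))))
    stop("snp_map must be sorted by (chromosome, position)")
  out <- list()
  offset <- 0L
  for (ch in chroms) {
    L <- sum(snp_map$chrom == ch)
    starts <- seq.int(0L, L - 1L, by = block_length)
    ends <- pmin(starts + block_length, L)
    out[[ch]] <- data.frame(chrom = ch, start = offset + starts,
                            end = offset + ends, stringsAsFactors = FALSE)
    offset <- offset + L
  }
  blocks <- do.call(rbind, out)
  rownames(blocks) <- NULL
  cbind(block_id = seq_len(nrow(blocks)), blocks)
}

#' Merge near-identical block haplotypes by greedy leader clustering
#'
#' Distinct raw haplotypes are processed in descending raw-count order
#' (ties by lexicographic allele string); each joins the first existing
#' cluster whose representative differs at no more than
#' `floor(mismatch * L)` sites, else founds a new cluster with itself as
#' representative. The cluster count is the sum of its members' raw counts.
#'
#' @param haps character vector of equal-length allele strings over
#'   \{0,1\} (one per observed gamete), or a matrix of 0/1 alleles with one
#'   row per gamete.
#' @param mismatch mismatch tolerance as a fraction of the block length
#'   (default 0.10); must satisfy `0 <= mismatch < 0.5`.
#' @return data.frame with columns `representative`, `count`, `frequency`;
#'   the per-gamete cluster assignment (1-based) is attached as attribute
#'   `"assignment"`.
#' @export
cluster_haplotypes <- function(haps, mismatch = 0.10) {
  if (is.matrix(haps))
    haps <- apply(haps, 1L, paste0, collapse = "")
  if (mismatch < 0 || mismatch >= 0.5)
    stop("mismatch tolerance must be in [0, 0.5)")
  L <- nchar(haps[1L])
  if (any(nchar(haps) != L)) stop("block haplotypes differ in length")
  res <- .cluster_block(haps, as.integer(floor(mismatch * L)))
  out <- data.frame(representative = res$representatives,
                    count = res$counts,
                    frequency = res$counts / length(haps),
                    stringsAsFactors = FALSE)
  attr(out, "assignment") <- res$assignment + 1L
  out
}

#' Build the haplotype library of a phased population
#'
#' Splits every chromosome into blocks of `block_length` SNPs, then merges
#' near-identical block haplotypes with [cluster_haplotypes()]'s greedy
#' rule at the given mismatch tolerance. Haplotype frequencies use the
#' observed gametes as denominator (2n), and haplotype ids are globally
#' unique across blocks.
#'
#' @param pop a `phased_pop`, or a raw/integer matrix of 0/1 alleles with
#'   two rows per animal (in which case `snp_map` is required).
#' @param block_length SNPs per block (default 100).
#' @param mismatch mismatch tolerance fraction (default 0.10).
#' @param snp_map SNP map, only when `pop` is a bare matrix.
#' @param animal_ids optional animal labels (defaults to `pop$ids` or
#'   1..n).
#' @return an object of class `hap_library`: `blocks`, a `haplotypes`
#'   table (`hap_id`, `block_id`, `representative`, `count`, `frequency`),
#'   the total haplotype count `p`, and the carriage pairs used by
#'   [build_incidence()].
#' @export
build_library <- function(pop, block_length = 100L, mismatch = 0.10,
                          snp_map = NULL, animal_ids = NULL) {
  if (inherits(pop, "phased_pop")) {
    H <- pop$haplotypes
    snp_map <- pop$snp_map
    if (is.null(animal_ids)) animal_ids <- pop$ids
  } else {
    H <- pop
    if (is.null(snp_map)) stop("snp_map is required for matrix input")
  }
  if (!is.raw(H)) {
    if (any(!H %in% c(0L, 1L))) stop("alleles must be 0/1")
    H <- matrix(as.raw(H), nrow = nrow(H))
  }
  if (nrow(H) %% 2L != 0L) stop("expected two haplotype rows per animal")
  if (ncol(H) != nrow(snp_map)) stop("snp_map does not match locus count")
  if (mismatch < 0 || mismatch >= 0.5)
    stop("mismatch tolerance must be in [0, 0.5)")
  n <- nrow(H) %/% 2L
  if (is.null(animal_ids)) animal_ids <- seq_len(n)
  if (length(animal_ids) != n) stop("animal_ids length mismatch")
  blocks <- define_blocks(snp_map, block_length)
  max_mm <- as.integer(floor(mismatch * (blocks$end - blocks$start)))
  res <- .build_library(H, blocks$start, blocks$end, max_mm)
  haps <- data.frame(hap_id = seq_along(res$block_id),
                     block_id = res$block_id,
                     representative = res$representative,
                     count = res$count,
                     frequency = res$count / (2L * n),
                     stringsAsFactors = FALSE)
  structure(list(blocks = blocks, haplotypes = haps, p = nrow(haps),
                 n_animals = n, animal_ids = animal_ids,
                 block_length = as.integer(block_length),
                 mismatch = mismatch,
                 carriage = data.frame(hap = res$tri_i, animal = res$tri_j)),
            class = "hap_library")
}

#' @export
print.hap_library <- function(x, ...) {
  cat("hap_library:", x$p, "haplotypes in", nrow(x$blocks), "blocks over",
      x$n_animals, "animals (block length", x$block_length,
      ", mismatch", x$mismatch, ")\n")
  invisible(x)
}

#' Binary haplotype-by-animal incidence matrix
#'
#' Builds the sparse p x n matrix A with `a[i, j] = 1` iff animal j carries
#' haplotype i on at least one chromosome copy (carriage, not dosage:
#' homozygous carriers still give 1), together with the haplotype frequency
#' vector `h` (denominator 2n gametes).
#'
#' @param library a `hap_library` from [build_library()].
#' @return an object of class `hap_incidence` with fields `A` (sparse
#'   dgCMatrix), `h`, `animal_ids`, `haplotype_ids`, `common_mask` and
#'   `min_freq`.
#' @export
build_incidence <- function(library) {
  stopifnot(inherits(library, "hap_library"))
  A <- sparseMatrix(i = library$carriage$hap, j = library$carriage$animal,
                    x = 1, dims = c(library$p, library$n_animals),
                    dimnames = list(NULL, as.character(library$animal_ids)))
  new_incidence(A = A, h = library$haplotypes$frequency,
                animal_ids = as.character(library$animal_ids),
                haplotype_ids = library$haplotypes$hap_id,
                min_freq = 0)
}

new_incidence <- function(A, h, animal_ids, haplotype_ids, min_freq) {
  structure(list(A = A, h = h, animal_ids = animal_ids,
                 haplotype_ids = as.integer(haplotype_ids),
                 common_mask = h >= min_freq, min_freq = min_freq),
            class = "hap_incidence")
}

#' @export
print.hap_incidence <- function(x, ...) {
  cat("hap_incidence:", nrow(x$A), "haplotypes x", ncol(x$A), "animals,",
      length(x$A@x), "carriage entries")
  if (x$min_freq > 0) cat(" (filtered at frequency >=", x$min_freq, ")")
  cat("\n")
  invisible(x)
}

#' Restrict an incidence matrix to common haplotypes
#'
#' Keeps rows whose haplotype frequency is at least `min_freq`; haplotypes
#' strictly below the threshold are excluded (a frequency exactly equal to
#' the threshold is retained). Animal columns are preserved, possibly with
#' all-zero columns.
#'
#' @param M a `hap_incidence`.
#' @param min_freq frequency threshold in `[0, 1)` (default 0.01).
#' @return the filtered `hap_incidence`.
#' @export
filter_common <- function(M, min_freq = 0.01) {
  stopifnot(inherits(M, "hap_incidence"))
  if (min_freq < 0 || min_freq >= 1) stop("min_freq must be in [0, 1)")
  keep <- M$h >= min_freq
  if (!any(keep)) stop("empty problem: all haplotype rows fall below min_freq")
  new_incidence(A = M$A[keep, , drop = FALSE], h = M$h[keep],
                animal_ids = M$animal_ids,
                haplotype_ids = M$haplotype_ids[keep], min_freq = min_freq)
}

#' @rdname filter_common
#' @details `filter_rare()` returns the complementary submatrix (rows with
#'   frequency strictly below the threshold), used to keep selecting once
#'   every common haplotype is covered.
#' @export
filter_rare <- function(M, min_freq = 0.01) {
  stopifnot(inherits(M, "hap_incidence"))
  keep <- M$h < min_freq
  if (!any(keep)) stop("no haplotype rows fall below min_freq")
  new_incidence(A = M$A[keep, , drop = FALSE], h = M$h[keep],
                animal_ids = M$animal_ids,
                haplotype_ids = M$haplotype_ids[keep], min_freq = 0)
}

# row-wise sparse index lists (0-based column indices per haplotype row,
# ready for the C++ kernels)
incidence_row_list <- function(M) {
  R <- methods::as(M$A, "RsparseMatrix")
  p <- nrow(R)
  out <- lapply(seq_len(p), function(i) {
    if (R@p[i + 1L] == R@p[i]) integer(0) else
      R@j[(R@p[i] + 1L):R@p[i + 1L]]
  })
  out
}
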