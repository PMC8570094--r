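#' AHAP1 selection: static frequency-weighted ranking
#'
#' Computes the weights `c = h' A` once and selects animals in descending
#' weight order (ties by column order), with no updating for animals
#' already selected. Runs either to a fixed budget or until every
#' haplotype row is covered.
#'
#' @param M a `hap_incidence`.
#' @param budget number of animals to select (ignored when
#'   `to_coverage = TRUE`).
#' @param to_coverage select until all rows are covered.
#' @return a `selection_result`.
#' @export
ahap1_select <- function(M, budget = NULL, to_coverage = FALSE) {
  stopifnot(inherits(M, "hap_incidence"))
  w <- compute_weights(M)
  ord <- order(-w, seq_along(w))
  if (to_coverage) {
    cov <- .coverage_prefix(incidence_row_list(M), ncol(M$A), ord)
    if (cov$needed == 0L)
      stop("full ranking never covers all haplotype rows")
    k <- cov$needed
  } else {
    if (is.null(budget)) stop("either budget or to_coverage is required")
    k <- min(as.integer(budget), ncol(M$A))
  }
  idx <- ord[seq_len(k)]
  res <- new_selection_result(M$animal_ids[idx], objective = sum(w[idx]),
                              M = M, method = "ahap1")
  res$weights <- w[idx]
  res
}

#' IWS selection: rare-haplotype-weighted, one animal at a time
#'
#' Each round the weight of an animal is the sum of inverse frequencies
#' `1/h_i` over the not-yet-covered haplotype rows it carries, so carriers
#' of rare haplotypes dominate; the single highest-weighted animal is
#' selected (ties by column order) and its rows count as covered.
#'
#' @inheritParams ahap1_select
#' @return a `selection_result`.
#' @export
iws_select <- function(M, budget = NULL, to_coverage = FALSE) {
  stopifnot(inherits(M, "hap_incidence"))
  if (!to_coverage && is.null(budget))
    stop("either budget or to_coverage is required")
  b <- if (to_coverage) -1L else as.integer(budget)
  run <- .iws_run(incidence_row_list(M), ncol(M$A), M$h, b)
  if (to_coverage && run$uncovered > 0L)
    stop("IWS could not cover all rows (", run$uncovered, " uncoverable)")
  res <- new_selection_result(M$animal_ids[run$selected],
                              objective = length(run$selected), M = M,
                              method = "iws")
  res$weights <- run$weights
  res
}

#' Greedy set cover baseline
#'
#' Repeatedly selects the animal carrying the most uncovered haplotype
#' rows (ties by column order) until all rows are covered. Provided as a
#' classical approximation baseline: its cover size is never below the
#' certified minimum from [solve_min_cover()] and can strictly exceed it.
#'
#' @param M a `hap_incidence` with every row carried by some animal.
#' @return a `selection_result`.
#' @export
greedy_cover <- function(M) {
  stopifnot(inherits(M, "hap_incidence"))
  run <- .greedy_cover_run(incidence_row_list(M), ncol(M$A))
  new_selection_result(M$animal_ids[run$selected],
                       objective = length(run$selected), M = M,
                       method = "greedy_cover")
}

#' Random selection baseline
#'
#' @param M a `hap_incidence`.
#' @param budget number of animals to draw without replacement.
#' @param seed optional RNG seed.
#' @return a `selection_result`.
#' @export
random_select <- function(M, budget, seed = NULL) {
  stopifnot(inherits(M, "hap_incidence"))
  if (!is.null(seed)) set.seed(seed)
  k <- min(as.integer(budget), ncol(M$A))
  idx <- sort(sample.int(ncol(M$A), k))
  new_selection_result(M$animal_ids[idx], objective = k, M = M,
                       method = "random")
}
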