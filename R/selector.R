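#' Frequency-weighted animal scores
#'
#' The weight of animal j is `c_j = sum_i h_i a_ij`: the summed population
#' frequencies of the haplotypes it carries. Animals carrying many common
#' haplotypes score high, which is what the budgeted selection maximizes.
#'
#' @param M a `hap_incidence`.
#' @return numeric vector of length n (one weight per animal column).
#' @export
compute_weights <- function(M) {
  stopifnot(inherits(M, "hap_incidence"))
  as.numeric(crossprod(M$A, M$h))
}

new_selection_result <- function(selected, objective, M = NULL,
                                 proven_optimal = NA, method = "",
                                 rounds = NULL, weights = NULL) {
  res <- list(selected = selected, objective = objective,
              proven_optimal = proven_optimal, method = method,
              rounds = rounds, weights = weights,
              coverage_counts = NULL, prop_all = NA_real_,
              prop_common = NA_real_)
  if (!is.null(M)) {
    idx <- match(selected, M$animal_ids)
    cc <- if (length(idx))
      as.integer(rowSums(M$A[, idx, drop = FALSE])) else
      integer(nrow(M$A))
    res$coverage_counts <- cc
    prop <- if (nrow(M$A)) mean(cc >= 1L) else NA_real_
    if (M$min_freq > 0) res$prop_common <- prop else res$prop_all <- prop
  }
  structure(res, class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$method, "]: ", length(x$selected),
      " animals, objective ", format(x$objective), sep = "")
  if (!is.na(x$proven_optimal))
    cat(if (isTRUE(x$proven_optimal)) " (proven optimal)" else
        " (NOT proven optimal)")
  cat("\n")
  if (!is.na(x$prop_all)) cat("  prop_all =", format(x$prop_all), "\n")
  if (!is.na(x$prop_common)) cat("  prop_common =", format(x$prop_common), "\n")
  invisible(x)
}

resolve_forced <- function(forced_in, M) {
  if (length(forced_in) == 0L) return(integer(0))
  idx <- match(as.character(forced_in), M$animal_ids)
  if (anyNA(idx)) stop("forced_in contains unknown animal ids: ",
                       paste(forced_in[is.na(idx)], collapse = ", "))
  idx
}

#' Minimum set of animals covering every haplotype
#'
#' Solves the integer program `min sum_j x_j` subject to `A x >= b`,
#' `x` binary, by exact branch and bound: the optimum is certified unless
#' the node budget is exhausted, in which case the best cover found is
#' returned with `proven_optimal = FALSE` and a warning. The default
#' `b = 1` requires every haplotype to be carried by at least one selected
#' animal; raising `b_i` for rare haplotype rows demands that many distinct
#' carriers.
#'
#' @param M a `hap_incidence` (all rows must have at least one carrier).
#' @param b per-haplotype coverage requirement: scalar or length-p vector
#'   of positive integers (default 1).
#' @param forced_in animal ids that must be part of the selection.
#' @param node_limit branch-and-bound node budget (default 2e6).
#' @return a `selection_result` with `objective` = number of selected
#'   animals (z1) and an optimality certificate flag.
#' @export
solve_min_cover <- function(M, b = 1L, forced_in = character(),
                            node_limit = 2e6) {
  stopifnot(inherits(M, "hap_incidence"))
  p <- nrow(M$A)
  b <- as.integer(rep_len(b, p))
  if (any(b < 1L)) stop("coverage requirements b must be >= 1")
  rows <- incidence_row_list(M)
  supp <- lengths(rows)
  if (any(supp == 0L))
    stop("haplotype row(s) without any carrier: ",
         paste(head(which(supp == 0L), 5L), collapse = ", "))
  bad <- which(b > supp)
  if (length(bad))
    stop("coverage requirement exceeds carrier count for row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  forced <- resolve_forced(forced_in, M)
  sol <- .bb_min_cover(rows, ncol(M$A), b, forced - 1L, node_limit)
  if (!sol$proven_optimal)
    warning("node limit reached: returning best cover found without an ",
            "optimality certificate")
  sel <- M$animal_ids[sort(sol$selected)]
  new_selection_result(sel, sol$objective, M = M,
                       proven_optimal = sol$proven_optimal,
                       method = "min_cover")
}

#' Budgeted selection maximizing frequency-weighted haplotype coverage
#'
#' Solves the integer program `max sum_j c_j x_j` subject to
#' `sum_j x_j <= n_max` and, per haplotype row, `sum_j a_ij x_j <= r_max_i`
#' (the redundancy cap), `x` binary, by exact branch and bound with an
#' optimality certificate. Weights default to [compute_weights()].
#'
#' @param M a `hap_incidence`.
#' @param n_max selection budget.
#' @param r_max redundancy cap: scalar or per-row vector of positive
#'   integers (default 2).
#' @param weights per-animal weights `c` (default `h' A`).
#' @param forced_in animal ids that must be selected (they consume budget
#'   and row caps).
#' @param node_limit branch-and-bound node budget (default 2e6).
#' @return a `selection_result` with `objective` = z2 and certificate flag.
#' @export
solve_budget <- function(M, n_max, r_max = 2L, weights = NULL,
                         forced_in = character(), node_limit = 2e6) {
  stopifnot(inherits(M, "hap_incidence"))
  n_max <- as.integer(n_max)
  if (n_max < 1L) stop("n_max must be >= 1")
  p <- nrow(M$A)
  r_max <- as.integer(rep_len(r_max, p))
  if (any(r_max < 1L)) stop("r_max must be >= 1")
  if (is.null(weights)) weights <- compute_weights(M)
  if (length(weights) != ncol(M$A)) stop("weights length mismatch")
  if (any(weights < 0)) stop("weights must be non-negative")
  rows <- incidence_row_list(M)
  forced <- resolve_forced(forced_in, M)
  if (length(forced) > n_max) stop("forced_in larger than the budget n_max")
  sol <- .bb_budget(rows, ncol(M$A), weights, n_max, r_max, forced - 1L,
                    node_limit)
  if (!sol$proven_optimal)
    warning("node limit reached: returning best selection found without an ",
            "optimality certificate")
  sel <- M$animal_ids[sol$selected]
  res <- new_selection_result(sel, sol$objective, M = M,
                              proven_optimal = sol$proven_optimal,
                              method = "budget")
  res$weights <- weights[sol$selected]
  res
}

#' Batched iterative budgeted selection
#'
#' Scales the budgeted selection to large populations by selecting `batch`
#' animals at a time (default 2, with redundancy cap `r_max = 2`): each
#' round recomputes the weights on the surviving submatrix, solves the
#' budgeted program exactly for `batch` animals, then removes the selected
#' animals and every haplotype row they carry. Haplotype frequencies `h`
#' are never recomputed; the weight of an animal in later rounds reflects
#' only haplotypes not yet carried by earlier picks.
#'
#' If every row is covered before the budget is spent, the remaining picks
#' continue on `rare` (an incidence of the below-threshold rows, when
#' supplied), else selection stops early (`on_exhaust = "stop"`).
#'
#' @param M a `hap_incidence` (typically the common-haplotype submatrix).
#' @param total_budget total number of animals to select (default 100).
#' @param batch animals selected per round (default 2).
#' @param r_max redundancy cap within a round (default 2).
#' @param rare optional `hap_incidence` of excluded rare rows used after
#'   full coverage.
#' @param on_exhaust `"rare"` or `"stop"`.
#' @param node_limit per-round branch-and-bound node budget.
#' @return a `selection_result`; `rounds` logs per-round batch size,
#'   objective, certificate and rows remaining.
#' @export
iterative_budget_select <- function(M, total_budget = 100L, batch = 2L,
                                    r_max = 2L, rare = NULL,
                                    on_exhaust = c("rare", "stop"),
                                    node_limit = 2e6) {
  stopifnot(inherits(M, "hap_incidence"))
  on_exhaust <- match.arg(on_exhaust)
  total_budget <- as.integer(total_budget)
  batch <- as.integer(batch)
  if (batch < 1L) stop("batch must be >= 1")
  n <- ncol(M$A)
  if (total_budget > n) {
    warning("total_budget exceeds the number of animals; capped at ", n)
    total_budget <- n
  }
  active_rows <- rep(TRUE, nrow(M$A))
  active_cols <- rep(TRUE, n)
  selected <- character(0)
  sel_weights <- numeric(0)
  rounds <- list()
  phase <- "common"
  cur <- M
  repeat {
    remaining <- total_budget - length(selected)
    if (remaining <= 0L) break
    if (!any(active_rows)) {
      if (phase == "common" && on_exhaust == "rare" && !is.null(rare)) {
        # continue on the excluded rare rows, same column bookkeeping
        phase <- "rare"
        cur <- rare
        active_rows <- rep(TRUE, nrow(rare$A))
        sel_idx <- match(selected, rare$animal_ids)
        cov <- rowSums(rare$A[, sel_idx, drop = FALSE]) >= 1
        active_rows[cov] <- FALSE
        if (!any(active_rows)) break
        next
      }
      break
    }
    sub <- new_incidence(
      A = cur$A[active_rows, active_cols, drop = FALSE],
      h = cur$h[active_rows],
      animal_ids = cur$animal_ids[active_cols],
      haplotype_ids = cur$haplotype_ids[active_rows],
      min_freq = 0)
    n_max <- min(batch, remaining, ncol(sub$A))
    if (n_max < 1L) break
    sol <- solve_budget(sub, n_max = n_max, r_max = r_max,
                        node_limit = node_limit)
    if (length(sol$selected) == 0L) break
    picked_idx <- match(sol$selected, cur$animal_ids)
    selected <- c(selected, sol$selected)
    sel_weights <- c(sel_weights, sol$weights)
    active_cols[picked_idx] <- FALSE
    covered <- rowSums(cur$A[, picked_idx, drop = FALSE]) >= 1
    newly <- active_rows & covered
    active_rows[newly] <- FALSE
    rounds[[length(rounds) + 1L]] <- data.frame(
      round = length(rounds) + 1L, phase = phase,
      n_selected = length(sol$selected), objective = sol$objective,
      proven_optimal = sol$proven_optimal,
      rows_covered = sum(newly), rows_remaining = sum(active_rows))
  }
  rounds <- if (length(rounds)) do.call(rbind, rounds) else NULL
  res <- new_selection_result(selected,
                              objective = sum(compute_weights(M)[
                                match(selected, M$animal_ids)]),
                              M = M,
                              proven_optimal = all(rounds$proven_optimal),
                              method = "iterative_budget", rounds = rounds)
  res$weights <- sel_weights  # round-local weight at the time of selection
  res
}

#' Coverage statistics of a selection
#'
#' Reports the fraction of haplotype rows carried by at least one selected
#' animal, against the full library and (optionally) the common-haplotype
#' submatrix.
#'
#' @param selected animal ids.
#' @param M_all `hap_incidence` over all haplotypes.
#' @param M_common optional `hap_incidence` over common haplotypes.
#' @return list with `prop_all`, `prop_common`, `coverage_counts` (against
#'   `M_all`) and the selection size.
#' @export
coverage_report <- function(selected, M_all, M_common = NULL) {
  idx <- match(as.character(selected), M_all$animal_ids)
  if (anyNA(idx)) stop("unknown animal id(s): ",
                       paste(selected[is.na(idx)], collapse = ", "))
  cc <- if (length(idx))
    as.integer(rowSums(M_all$A[, idx, drop = FALSE])) else
    integer(nrow(M_all$A))
  out <- list(n_selected = length(idx), coverage_counts = cc,
              prop_all = if (nrow(M_all$A)) mean(cc >= 1L) else NA_real_,
              prop_common = NA_real_)
  if (!is.null(M_common)) {
    idx2 <- match(as.character(selected), M_common$animal_ids)
    cc2 <- if (length(idx2))
      as.integer(rowSums(M_common$A[, idx2, drop = FALSE])) else
      integer(nrow(M_common$A))
    out$prop_common <- if (nrow(M_common$A)) mean(cc2 >= 1L) else NA_real_
  }
  out
}
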