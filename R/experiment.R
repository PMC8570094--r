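#' Specification of a benchmark experiment
#'
#' Describes one benchmarking run: simulate a scenario population, build
#' its haplotype library, and evaluate a set of selection methods either
#' in `min_cover` mode (run-to-coverage set sizes over all haplotypes) or
#' `budget` mode (coverage proportions achieved by a fixed budget).
#'
#' @param scenario 1..5 (5/10/15/30/50 generations).
#' @param replicates number of independent simulation replicates.
#' @param seed_base replicate r uses seed `seed_base + r - 1`.
#' @param budget selection budget in `budget` mode (default 100).
#' @param block_length,mismatch,min_freq library parameters.
#' @param methods subset of `"ilp"`, `"iws"`, `"ahap1"`, `"greedy"`,
#'   `"random"`.
#' @param mode `"budget"` or `"min_cover"`.
#' @param batch,r_max iterative selection parameters (budget mode).
#' @param ... overrides passed to [sim_config()] via
#'   [simulate_scenario()], e.g. `snps_per_chromosome`.
#' @return an `experiment_spec` object.
#' @export
experiment_spec <- function(scenario = 1L, replicates = 3L, seed_base = 1L,
                            budget = 100L, block_length = 100L,
                            mismatch = 0.10, min_freq = 0.01,
                            methods = c("ilp", "iws", "ahap1"),
                            mode = c("budget", "min_cover"), batch = 2L,
                            r_max = 2L, ...) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, c("ilp", "iws", "ahap1", "greedy",
                                  "random"), several.ok = TRUE)
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(scenario = as.integer(scenario),
                 replicates = as.integer(replicates),
                 seed_base = as.integer(seed_base),
                 budget = as.integer(budget),
                 block_length = as.integer(block_length),
                 mismatch = mismatch, min_freq = min_freq,
                 methods = methods, mode = mode, batch = as.integer(batch),
                 r_max = as.integer(r_max), sim_args = list(...)),
            class = "experiment_spec")
}

run_one_method <- function(method, spec, M_all, M_common, seed) {
  if (spec$mode == "min_cover") {
    res <- switch(method,
      ilp = solve_min_cover(M_all),
      iws = iws_select(M_all, to_coverage = TRUE),
      ahap1 = ahap1_select(M_all, to_coverage = TRUE),
      greedy = greedy_cover(M_all),
      random = stop("random selection has no run-to-coverage mode"))
    data.frame(method = method, z1 = length(res$selected),
               proven_optimal = isTRUE(res$proven_optimal))
  } else {
    rare <- if (any(M_all$h < spec$min_freq))
      filter_rare(M_all, spec$min_freq) else NULL
    res <- switch(method,
      ilp = iterative_budget_select(M_common, total_budget = spec$budget,
                                    batch = spec$batch, r_max = spec$r_max,
                                    rare = rare, on_exhaust = "rare"),
      # IWS prioritizes carriers of rare haplotypes, so it selects on the
      # unfiltered library; coverage is still reported on both denominators
      iws = iws_select(M_all, budget = spec$budget),
      ahap1 = ahap1_select(M_common, budget = spec$budget),
      greedy = stop("greedy baseline is a run-to-coverage method"),
      random = random_select(M_common, budget = spec$budget, seed = seed))
    cov <- coverage_report(res$selected, M_all, M_common)
    data.frame(method = method, prop_all = cov$prop_all,
               prop_common = cov$prop_common,
               n_selected = cov$n_selected)
  }
}

#' Run a benchmark experiment
#'
#' For each replicate: simulate the scenario population, build the
#' haplotype library and incidence matrix, filter common haplotypes, and
#' run every requested method. A failed method aborts only that cell (the
#' reason is recorded); partial results are still returned.
#'
#' @param spec an [experiment_spec()].
#' @param verbose print per-replicate progress.
#' @return list with `results` (one row per replicate x method) and
#'   `summary` (mean and sample SD per method).
#' @export
run_experiment <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  rows <- list()
  for (r in seq_len(spec$replicates)) {
    seed <- spec$seed_base + r - 1L
    pop <- do.call(simulate_scenario,
                   c(list(scenario = spec$scenario, seed = seed),
                     spec$sim_args))
    lib <- build_library(pop, block_length = spec$block_length,
                         mismatch = spec$mismatch)
    M_all <- build_incidence(lib)
    M_common <- filter_common(M_all, spec$min_freq)
    for (method in spec$methods) {
      cell <- tryCatch(
        run_one_method(method, spec, M_all, M_common, seed = seed),
        error = function(e) {
          warning("replicate ", r, ", method ", method, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(cell)) next
      cell$replicate <- r
      cell$seed <- seed
      rows[[length(rows) + 1L]] <- cell
      if (verbose)
        message("replicate ", r, " ", method, ": ",
                paste(names(cell)[1:2], unlist(cell[1, 1:2]),
                      collapse = " ", sep = "="))
    }
  }
  results <- do.call(rbind, rows)
  metric_cols <- intersect(c("z1", "prop_all", "prop_common"),
                           names(results))
  summ <- do.call(rbind, lapply(split(results, results$method), function(d) {
    s <- data.frame(method = d$method[1L], n = nrow(d))
    for (mc in metric_cols) {
      s[[paste0(mc, "_mean")]] <- mean(d[[mc]])
      s[[paste0(mc, "_sd")]] <- if (nrow(d) > 1L) sd(d[[mc]]) else 0
    }
    s
  }))
  rownames(summ) <- NULL
  list(results = results, summary = summ)
}

#' Independently verify a selection result against the incidence matrix
#'
#' Recomputes coverage counts and the objective from the raw matrix and
#' checks the declared constraints; any mismatch fails with diagnostics.
#'
#' @param result a `selection_result`.
#' @param M the `hap_incidence` the selection was made on.
#' @param mode `"min_cover"` or `"budget"`.
#' @param b,n_max,r_max constraints to verify (as in the solve).
#' @param weights weights used for the budget objective (default
#'   recomputed from `M`).
#' @param tol relative objective tolerance.
#' @return list with `pass` (logical) and `messages` (character).
#' @export
validate_result <- function(result, M, mode = c("budget", "min_cover"),
                            b = 1L, n_max = NULL, r_max = NULL,
                            weights = NULL, tol = 1e-9) {
  mode <- match.arg(mode)
  msgs <- character(0)
  idx <- match(result$selected, M$animal_ids)
  if (anyNA(idx)) {
    msgs <- c(msgs, paste("unknown animal ids:",
                          paste(result$selected[is.na(idx)], collapse = ", ")))
    return(list(pass = FALSE, messages = msgs))
  }
  cc <- if (length(idx))
    as.integer(rowSums(M$A[, idx, drop = FALSE])) else integer(nrow(M$A))
  if (!is.null(result$coverage_counts) &&
      !identical(cc, result$coverage_counts))
    msgs <- c(msgs, "stored coverage_counts disagree with recomputation")
  if (mode == "min_cover") {
    bb <- rep_len(as.integer(b), nrow(M$A))
    uncov <- which(cc < bb)
    if (length(uncov))
      msgs <- c(msgs, paste("uncovered haplotype rows:",
                            paste(head(uncov, 10L), collapse = ", ")))
    obj <- length(idx)
  } else {
    if (!is.null(n_max) && length(idx) > n_max)
      msgs <- c(msgs, sprintf("selection size %d exceeds n_max %d",
                              length(idx), n_max))
    if (!is.null(r_max)) {
      rm_ <- rep_len(as.integer(r_max), nrow(M$A))
      over <- which(cc > rm_)
      if (length(over))
        msgs <- c(msgs, paste("redundancy cap violated on rows:",
                              paste(head(over, 10L), collapse = ", ")))
    }
    if (is.null(weights)) weights <- compute_weights(M)
    obj <- sum(weights[idx])
  }
  rel <- abs(obj - result$objective) / max(1, abs(obj))
  if (rel > tol)
    msgs <- c(msgs, sprintf("objective mismatch: recomputed %g vs stored %g",
                            obj, result$objective))
  list(pass = length(msgs) == 0L, messages = msgs)
}
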