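naive_iws <- function(A, h, budget) {
  covered <- rep(FALSE, nrow(A))
  taken <- rep(FALSE, ncol(A))
  picks <- integer(0)
  for (t in seq_len(budget)) {
    w <- colSums(A[!covered, , drop = FALSE] / h[!covered])
    w[taken] <- -Inf
    wmax <- max(w)
    if (!is.finite(wmax) || wmax <= 1e-12) break
    # ties within relative 1e-9 of the maximum go to the lowest index
    j <- which(w >= wmax - 1e-9 * max(1, wmax))[1]
    picks <- c(picks, j)
    taken[j] <- TRUE
    covered <- covered | A[, j] == 1
    if (all(covered)) break
  }
  picks
}

test_that("AHAP1 ranks once by static weight with id tie-breaks", {
  A <- cbind(c(1, 1, 1), c(1, 0, 0))
  M <- as_incidence(A, h = c(1, 1, 1))  # weights c = (3, 1)
  res <- ahap1_select(M, budget = 1)
  expect_equal(res$selected, "1")
  expect_equal(res$weights, 3)
  # equal weights: selection order follows column order
  Aeq <- cbind(c(1, 0), c(0, 1))
  req <- ahap1_select(as_incidence(Aeq, h = c(0.5, 0.5)), budget = 2)
  expect_equal(req$selected, c("1", "2"))
})

test_that("IWS favors carriers of rare haplotypes", {
  # animal 1 carries only a 1% haplotype, animal 2 only a 50% one:
  # inverse-frequency weights 100 vs 2
  A <- cbind(c(1, 0), c(0, 1))
  M <- as_incidence(A, h = c(0.01, 0.5))
  res <- iws_select(M, budget = 2)
  expect_equal(res$selected, c("1", "2"))
  expect_equal(res$weights, c(100, 2))
})

test_that("IWS matches an independent reimplementation pick by pick", {
  set.seed(19)
  for (t in 1:8) {
    n <- sample(6:12, 1)
    p <- sample(5:18, 1)
    A <- random_incidence_matrix(n, p)
    h <- rowSums(A) / (2 * n)
    M <- as_incidence(A, h = h)
    budget <- sample(2:n, 1)
    res <- iws_select(M, budget = budget)
    expect_equal(match(res$selected, M$animal_ids),
                 naive_iws(A, h, budget))
  }
})

test_that("greedy cover is exact on trivial instances, suboptimal in general", {
  M <- as_incidence(diag(4))
  expect_equal(length(greedy_cover(M)$selected), 4)
  A1 <- cbind(rep(1, 4), c(1, 0, 0, 0))
  expect_equal(length(greedy_cover(as_incidence(A1))$selected), 1)
  # classical trap: the large middle set draws greedy away from the
  # two-set optimum
  A <- cbind(c(1, 1, 1, 0, 0, 0),
             c(0, 0, 0, 1, 1, 1),
             c(0, 1, 1, 1, 1, 0))
  M2 <- as_incidence(A)
  greedy <- greedy_cover(M2)
  exact <- solve_min_cover(M2)
  expect_equal(exact$objective, 2)
  expect_equal(length(greedy$selected), 3)
  expect_equal(greedy$selected[1], "3")
})

test_that("no heuristic beats the certified minimum cover", {
  set.seed(29)
  for (t in 1:5) {
    A <- random_incidence_matrix(sample(6:12, 1), sample(6:20, 1))
    M <- as_incidence(A)
    z1 <- solve_min_cover(M)$objective
    expect_gte(length(iws_select(M, to_coverage = TRUE)$selected), z1)
    expect_gte(length(ahap1_select(M, to_coverage = TRUE)$selected), z1)
    expect_gte(length(greedy_cover(M)$selected), z1)
  }
})

test_that("iterative ILP selection dominates AHAP1 and random on coverage", {
  props <- t(vapply(1:3, function(r) {
    pop <- small_scenario_pop(seed = 60 + r)
    M <- build_incidence(build_library(pop))
    Mc <- filter_common(M, 0.01)
    bud <- 12
    lp <- iterative_budget_select(Mc, total_budget = bud)
    ah <- ahap1_select(Mc, budget = bud)
    rnd <- mean(vapply(1:5, function(s)
      coverage_report(random_select(Mc, bud, seed = s)$selected,
                      Mc)$prop_all, numeric(1)))
    c(lp = coverage_report(lp$selected, M, Mc)$prop_common,
      ahap = coverage_report(ah$selected, M, Mc)$prop_common,
      random = rnd)
  }, numeric(3)))
  expect_gte(mean(props[, "lp"]), mean(props[, "ahap"]))
  expect_gte(mean(props[, "lp"]), mean(props[, "random"]))
})

test_that("random selection respects the budget and the seed", {
  A <- random_incidence_matrix(10, 8)
  M <- as_incidence(A)
  r1 <- random_select(M, 4, seed = 1)
  r2 <- random_select(M, 4, seed = 1)
  expect_identical(r1$selected, r2$selected)
  expect_equal(length(r1$selected), 4)
})
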