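test_that("animal weights are frequency-weighted carriage sums", {
  # an animal carrying two haplotypes of frequency 0.5 each scores 1.0
  A <- matrix(c(1, 1), ncol = 1)
  M <- as_incidence(A, h = c(0.5, 0.5))
  expect_equal(compute_weights(M), 1.0)
  # an animal carrying nothing scores 0
  A2 <- cbind(c(1, 1), c(0, 0))
  expect_equal(compute_weights(as_incidence(A2, h = c(0.5, 0.5))),
               c(1.0, 0.0))
  # random instances match the naive double loop
  set.seed(14)
  for (t in 1:5) {
    A3 <- random_incidence_matrix(4, 6)
    h <- runif(6)
    M3 <- as_incidence(A3, h = h)
    naive <- vapply(seq_len(ncol(A3)),
                    function(j) sum(h * A3[, j]), numeric(1))
    expect_equal(compute_weights(M3), naive)
  }
})

test_that("minimum cover handles the trivial extremes", {
  M <- as_incidence(diag(3))
  res <- solve_min_cover(M)
  expect_equal(res$objective, 3)          # every haplotype private
  expect_setequal(res$selected, c("1", "2", "3"))
  expect_true(res$proven_optimal)

  A <- cbind(rep(1, 5), c(1, 0, 0, 0, 0))  # animal 1 carries everything
  res2 <- solve_min_cover(as_incidence(A))
  expect_equal(res2$objective, 1)
  expect_equal(res2$selected, "1")
})

test_that("coverage demands above one and forced animals are honored", {
  A <- cbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  M <- as_incidence(A)
  res <- solve_min_cover(M, b = c(2, 1, 1))
  cc <- as.integer(Matrix::rowSums(M$A[, match(res$selected, M$animal_ids),
                                       drop = FALSE]))
  expect_gte(cc[1], 2)
  expect_equal(res$objective, oracle_min_cover(A, b = c(2, 1, 1)))
  # infeasible demand names the row
  expect_error(solve_min_cover(M, b = c(3, 1, 1)), "row")
  # forced animal appears in the solution
  resf <- solve_min_cover(M, forced_in = "3")
  expect_true("3" %in% resf$selected)
})

test_that("budgeted selection handles the trivial extremes", {
  set.seed(3)
  A <- random_incidence_matrix(5, 8)
  M <- as_incidence(A)
  w <- compute_weights(M)
  # unconstrained budget selects every animal with positive weight
  res <- solve_budget(M, n_max = ncol(A), r_max = ncol(A))
  expect_setequal(res$selected, M$animal_ids[w > 0])
  expect_equal(res$objective, sum(w[w > 0]))
  # r_max = 1 forbids selecting two animals sharing any haplotype
  res1 <- solve_budget(M, n_max = 2, r_max = 1)
  idx <- match(res1$selected, M$animal_ids)
  if (length(idx) == 2)
    expect_true(all(A[, idx[1]] + A[, idx[2]] <= 1))
  expect_equal(res1$objective, oracle_budget(A, w, n_max = 2, r_max = 1))
})

test_that("a budget of two under cap two picks the top pair by weight", {
  set.seed(9)
  A <- random_incidence_matrix(6, 10)
  M <- as_incidence(A)
  w <- compute_weights(M)
  res <- solve_budget(M, n_max = 2, r_max = 2)
  expect_equal(res$objective, sum(sort(w, decreasing = TRUE)[1:2]))
})

test_that("solver optima equal exhaustive enumeration on random instances", {
  set.seed(27)
  for (t in 1:10) {
    n <- sample(5:12, 1)
    p <- sample(4:20, 1)
    A <- random_incidence_matrix(n, p, runif(1, 0.2, 0.5))
    M <- as_incidence(A)
    res <- solve_min_cover(M)
    expect_equal(res$objective, oracle_min_cover(A))
    expect_true(res$proven_optimal)
    w <- compute_weights(M)
    nmax <- sample(2:4, 1)
    rmax <- sample(1:2, 1)
    resb <- solve_budget(M, n_max = nmax, r_max = rmax)
    expect_equal(resb$objective, oracle_budget(A, w, nmax, rmax))
    expect_true(resb$proven_optimal)
    # reported objective is consistent with the selected set
    expect_equal(resb$objective,
                 sum(w[match(resb$selected, M$animal_ids)]))
  }
})

test_that("iterative batching removes covered rows between rounds", {
  pop <- small_scenario_pop(seed = 17)
  M <- build_incidence(build_library(pop))
  Mc <- filter_common(M, 0.01)
  res <- iterative_budget_select(Mc, total_budget = 10, batch = 2, r_max = 2)
  expect_equal(length(res$selected), 10)
  expect_equal(nrow(res$rounds), 5)              # 10 / 2 rounds
  expect_true(all(res$rounds$n_selected == 2))
  expect_true(all(res$rounds$proven_optimal))
  # rows remaining decreases by exactly the rows covered each round
  rr <- res$rounds
  expect_equal(rr$rows_remaining[-nrow(rr)] - rr$rows_covered[-1],
               rr$rows_remaining[-1])
  # no animal repeats
  expect_equal(anyDuplicated(res$selected), 0)
  # a single round with batch = budget is one exact solve
  one <- iterative_budget_select(Mc, total_budget = 4, batch = 4, r_max = 2)
  expect_equal(nrow(one$rounds), 1)
  # odd budget: final round selects a single animal
  odd <- iterative_budget_select(Mc, total_budget = 5, batch = 2, r_max = 2)
  expect_equal(length(odd$selected), 5)
  expect_equal(odd$rounds$n_selected[nrow(odd$rounds)], 1)
})

test_that("coverage proportion is non-decreasing in the budget", {
  pop <- small_scenario_pop(seed = 23)
  M <- build_incidence(build_library(pop))
  Mc <- filter_common(M, 0.01)
  props <- vapply(c(4, 8, 16, 32), function(bud) {
    r <- iterative_budget_select(Mc, total_budget = bud)
    coverage_report(r$selected, M, Mc)$prop_common
  }, numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("coverage reports match a naive recount", {
  set.seed(31)
  A <- random_incidence_matrix(8, 12)
  M <- as_incidence(A)
  Mc <- filter_common(M, 0.15)
  expect_equal(coverage_report(M$animal_ids, M)$prop_all, 1.0)
  expect_equal(coverage_report(character(0), M)$prop_all, 0.0)
  for (t in 1:5) {
    sel <- as.character(sample(8, 3))
    rep_ <- coverage_report(sel, M, Mc)
    idx <- as.integer(sel)
    expect_equal(rep_$prop_all,
                 mean(rowSums(A[, idx, drop = FALSE]) >= 1))
  }
  expect_error(coverage_report("zebra", M), "unknown")
})

test_that("independent validation flags tampered selections", {
  set.seed(35)
  A <- random_incidence_matrix(6, 10)
  M <- as_incidence(A)
  res <- solve_min_cover(M)
  expect_true(validate_result(res, M, mode = "min_cover")$pass)
  tampered <- res
  tampered$selected <- tampered$selected[-1]
  v <- validate_result(tampered, M, mode = "min_cover")
  expect_false(v$pass)
  expect_true(any(grepl("uncovered", v$messages)))
  wrong_obj <- res
  wrong_obj$objective <- res$objective + 1
  wrong_obj$coverage_counts <- NULL
  expect_false(validate_result(wrong_obj, M, mode = "min_cover")$pass)
})
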