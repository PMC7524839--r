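test_that("seeding keeps only each column's dominant dense-fit entries", {
  seeds <- seed_population(dyn_ctx(), target_size = 40, seed = 1)
  expect_gte(length(seeds), 40 - 1)
  expect_true(all(vapply(seeds, function(m) all(m[1, ] == 1), logical(1))))
  expect_true(all(vapply(seeds, function(m) all(colSums(m) >= 1), logical(1))))
  # uniqueness
  hashes <- vapply(seeds, function(m) paste(m, collapse = ""), character(1))
  expect_equal(anyDuplicated(hashes), 0)
})

test_that("the bisection threshold keeps only maximal-magnitude entries", {
  expect_equal(which(abs(c(5, 0.1, 0.1)) > dyndisc:::bisect_threshold(c(5, 0.1, 0.1))),
               1L)
  expect_equal(which(abs(c(2, 2, 0.5)) > dyndisc:::bisect_threshold(c(2, 2, 0.5))),
               c(1L, 2L))
})

test_that("mutation schedule: start, halvings, floor and zero tail", {
  # printed formula: r_mut = 0.05, N = 60 -> ceil(log2(3) + 1) = 3 halvings
  expect_equal(max(2, ceiling(log2(0.05 * 60) + 1)), 3)
  expect_equal(mutation_rate(1, 100, 60), 0.05)
  expect_equal(mutation_rate(95, 100, 60), 0)
  rates <- vapply(1:100, mutation_rate, numeric(1), total_gens = 100,
                  n_elements = 60)
  expect_true(all(diff(rates) <= 0))
  expect_equal(length(unique(rates[rates > 0])), 4)  # 0.05 plus 3 halvings
  # tiny r_mut * N clamps the halvings at 2
  r_tiny <- vapply(1:100, mutation_rate, numeric(1), total_gens = 100,
                   n_elements = 60, r_mut = 0.001)
  expect_equal(length(unique(r_tiny[r_tiny > 0])), 3)  # 0.05 plus 2 halvings
})

test_that("crossover keeps shared bits and flips complete under rate 1", {
  lib <- build_library(2)
  a <- dyndisc:::new_mask(matrix(1L, 10, 2), lib)
  withr::with_seed(4, {
    # identical parents, no mutation: child equals parent
    expect_equal(dyndisc:::cross_and_mutate(a, a, 0, lib), a)
    # all-ones x all-zeros at rate 0: bits are Bernoulli(1/2)
    b <- dyndisc:::new_mask(matrix(0L, 10, 2), lib)
    kids <- replicate(400, dyndisc:::cross_and_mutate(a, b, 0, lib))
    free <- as.vector(kids[-1, , ])   # constant row is pinned to 1
    expect_gt(binom.test(sum(free), length(free), 0.5)$p.value, 1e-4)
    # rate 1 flips every free bit (then the constant row is repaired)
    flip <- dyndisc:::cross_and_mutate(a, a, 1, lib)
    expect_true(all(flip[1, ] == 1))
    expect_true(all(flip[-1, ] == 0))
  })
})

test_that("elitism under a deterministic objective is monotone and reproducible", {
  ctx <- dyn_ctx()
  obj <- gof_objective(ctx)
  evo1 <- run_evolution(ctx, obj, generations = 4, population = 20,
                        n_elites = 5, seed = 77)
  evo2 <- run_evolution(ctx, obj, generations = 4, population = 20,
                        n_elites = 5, seed = 77)
  expect_true(all(diff(evo1$history$best) <= 1e-12))
  expect_identical(evo1$elites$mask, evo2$elites$mask)
  expect_equal(evo1$elites$fitness, evo2$elites$fitness)
  expect_equal(nrow(evo1$elites), 5)
})

test_that("a constant objective triggers early termination", {
  ctx <- dyn_ctx()
  evo <- run_evolution(ctx, function(m) list(fitness = 0.5),
                       generations = 50, population = 20, n_elites = 5,
                       seed = 3)
  expect_lt(nrow(evo$history), 50)
})

test_that("objective failures are absorbed as worst fitness", {
  ctx <- dyn_ctx()
  flaky <- function(m) {
    if (sum(m) %% 2 == 0) stop("boom")
    list(fitness = 0.1, error_term = 0.1, sparsity_term = 0.1)
  }
  evo <- run_evolution(ctx, flaky, generations = 2, population = 16,
                       n_elites = 4, seed = 5)
  expect_true(all(is.finite(evo$elites$fitness)))
})
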