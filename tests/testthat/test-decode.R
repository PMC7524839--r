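subset_ctx_one_label <- function(ctx) {
  idx <- which(ctx$stimulus_index == 1)
  dyndisc:::subset_context(ctx, idx)
}

test_that("F1/CCR arithmetic follows the definitions", {
  sc <- score_classification(c(1, 1, 2, 2), c(1, 1, 2, 1))
  expect_equal(unname(sc$f1["1"]), 2 * 2 / (2 * 2 + 1 + 0))
  expect_equal(unname(sc$f1["2"]), 2 * 1 / (2 * 1 + 0 + 1))
  expect_equal(sc$ccr, 0.75)
  # constant classifier on balanced labels: CCR = 1/k exactly
  sc2 <- score_classification(rep(1:4, each = 5), rep(1, 20),
                              labels = as.character(1:4))
  expect_equal(sc2$ccr, 0.25)
  expect_true(all(sc2$f1 >= 0 & sc2$f1 <= 1))
})

test_that("objective fitness is 0.8 error + 0.2 sparsity", {
  ctx <- dyn_ctx()
  obj <- classification_objective(ctx, rounds = 4)
  m <- seed_population(ctx, target_size = 5, seed = 2)[[1]]
  withr::with_seed(6, r <- obj(m))
  expect_equal(r$fitness, 0.8 * r$error_term + 0.2 * r$sparsity_term)
  expect_equal(r$sparsity_term, mean(m != 0))
  # the fixture's stimulus-coded oscillations are nearly separable
  expect_lt(r$error_term, 0.35)
  expect_error(classification_objective(subset_ctx_one_label(ctx)),
               ">= 2 stimulus labels")
})

test_that("shuffled labels push the classification objective to chance", {
  ctx <- dyn_ctx()
  withr::with_seed(8, {
    shuffled <- sample(ctx$stimulus_index)
    obj <- classification_objective(ctx, labels = shuffled, rounds = 8)
    m <- seed_population(ctx, target_size = 5, seed = 2)[[1]]
    r <- obj(m)
  })
  # macro-F1 for 3 balanced shuffled labels concentrates near chance
  expect_gt(r$error_term, 0.35)
})

test_that("goodness of fit hits the perfect-model and constant-predictor limits", {
  # 2-D linear decay: the cubic library contains the truth
  lib <- build_library(2)
  A <- matrix(c(-0.02, 0.01, -0.01, -0.03), 2, 2)
  v <- matrix(0, 400, 2); v[1, ] <- c(3, -2)
  for (t in 2:400) v[t, ] <- drop(v[t - 1, ] + A %*% v[t - 1, ])
  traj <- tibble::tibble(trial_id = "lin", stimulus_index = 1L,
                         points = list(v))
  ctx <- prepare_sindy_data(traj, lib)
  mask_lin <- matrix(0L, 10, 2); mask_lin[1:3, ] <- 1L
  r <- gof_objective(ctx)(mask_lin)
  expect_lt(r$error_term, 0.02)
  expect_equal(r$fitness, 0.8 * r$error_term + 0.2 * r$sparsity_term)
  # constant-only model on oscillatory data explains nothing
  osc <- matrix(c(cos(2 * pi * (0:399) / 8), sin(2 * pi * (0:399) / 8)),
                ncol = 2)
  ctx2 <- prepare_sindy_data(
    tibble::tibble(trial_id = "osc", stimulus_index = 1L, points = list(osc)),
    lib)
  mask_const <- matrix(0L, 10, 2); mask_const[1, ] <- 1L
  r2 <- gof_objective(ctx2)(mask_const)
  expect_gt(r2$error_term, 0.9)
})

test_that("true Lorenz support beats a random equal-size support", {
  xyz <- lorenz_states()[seq(1, 3000, by = 2), ]
  ctx <- prepare_sindy_data(tibble::tibble(trial_id = "lz",
                                           stimulus_index = 1L,
                                           points = list(xyz)))
  obj <- gof_objective(ctx)
  true_mask <- lorenz_true_mask()
  r_true <- obj(true_mask)
  withr::with_seed(13, {
    worse <- 0L
    for (i in 1:5) {
      rand <- matrix(0L, 20, 3)
      for (k in 1:3) rand[sample(2:20, sum(true_mask[-1, k])), k] <- 1L
      rand[1, ] <- 1L
      if (obj(rand)$error_term > r_true$error_term) worse <- worse + 1L
    }
  })
  expect_gte(worse, 4L)
})

test_that("ensemble voting follows majority, rank tie-break, and median", {
  votes <- matrix(c(rep("A", 23), rep("B", 22)), nrow = 1)
  expect_equal(dyndisc:::vote_mode(votes, 1:45), "A")
  v3 <- matrix(c(rep("A", 15), rep("B", 15), rep("C", 15)), nrow = 1)
  ranks <- 1:45; ranks[16] <- 45; ranks[45] <- 16  # best member votes B
  expect_equal(dyndisc:::vote_mode(v3, ranks), "B")
  expect_equal(median(1:45), 23)
})

test_that("trained ensemble has one member per elite and beats chance when separable", {
  ctx <- dyn_ctx()
  labels <- factor(ctx$stimulus_index)
  obj <- classification_objective(ctx, rounds = 3)
  withr::with_seed(14, {
    evo <- run_evolution(ctx, obj, generations = 3, population = 16,
                         n_elites = 5, seed = 21)
    ens <- train_ensemble(evo$elites, ctx, labels, final_trees = 25)
    expect_length(ens$members, 5)
    pred <- predict_ensemble(ens, ctx)
  })
  # training-distribution sanity: well above the 1/3 chance level
  expect_gt(mean(pred == as.character(labels)), 0.8)
})

test_that("deflection decoder separates disjoint distributions but not identical ones", {
  withr::with_seed(15, {
    labels <- rep(1:3, each = 8)
    sep <- rnorm(24, mean = c(0, 50, 100)[labels], sd = 1)
    r_sep <- deflection_decoder(sep, labels, reps = 10, seed = 1)
    null <- rnorm(24, mean = 10, sd = 5)
    r_null <- deflection_decoder(null, labels, reps = 30, seed = 2)
  })
  expect_gt(r_sep$ccr, 0.95)
  # repetitions reuse the same 24 trials (dependent predictions) and
  # hold-one-out on null data carries a known below-chance bias, so the
  # band is exact binomial at the distinct-trial count, 99.9% level
  band <- dyndisc:::chance_interval(24, 1 / 3, level = 0.999)
  expect_gte(r_null$ccr, band["lower"] - 1e-9)
  expect_lte(r_null$ccr, band["upper"] + 1e-9)
})

test_that("outer holdout reaches the ceiling on separable data and chance on surrogates", {
  st <- dyn_fixture()
  cfg <- tiny_config()
  res <- outer_holdout(st, mode = "dynamical", config = cfg, seed = 31)
  expect_gt(res$ccr, 2 * 1 / 3)  # well above chance for coded dynamics
  expect_true(all(res$predictions$truth %in% c("1", "2", "3")))
  expect_equal(nrow(res$predictions), 3 * cfg$outer_reps)
  sur <- outer_holdout(st, mode = "dynamical", config = cfg, surrogate = TRUE,
                       seed = 32)
  band <- dyndisc:::chance_interval(nrow(dyn_fixture()), 1 / 3, level = 0.999)
  expect_gte(sur$ccr, band["lower"] - 1e-9)
  expect_lte(sur$ccr, band["upper"] + 1e-9)
})
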