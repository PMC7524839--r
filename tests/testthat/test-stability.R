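# coefficient object encoding a known polynomial system exactly, with
# nontrivial normalization statistics taken from sample data
coeffs_from_system <- function(d, rhs, sample_points, support) {
  lib <- build_library(d)
  nz <- normalize_library(poly_features(sample_points, lib), lib)
  dv <- rhs(sample_points)
  mask <- matrix(0L, nrow(lib$powers), d)
  for (k in seq_len(d)) mask[match(support[[k]], lib$term_names), k] <- 1L
  mask[1, ] <- 1L
  fit_coefficients(nz$theta_z, dv, mask, lib, nz$norm)
}

lorenz_coeffs <- function(rho, dt = 1) {
  set.seed(41)
  pts <- cbind(runif(400, -20, 20), runif(400, -25, 25), runif(400, -5, 60))
  rhs <- function(v) {
    dt * cbind(10 * (v[, 2] - v[, 1]),
               v[, 1] * (rho - v[, 3]) - v[, 2],
               v[, 1] * v[, 2] - 8 / 3 * v[, 3])
  }
  coeffs_from_system(3, rhs, pts,
                     list(c("x1", "x2"), c("x1", "x2", "x1*x3"),
                          c("x3", "x1*x2")))
}

test_that("1-D linear decay has a single fixed point at the origin", {
  set.seed(42)
  pts <- matrix(runif(200, -3, 3), ncol = 1)
  co <- coeffs_from_system(1, function(v) -v, pts, list("x1"))
  fp <- find_fixed_points(co)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$coords[[1]], 0, tolerance = 1e-8)
  cl <- classify_fixed_points(co, fp)
  expect_true("convergent" %in% cl$klass[[1]])
  expect_true(cl$net_convergent[1])
})

test_that("Lorenz fixed points and their stability match the closed form", {
  co <- lorenz_coeffs(28, dt = 0.01)  # scaled time does not move fixed points
  fp <- find_fixed_points(co, box = c(30, 30, 60), n_starts = 150, seed = 2)
  expect_equal(nrow(fp), 3)
  zs <- sort(vapply(fp$coords, function(p) p[3], numeric(1)))
  expect_equal(zs, c(0, 27, 27), tolerance = 1e-6)
  a <- sqrt(8 / 3 * 27)
  xs <- sort(vapply(fp$coords, function(p) p[1], numeric(1)))
  expect_equal(xs, c(-a, 0, a), tolerance = 1e-6)
  # non-origin points at rho = 28 are unstable spirals
  cl <- classify_fixed_points(co, fp)
  wings <- which(abs(vapply(cl$coords, function(p) p[3], numeric(1)) - 27) < 1)
  for (w in wings) {
    expect_true("oscillatory" %in% cl$klass[[w]])
    expect_true("divergent" %in% cl$klass[[w]])
    expect_true(cl$net_convergent[w])  # trace is still negative
  }
  # residual invariant holds at every reported point
  expect_true(all(fp$residual < 1e-8))
  # below rho = 1 only the origin remains
  co2 <- lorenz_coeffs(0.5, dt = 0.01)
  fp2 <- find_fixed_points(co2, box = c(30, 30, 60), n_starts = 100, seed = 3)
  expect_equal(nrow(fp2), 1)
  expect_lt(max(abs(fp2$coords[[1]])), 1e-6)
})

test_that("eigenvalue classification rules apply as stated", {
  # dv1 = -v1 + 2 v2, dv2 = -2 v1 - v2: eigenvalues -1 +/- 2i
  set.seed(44)
  pts <- matrix(runif(400, -3, 3), ncol = 2)
  co <- coeffs_from_system(2, function(v) cbind(-v[, 1] + 2 * v[, 2],
                                                -2 * v[, 1] - v[, 2]),
                           pts, list(c("x1", "x2"), c("x1", "x2")))
  cl <- classify_fixed_points(co, find_fixed_points(co, box = 5, seed = 4))
  expect_setequal(cl$klass[[1]], c("oscillatory", "convergent"))
  ev <- sort(Im(cl$eigenvalues[[1]]))
  expect_equal(ev, c(-2, 2), tolerance = 1e-6)
})

test_that("Jacobian of a fitted linear system matches eig(A) within 1%", {
  # fit from trajectory data (not hand-coded): de-normalization correctness
  A <- matrix(c(-0.03, 0.02, -0.02, -0.01), 2, 2)
  v <- matrix(0, 500, 2); v[1, ] <- c(2, 1)
  for (t in 2:500) v[t, ] <- drop(v[t - 1, ] + A %*% v[t - 1, ])
  lib <- build_library(2)
  ctx <- prepare_sindy_data(tibble::tibble(trial_id = "a", stimulus_index = 1L,
                                           points = list(v)), lib)
  mask <- matrix(0L, 10, 2); mask[1:3, ] <- 1L
  co <- dyndisc:::fit_trajectory_coeffs(ctx, 1, mask)
  J <- dyndisc:::jacobian_at(co, c(0, 0))
  evJ <- sort(Re(eigen(J)$values))
  evA <- sort(Re(eigen(A)$values))
  expect_lt(max(abs(evJ - evA) / abs(evA)), 0.01)
})

test_that("the Hopf crossing flips stability of the Lorenz wings", {
  below <- classify_fixed_points(lorenz_coeffs(22, 0.01),
                                 find_fixed_points(lorenz_coeffs(22, 0.01),
                                                   box = c(30, 30, 60), seed = 5))
  above <- classify_fixed_points(lorenz_coeffs(28, 0.01),
                                 find_fixed_points(lorenz_coeffs(28, 0.01),
                                                   box = c(30, 30, 60), seed = 6))
  wing_stable <- function(cl) {
    w <- which(vapply(cl$coords, function(p) p[3], numeric(1)) > 1)
    all(vapply(cl$klass[w], function(k) "convergent" %in% k, logical(1)))
  }
  expect_true(wing_stable(below))
  expect_false(wing_stable(above))
})

test_that("regime summary aggregates counts and fractions per stimulus", {
  set.seed(45)
  pts <- matrix(runif(200, -3, 3), ncol = 1)
  co <- coeffs_from_system(1, function(v) -v, pts, list("x1"))
  fp <- classify_fixed_points(co, find_fixed_points(co))
  tab <- dplyr::bind_rows(
    dplyr::mutate(fp, trial_id = "t1", stimulus_index = 1L),
    dplyr::mutate(fp, trial_id = "t2", stimulus_index = 1L))
  out <- regime_summary(tab)
  expect_equal(out$n_trials, 2)
  expect_equal(out$mean_fp_count, 1)
  expect_equal(out$frac_net_convergent, 1)
  expect_equal(nrow(regime_summary(tab[0, ])), 0)
})
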