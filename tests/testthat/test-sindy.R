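test_that("library enumeration matches stars-and-bars counts", {
  expect_equal(build_library(1)$term_names, c("1", "x1", "x1^2", "x1^3"))
  expect_equal(nrow(build_library(2)$powers), 10)
  expect_equal(nrow(build_library(3)$powers), 20)
  lib <- build_library(3)
  expect_true(all(rowSums(lib$powers) <= 3))
  expect_equal(lib$term_names[1], "1")
})

de_times <- function(t) t[3:(length(t) - 2)]

test_that("derivative stencil is exact for polynomials and accurate for sines", {
  # ramp: all interior derivatives equal the slope
  de <- estimate_derivatives(cbind(0.5 * (0:49)))
  expect_equal(de$dv[, 1], rep(0.5, 46), tolerance = 1e-12)
  # sine at 5 Hz, 1 kHz sampling: error below 1e-3 of derivative amplitude
  t <- 0:999
  x <- sin(2 * pi * 5 * t / 1000)
  de <- estimate_derivatives(cbind(x))
  truth <- (2 * pi * 5 / 1000) * cos(2 * pi * 5 * de_times(t) / 1000)
  interior <- 2:(length(truth) - 1)  # edge smoothing uses truncated windows
  expect_lt(max(abs(de$dv[interior, 1] - truth[interior])),
            1e-3 * (2 * pi * 5 / 1000))
  expect_error(estimate_derivatives(cbind(1:5)), "too short")
})

test_that("Z-scoring is exact, exempts the constant, and round-trips", {
  lib <- build_library(2)
  set.seed(8)
  th <- poly_features(matrix(rnorm(200), ncol = 2), lib)
  nz <- normalize_library(th, lib)
  nonconst <- -1
  expect_lt(max(abs(colMeans(nz$theta_z[, nonconst]))), 1e-12)
  expect_lt(max(abs(apply(nz$theta_z[, nonconst], 2, sd) - 1)), 1e-12)
  expect_equal(nz$theta_z[, 1], rep(1, 100))
  back <- sweep(sweep(nz$theta_z, 2, nz$norm$sigma, "*"), 2, nz$norm$mu, "+")
  expect_equal(back, th, tolerance = 1e-12)
  # zero-variance non-constant column is named in the error
  th2 <- th; th2[, 3] <- 2
  expect_error(normalize_library(th2, lib), lib$term_names[3], fixed = TRUE)
})

test_that("masked fit recovers a linear law and zeroes unselected terms", {
  lib <- build_library(1)
  set.seed(9)
  x <- matrix(rnorm(500), ncol = 1)
  dv <- 2 * x
  th <- poly_features(x, lib)
  nz <- normalize_library(th, lib)
  mask <- matrix(c(1, 1, 0, 0), 4, 1)
  co <- fit_coefficients(nz$theta_z, dv, mask, lib, nz$norm)
  raw <- denormalize_coefficients(co)
  expect_equal(raw[2, 1], 2, tolerance = 1e-10)
  expect_equal(raw[3:4, 1], c(0, 0))
  expect_error(fit_coefficients(nz$theta_z, dv, matrix(0, 4, 1), lib, nz$norm),
               ">= 1 term")
  # residual orthogonality to selected columns (normal equations)
  res <- dv - nz$theta_z %*% co$xi
  expect_lt(max(abs(crossprod(nz$theta_z[, 1:2], res))), 1e-8 * nrow(x))
})

test_that("clean Lorenz states under the true support recover parameters to <1%", {
  co <- fit_lorenz_states()
  raw <- denormalize_coefficients(co) / 0.002  # fitting timestep
  tn <- co$library$term_names
  got <- c(sigma1 = -raw[match("x1", tn), 1], sigma2 = raw[match("x2", tn), 1],
           rho = raw[match("x1", tn), 2], xz = -raw[match("x1*x3", tn), 2],
           y = -raw[match("x2", tn), 2],
           beta = -raw[match("x3", tn), 3], xy = raw[match("x1*x2", tn), 3])
  truth <- c(10, 10, 28, 1, 1, 8 / 3, 1)
  expect_lt(max(abs(got - truth) / truth), 0.01)
  expect_true(all(co$fit_r2 > 0.999))
})

test_that("Euler integration applies the de-normalization bookkeeping", {
  # 1-D dv = -v via a hand-built coefficient object
  lib <- build_library(1)
  v <- matrix(seq(-2, 2, length.out = 200), ncol = 1)
  th <- poly_features(v, lib)
  nz <- normalize_library(th, lib)
  mask <- matrix(c(1, 1, 0, 0), 4, 1)
  co <- fit_coefficients(nz$theta_z, -v, mask, lib, nz$norm)
  sim <- integrate_model(co, ic = 1, n_steps = 1)
  # one Euler step of dv=-v from 1: 1 + (-1) = 0
  expect_equal(sim$path[2, 1], 0, tolerance = 1e-10)
  # constant-only coefficients: straight-line drift at the constant rate
  co2 <- fit_coefficients(nz$theta_z, matrix(0.3, 200, 1),
                          matrix(c(1, 0, 0, 0), 4, 1), lib, nz$norm)
  sim2 <- integrate_model(co2, ic = 0, n_steps = 10)
  expect_equal(sim2$path[, 1], 0.3 * (0:10), tolerance = 1e-10)
})

test_that("integration matches the matrix-exponential solution to first order", {
  # dv = A v with slow decay; Euler error is O(h^2) per step
  lib <- build_library(2)
  set.seed(10)
  v <- matrix(rnorm(600), ncol = 2)
  A <- matrix(c(-0.01, 0.004, -0.003, -0.02), 2, 2)
  dv <- v %*% t(A)
  th <- poly_features(v, lib)
  nz <- normalize_library(th, lib)
  mask <- matrix(0L, 10, 2); mask[1:3, ] <- 1L
  co <- fit_coefficients(nz$theta_z, dv, mask, lib, nz$norm)
  sim <- integrate_model(co, ic = c(1, 1), n_steps = 50)
  euler_truth <- matrix(0, 51, 2)
  s <- c(1, 1); euler_truth[1, ] <- s
  for (i in 1:50) { s <- drop(s + A %*% s); euler_truth[i + 1, ] <- s }
  expect_equal(sim$path, euler_truth, tolerance = 1e-6)
  # first step agrees with the matrix exponential to first order in h
  expect_equal(sim$path[2, ], drop((diag(2) + A) %*% c(1, 1)), tolerance = 1e-8)
})

test_that("fitted Lorenz model integrates within the source bounding box", {
  co <- fit_lorenz_states()
  src <- lorenz_states()[3:3998, ]
  sim <- integrate_model(co, ic = src[1, ], n_steps = 1000,
                         blowup_scale = max(abs(src)))
  expect_false(sim$blew_up)
  expect_true(all(abs(sim$path) <= 5 * max(abs(src))))
})

test_that("initial-condition screening enforces the spread bounds", {
  co <- fit_lorenz_states()
  src <- lorenz_states()[3:3998, ]
  # a self-consistent chaotic fit accepts at least one on-attractor start
  cands <- lapply(c(1, 500, 1500, 2500), function(i) src[i, ])
  acc <- screen_initial_conditions(co, src, cands)
  expect_true(any(acc))
  # a collapsing linear system from a near-zero start is rejected
  lib <- build_library(1)
  v <- matrix(seq(-2, 2, length.out = 300), ncol = 1)
  nz <- normalize_library(poly_features(v, lib), lib)
  fast_decay <- fit_coefficients(nz$theta_z, -0.9 * v,
                                 matrix(c(1, 1, 0, 0), 4, 1), lib, nz$norm)
  expect_false(screen_initial_conditions(fast_decay, v, list(0.01)))
})
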