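test_that("analytic and numeric Hopf thresholds agree at 470/19", {
  expect_equal(lorenz_hopf_threshold(10, 8 / 3), 470 / 19)
  expect_equal(lorenz_hopf_numeric(10, 8 / 3), 470 / 19, tolerance = 1e-6)
  expect_equal(round(lorenz_hopf_threshold(), 1), 24.7)
})

test_that("Lorenz integration is bounded in chaos and contracts below rho = 1", {
  x28 <- simulate_lorenz(28, ic = c(5, 5, 20))[, 1]
  expect_true(all(abs(x28) < 25))
  xs <- simulate_lorenz(0.5, ic = c(5, 5, 20), dt = 5e-3, n_steps = 4000)
  expect_lt(max(abs(xs[3500:4000, ])), 0.5)
  # fixed seed reproduces the trial generator bit-for-bit
  t1 <- withr::with_seed(61, lorenz_band_trial(28))
  t2 <- withr::with_seed(61, lorenz_band_trial(28))
  expect_identical(t1$x, t2$x)
})

test_that("band-power criterion and resampling factor behave as defined", {
  fs <- 10000
  t <- (0:9999) / fs
  slow <- sin(2 * pi * 50 * t)
  expect_equal(resample_to_band(slow, fs), 1)
  expect_gt(band_power_fraction(slow, fs), 0.99)
  # half the power below the cutoff: tau = 0.9 / 0.5 = 1.8
  mixed <- sin(2 * pi * 100 * t) + sin(2 * pi * 1000 * t)
  expect_equal(band_power_fraction(mixed, fs), 0.5, tolerance = 1e-6)
  expect_equal(resample_to_band(mixed, fs), 1.8, tolerance = 1e-4)
  # generated trials always satisfy the criterion on re-audit
  withr::with_seed(62, {
    for (rho in c(20, 30, 40)) {
      tr <- lorenz_band_trial(rho)
      expect_gte(band_power_fraction(tr$x, fs), 0.9)
    }
  })
})

test_that("HH encoder rests at zero input, spikes under drive, and scales monotonically", {
  n <- 5000  # 0.5 s at 10 kHz
  quiet <- hh_response(rep(0, n), 1, 0, spikes_removed = FALSE)
  expect_equal(quiet$spike_count, 0)
  expect_lt(max(abs(quiet$vm - quiet$vm[1])), 2)  # settled near rest
  # strong constant current: tonic spiking, count grows with duration
  tonic1 <- hh_response(rep(1, n), 0.12, 0, spikes_removed = FALSE)
  tonic2 <- hh_response(rep(1, 2 * n), 0.12, 0, spikes_removed = FALSE)
  expect_gt(tonic1$spike_count, 5)
  expect_gt(tonic2$spike_count, 1.7 * tonic1$spike_count)
  # scaling the gain down never increases the spike count
  weak <- hh_response(rep(1, n), 0.012, 0, spikes_removed = FALSE)
  expect_lte(weak$spike_count, tonic1$spike_count)
  expect_error(hh_response(rep(1, n), 1, 0), "0.15")
})

test_that("median-filter spike removal preserves the subthreshold envelope", {
  withr::with_seed(63, tr <- lorenz_band_trial(32))
  zeta <- mean(range(tr$x)); alpha <- 0.15 / max(abs(tr$x - zeta))
  kept <- hh_response(tr$x, alpha, zeta, spikes_removed = FALSE)
  removed <- hh_response(tr$x, alpha, zeta, spikes_removed = TRUE)
  expect_equal(length(kept$vm), length(removed$vm))
  expect_lte(max(removed$vm), max(kept$vm))
})

test_that("synaptic kernel peaks at the closed-form time and gmax scales with n_syn", {
  # single event at t = 0: peak at (tr*td/(td-tr))*ln(td/tr) ~ 0.402 ms
  ev <- c(1, rep(0, 99))
  g <- dyndisc:::syn_conductance(ev, gmax = 1, dt = 0.1)
  t_peak <- (which.max(g) - 1) * 0.1
  expect_equal(t_peak, 0.4, tolerance = 0.1)
  expect_equal(max(g), 1, tolerance = 0.01)
  # doubling n_syn halves the per-event peak exactly: g0 * 80 / n_syn
  expect_equal((5e-4 * 80 / 160) * 2, 5e-4 * 80 / 80)
  # silent input: resting membrane
  quiet <- synaptic_response(rep(0, 2000), 1, 0, n_syn = 80)
  expect_equal(quiet$event_count, 0)
  expect_equal(quiet$spike_count, 0)
  expect_error(synaptic_response(rep(2, 100), 1, 0, n_syn = 80), "probability")
})

test_that("spike bins follow the log-spacing anchors and acceptance rules", {
  br <- dyndisc:::spike_bin_breaks()
  expect_equal(length(br) - 1, 15)         # 15 bins
  expect_equal(br[1:2], c(0, 1))           # [0, 1) first
  expect_equal(br[14:16], c(39, 50, Inf))  # [39, 50) fourteenth, [50, Inf) last
  # partitioning: per-rho minimum then the 45-trial acceptance threshold
  trials <- tibble::tibble(
    trial_id = sprintf("t%03d", 1:100),
    rho = rep(c(20, 25, 30, 35), 25),
    tau = 1, encoder = "current_hh", alpha = 1, zeta = 0,
    n_syn = NA_integer_,
    spike_count = rep(0L, 100), spikes_removed = TRUE,
    vm = replicate(100, numeric(0), simplify = FALSE))
  bins <- partition_bins(trials)
  expect_true(bins$accepted[1])
  expect_equal(bins$n_trials[1], 100)
  # a rho with only 2 trials is dropped before the count test
  tr2 <- trials[c(1:43, 2, 3), ]          # 45 rows, rho 20 has 12, 35 has 10...
  tr2$rho <- c(rep(20, 43), 35, 35)       # 43 of rho 20, 2 of rho 35
  b2 <- partition_bins(tr2, min_trials = 44)
  expect_equal(b2$n_trials[1], 43)        # the 2-trial rho was dropped
  expect_false(b2$accepted[1])
  b3 <- partition_bins(tr2, min_trials = 43)
  expect_true(b3$accepted[1])
})

test_that("trial with 0 spikes lands in the first bin and 50+ in the last", {
  br <- dyndisc:::spike_bin_breaks()
  expect_equal(as.integer(cut(0, br, right = FALSE)), 1L)
  expect_equal(as.integer(cut(55, br, right = FALSE)), 15L)
  expect_equal(as.integer(cut(45, br, right = FALSE)), 14L)
})
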