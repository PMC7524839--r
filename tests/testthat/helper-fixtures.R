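# shared small fixtures, built once per test run

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# a small multi-cell store for io round-trips
small_store <- function(n_cells = 2, seed = 7) {
  dplyr::bind_rows(lapply(seq_len(n_cells), function(c) {
    generate_fixture(n_stimuli = 2, trials_per_stimulus = 3,
                     cell_id = sprintf("cell%02d", c), seed = seed + c,
                     t_on = 300, t_off = 600)
  }))
}

# fixture with stimulus-coded oscillation frequencies (dynamics separable)
dyn_fixture <- function() {
  memo("dyn_fixture", generate_fixture(
    n_stimuli = 3, trials_per_stimulus = 6, tuning = "ramp",
    osc_freq_hz = c(8, 14, 22), osc_amp = 12, noise_sd = 0.5, seed = 42))
}

dyn_ctx <- function() {
  memo("dyn_ctx", {
    emb <- expand_and_center(dyn_fixture(), epoch = "on")
    prepare_sindy_data(emb$trajectories)
  })
}

# GA scale small enough for unit tests
tiny_config <- function(...) {
  dd_config(population = 24L, n_elites = 6L, generations = 4L,
            rounds = 3L, interim_trees = 5L, final_trees = 15L,
            outer_reps = 4L, ...)
}

# clean Lorenz states context (no embedding): the parameter-recovery oracle
lorenz_states <- function() {
  memo("lorenz_states", simulate_lorenz(28, ic = c(-8, 7, 27),
                                        dt = 0.002, n_steps = 4000))
}

lorenz_true_mask <- function(lib = build_library(3)) {
  tn <- lib$term_names
  m <- matrix(0L, length(tn), 3)
  m[match(c("1", "x1", "x2"), tn), 1] <- 1L
  m[match(c("1", "x1", "x2", "x1*x3"), tn), 2] <- 1L
  m[match(c("1", "x3", "x1*x2"), tn), 3] <- 1L
  m
}

fit_lorenz_states <- function() {
  memo("fit_lorenz_states", {
    lib <- build_library(3)
    de <- estimate_derivatives(lorenz_states())
    th <- poly_features(de$v, lib)
    nz <- normalize_library(th, lib)
    fit_coefficients(nz$theta_z, de$dv, lorenz_true_mask(lib), lib, nz$norm)
  })
}
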