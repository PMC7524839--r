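#' Run configuration with documented defaults
#'
#' Central knobs of the pipeline. Defaults reproduce the standard protocol:
#' 100 one-millisecond delays reduced to 3 dimensions, cubic library, first
#' order derivatives, GA population 300 with 45 elites and 100 generations
#' per three mask columns, mutation schedule 0.15 (seeding) / 0.05
#' (generation 1, halved on an even schedule, zero for the last 10%),
#' classification forests with 5 interim / 51 final trees over 10 rounds of
#' 25% holdout, 20 outer hold-one-out repetitions, and the "on" response
#' epoch (the most informative epoch for discrimination).
#'
#' @param n_delays,d Embedding delays and kept dimension.
#' @param epoch Response epoch used for discrimination.
#' @param max_degree Library polynomial degree.
#' @param population,n_elites GA population and elite count.
#' @param generations GA generations (`NULL` = `100 * ceiling(d/3)`).
#' @param interim_trees,final_trees Random-forest sizes.
#' @param rounds,holdout_frac Objective cross-validation scheme.
#' @param outer_reps Outer hold-one-out repetitions.
#' @param mle_reps,z_bins,r_bins Occupancy-decoder settings.
#' @param seed Base RNG seed.
#' @return A named list of class `dd_config`.
#' @export
dd_config <- function(n_delays = 100L, d = 3L, epoch = "on", max_degree = 3L,
                      population = 300L, n_elites = 45L, generations = NULL,
                      interim_trees = 5L, final_trees = 51L, rounds = 10L,
                      holdout_frac = 0.25, outer_reps = 20L, mle_reps = 510L,
                      z_bins = 20L, r_bins = 10L, seed = 1L) {
  structure(list(n_delays = n_delays, d = d, epoch = epoch,
                 max_degree = max_degree, population = population,
                 n_elites = n_elites, generations = generations,
                 interim_trees = interim_trees, final_trees = final_trees,
                 rounds = rounds, holdout_frac = holdout_frac,
                 outer_reps = outer_reps, mle_reps = mle_reps,
                 z_bins = z_bins, r_bins = r_bins, seed = seed),
            class = "dd_config")
}

#' Read/write a flat JSON run configuration
#'
#' @param path JSON file mirroring [dd_config()] fields (unknown fields
#'   rejected).
#' @return A `dd_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(dd_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(dd_config, vals)
}

#' @rdname read_config
#' @param config A `dd_config` to serialize.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(Filter(Negate(is.null), unclass(config)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
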