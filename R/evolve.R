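# The sexual genetic algorithm over binary coefficient masks. A mask (the
# genome) marks which polynomial-library coefficients are free when fitting
# one sparse ODE per trajectory; fitness is supplied by an objective closure
# (classification, regression, or goodness of fit; see R/decode.R).

new_mask <- function(bits, lib) {
  bits <- matrix(as.integer(bits != 0), nrow(lib$powers), lib$d)
  bits[rowSums(lib$powers) == 0, ] <- 1L  # constant row always live
  bits
}

# crossover per the tournament rule: keep bits present in both parents,
# Bernoulli(1/2) where present in exactly one, then mutate at `rate`
cross_and_mutate <- function(a, b, rate, lib) {
  both <- a & b
  one <- xor(a != 0, b != 0)
  child <- both + (one & (stats::runif(length(a)) < 0.5))
  if (rate > 0) {
    flip <- stats::runif(length(child)) < rate
    child[flip] <- 1L - child[flip]
  }
  new_mask(child, lib)
}

#' Seed the genetic population by per-column threshold masks
#'
#' For each trajectory a dense (unmasked) coefficient matrix is fitted; a
#' bisection over magnitude thresholds per column finds the largest
#' threshold that leaves at least one surviving entry, i.e. the survivors
#' are the maximal-magnitude entries of each column (plus the always-live
#' constant row). The deduplicated seed masks are expanded to `target_size`
#' unique masks by mating and mutation at the seeding rate.
#'
#' @param ctx A [prepare_sindy_data()] context.
#' @param target_size Population size (default 300).
#' @param rate Seeding mutation rate (default 0.15).
#' @param seed RNG seed for the expansion.
#' @return List of unique binary masks.
#' @export
seed_population <- function(ctx, target_size = 300L, rate = 0.15, seed = NULL) {
  lib <- ctx$lib
  dense <- matrix(1L, nrow(lib$powers), lib$d)
  seeds <- list(); seen <- character(0)
  for (e in ctx$entries) {
    xi <- fit_entry(e, dense, lib)$xi
    bits <- matrix(0L, nrow(xi), ncol(xi))
    for (k in seq_len(ncol(xi))) {
      mag <- abs(xi[, k])
      thr <- bisect_threshold(mag)
      bits[mag > thr, k] <- 1L
    }
    m <- new_mask(bits, lib)
    h <- mask_hash(m)
    if (!h %in% seen) { seeds <- c(seeds, list(m)); seen <- c(seen, h) }
  }
  with_seed(seed, {
    guard <- 0L
    while (length(seeds) < target_size && guard < 50L * target_size) {
      guard <- guard + 1L
      p <- sample.int(length(seeds), 2L, replace = length(seeds) < 2)
      child <- cross_and_mutate(seeds[[p[1]]], seeds[[p[2]]], rate, lib)
      h <- mask_hash(child)
      if (!h %in% seen) { seeds <- c(seeds, list(child)); seen <- c(seen, h) }
    }
  })
  seeds
}

# largest threshold leaving >= 1 survivor (strictly-greater semantics):
# bisection between 0 and max|xi|, converging to just below the max
bisect_threshold <- function(mag, iters = 40L) {
  lo <- 0; hi <- max(mag)
  if (hi == 0) return(-1)  # all-zero column: every entry "survives" threshold -1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (any(mag > mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Scheduled mutation rate
#'
#' The rate starts at `r_gen1` (0.05) in generation 1, is halved at evenly
#' spaced checkpoints across the first 90% of generations (`n_halvings =
#' max(2, ceil(log2(r_mut * n_elements) + 1))`), and is 0 for the last 10%.
#'
#' @param gen Generation index, `1..total_gens`.
#' @param total_gens Total number of generations.
#' @param n_elements Number of mask elements (library terms x dimensions).
#' @param r_gen1 Generation-1 rate.
#' @param r_mut Rate used in the halvings formula (the schedule context's
#'   rate, 0.05).
#' @return Mutation probability for that generation.
#' @export
mutation_rate <- function(gen, total_gens, n_elements, r_gen1 = 0.05,
                          r_mut = 0.05) {
  stopifnot(gen >= 1, gen <= total_gens)
  zero_from <- floor(0.9 * total_gens) + 1L
  if (gen >= zero_from) return(0)
  n_halv <- max(2L, ceiling(log2(r_mut * n_elements) + 1))
  # n_halv + 1 equal blocks over the pre-zero phase; each block halves again
  block <- ceiling(gen / ((zero_from - 1) / (n_halv + 1)))
  r_gen1 / 2^(min(block, n_halv + 1L) - 1L)
}

#' Breed one generation of children from the ranked elites
#'
#' One parent cycles deterministically through the elites; the other is
#' drawn with probability proportional to rank (best rank = largest),
#' never equal to the first. Children are produced by the keep-both /
#' coin-flip-one crossover followed by independent bit-flip mutation; the
#' constant-row invariant is re-enforced after mutation.
#'
#' @param elites List of masks ranked worst (1) to best (n).
#' @param n_children Number of children (default 255).
#' @param rate Mutation rate for this generation.
#' @param lib Library specification (for the constant-row repair).
#' @return List of `n_children` masks.
#' @export
breed <- function(elites, n_children, rate, lib) {
  n <- length(elites)
  stopifnot(n >= 2)
  ranks <- seq_len(n)
  lapply(seq_len(n_children), function(i) {
    p1 <- ((i - 1L) %% n) + 1L
    w <- ranks; w[p1] <- 0
    p2 <- sample.int(n, 1L, prob = w)
    cross_and_mutate(elites[[p1]], elites[[p2]], rate, lib)
  })
}

#' Run the genetic search over coefficient masks
#'
#' Seeds the population, then per generation evaluates all children and
#' re-evaluates the elites (the classification objective is noisy), keeping
#' the best `n_elites` unique masks. Fitness ties break toward the sparser
#' mask, then by hash, for determinism. Terminates early when the elite
#' fitness spread falls below 1/1000 of the initial population's fitness
#' range.
#'
#' @param ctx A [prepare_sindy_data()] context.
#' @param objective Function `mask -> list(fitness, error_term,
#'   sparsity_term)` with fitness in `[0, 1]` (lower is better). An
#'   objective error on a mask assigns worst fitness 1.
#' @param generations Number of generations; default `100 * ceiling(d/3)`.
#' @param population Total population size (elites + children per
#'   generation; default 300).
#' @param n_elites Number of elites kept and finally returned (default 45).
#' @param seed RNG seed; the full run is reproducible given the seed.
#' @return List with `elites` (tibble: `rank` 1 = worst of the kept set,
#'   `fitness`, `mask` list-column, best last), and `history` (per
#'   generation best/median fitness).
#' @export
run_evolution <- function(ctx, objective, generations = NULL,
                          population = 300L, n_elites = 45L, seed = NULL) {
  lib <- ctx$lib
  if (is.null(generations)) generations <- 100L * ceiling(lib$d / 3)
  n_children <- population - n_elites
  stopifnot(n_children >= 1, n_elites >= 2)
  eval_mask <- function(m) {
    r <- tryCatch(objective(m), error = function(e) NULL)
    if (is.null(r) || !is.finite(r$fitness)) list(fitness = 1, failed = TRUE)
    else r
  }
  with_seed(seed, {
    pop <- seed_population(ctx, target_size = population, seed = NULL)
    fits <- vapply(pop, function(m) eval_mask(m)$fitness, numeric(1))
    init_range <- diff(range(fits))
    sel <- select_elites(pop, fits, n_elites)
    elites <- sel$masks; efits <- sel$fits
    hist <- vector("list", generations)
    for (gen in seq_len(generations)) {
      rate <- mutation_rate(gen, generations, length(elites[[1]]))
      children <- breed(elites, n_children, rate, lib)
      cfits <- vapply(children, function(m) eval_mask(m)$fitness, numeric(1))
      efits <- vapply(elites, function(m) eval_mask(m)$fitness, numeric(1))
      sel <- select_elites(c(elites, children), c(efits, cfits), n_elites)
      elites <- sel$masks; efits <- sel$fits
      hist[[gen]] <- tibble::tibble(generation = gen, rate = rate,
                                    best = min(efits),
                                    median = stats::median(efits))
      if (diff(range(efits)) <= init_range / 1000) break
    }
    ord <- order(efits, decreasing = TRUE)  # rank 1 = worst ... n = best
    list(elites = tibble::tibble(rank = seq_along(ord),
                                 fitness = efits[ord],
                                 mask = elites[ord]),
         history = dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))]))
  })
}

# keep the n best unique masks; ties by fitness break to sparser mask, then hash
select_elites <- function(masks, fits, n) {
  hashes <- vapply(masks, mask_hash, character(1))
  dup <- duplicated(hashes)
  masks <- masks[!dup]; fits <- fits[!dup]; hashes <- hashes[!dup]
  nnz <- vapply(masks, function(m) sum(m != 0), numeric(1))
  ord <- order(fits, nnz, hashes)
  keep <- ord[seq_len(min(n, length(ord)))]
  list(masks = masks[keep], fits = fits[keep])
}
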