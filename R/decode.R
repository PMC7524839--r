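# Objective functions for the genetic search, the voting/median ensemble of
# random forests over elite masks, the outer hold-one-out protocol, and the
# baseline decoders (deflection tuning-curve, occupancy maximum likelihood,
# and the two-state-variable re-analysis).

rf_fit <- function(x, y, num.trees) {
  ranger::ranger(x = as.data.frame(x), y = y, num.trees = num.trees,
                 num.threads = 1L, verbose = FALSE,
                 seed = sample.int(.Machine$integer.max, 1L))
}

rf_predict <- function(fit, x) {
  stats::predict(fit, data = as.data.frame(x), num.threads = 1L)$predictions
}

# indices held out per label: a `frac` fraction of each label's examples, >= 1
holdout_indices <- function(labels, frac) {
  unlist(lapply(unique(labels), function(l) {
    idx <- which(labels == l)
    idx[sample.int(length(idx), max(1L, round(frac * length(idx))))]
  }), use.names = FALSE)
}

objective_result <- function(error_term, mask) {
  s <- mean(mask != 0)
  list(fitness = 0.8 * error_term + 0.2 * s,
       error_term = error_term, sparsity_term = s)
}

#' Classification objective for the genetic search
#'
#' Returns a closure evaluating one mask: sparse ODEs are fitted per
#' trajectory under the mask, and over `rounds` random splits a small
#' random-forest classifier (`interim_trees`) is trained on the vectorized
#' nonzero coefficients of 75% of each stimulus's trials and scored by
#' macro-averaged F1 on the held-out 25%. The fitness is
#' `0.8 * (1 - mean macro-F1) + 0.2 * (fraction of mask entries nonzero)`.
#'
#' @param ctx A [prepare_sindy_data()] context.
#' @param labels Stimulus label per trajectory (defaults to the context's
#'   stimulus indices). Every label needs `>= 2` examples.
#' @param interim_trees Trees per interim forest (default 5).
#' @param rounds Number of random hold-out rounds (default 10).
#' @param holdout_frac Held-out fraction per stimulus (default 0.25).
#' @return Function `mask -> list(fitness, error_term, sparsity_term)`.
#' @export
classification_objective <- function(ctx, labels = NULL, interim_trees = 5L,
                                     rounds = 10L, holdout_frac = 0.25) {
  if (is.null(labels)) labels <- ctx$stimulus_index
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 stimulus labels")
  if (any(table(labels) < 2)) stop("every label needs >= 2 examples")
  force(ctx)
  function(mask) {
    feats <- features_for_mask(ctx, mask)
    f1s <- vapply(seq_len(rounds), function(r) {
      te <- holdout_indices(labels, holdout_frac)
      fit <- rf_fit(feats[-te, , drop = FALSE], droplevels(labels[-te]),
                    interim_trees)
      pred <- rf_predict(fit, feats[te, , drop = FALSE])
      score_classification(labels[te], pred, labels = levels(labels))$macro_f1
    }, numeric(1))
    objective_result(1 - mean(f1s), mask)
  }
}

#' Regression objective for the genetic search
#'
#' Same scheme as [classification_objective()] but the forest regresses the
#' coefficient features onto a continuous target (e.g. the Lorenz parameter
#' rho) and the error term is `1 - R^2` of the held-out predictions,
#' clipped to `[0, 1]`.
#'
#' @param ctx Fit context.
#' @param targets Numeric target per trajectory.
#' @param group Grouping used for stratified holdout (defaults to
#'   `targets`).
#' @inheritParams classification_objective
#' @return Objective closure.
#' @export
regression_objective <- function(ctx, targets, group = NULL,
                                 interim_trees = 5L, rounds = 10L,
                                 holdout_frac = 0.25) {
  stopifnot(length(targets) == ctx$n_traj)
  if (is.null(group)) group <- targets
  force(ctx)
  function(mask) {
    feats <- features_for_mask(ctx, mask)
    r2s <- vapply(seq_len(rounds), function(r) {
      te <- holdout_indices(group, holdout_frac)
      fit <- rf_fit(feats[-te, , drop = FALSE], targets[-te], interim_trees)
      pred <- rf_predict(fit, feats[te, , drop = FALSE])
      tss <- sum((targets[te] - mean(targets[te]))^2)
      if (tss <= 0) return(0)
      1 - sum((targets[te] - pred)^2) / tss
    }, numeric(1))
    objective_result(min(max(1 - mean(r2s), 0), 1), mask)
  }
}

#' Goodness-of-fit objective for the genetic search
#'
#' Deterministic objective: each trajectory's fitted ODE is Euler-integrated
#' `steps` timesteps forward from every trajectory point, and the predicted
#' endpoints are compared with the observed states `steps` samples ahead via
#' an R-squared pooled across dimensions. The error term is the mean of
#' `1 - R^2` over trajectories, clipped to `[0, 1]`; integration blow-up on
#' a trajectory contributes the worst error 1.
#'
#' @param ctx Fit context.
#' @param steps Forward-integration horizon in samples (default 4).
#' @return Objective closure.
#' @export
gof_objective <- function(ctx, steps = 4L) {
  force(ctx)
  function(mask) {
    errs <- vapply(ctx$entries, function(e) {
      f <- fit_entry(e, mask, ctx$lib)
      n <- nrow(e$v)
      if (n <= steps) return(1)
      S <- e$v[seq_len(n - steps), , drop = FALSE]
      for (s in seq_len(steps)) {
        th <- poly_features(S, ctx$lib)
        tz <- sweep(sweep(th, 2L, e$norm$mu, "-"), 2L, e$norm$sigma, "/")
        S <- S + tz %*% f$xi
        if (!all(is.finite(S))) return(1)
      }
      obs <- e$v[(steps + 1):n, , drop = FALSE]
      tss <- sum(sweep(obs, 2L, colMeans(obs), "-")^2)
      if (tss <= 0) return(1)
      min(max(sum((S - obs)^2) / tss, 0), 1)
    }, numeric(1))
    objective_result(mean(errs), mask)
  }
}

#' Train the elite-mask ensemble
#'
#' One random forest per elite mask, trained on that mask's coefficient
#' features over the supplied training trajectories.
#'
#' @param elites Elite tibble from [run_evolution()] (`rank`, `mask`).
#' @param ctx Fit context for the training trajectories.
#' @param y Label factor (classification) or numeric target (regression)
#'   per training trajectory.
#' @param final_trees Trees per member forest (default 51).
#' @return A `dd_ensemble` object.
#' @export
train_ensemble <- function(elites, ctx, y, final_trees = 51L) {
  task <- if (is.factor(y)) "classify" else "regress"
  members <- lapply(seq_len(nrow(elites)), function(i) {
    m <- elites$mask[[i]]
    list(rank = elites$rank[i], mask = m,
         model = rf_fit(features_for_mask(ctx, m),
                        if (task == "classify") droplevels(y) else y,
                        final_trees))
  })
  structure(list(members = members, task = task,
                 levels = if (task == "classify") levels(y) else NULL),
            class = "dd_ensemble")
}

#' @export
print.dd_ensemble <- function(x, ...) {
  cat(sprintf("<dd_ensemble> %d members, task=%s\n", length(x$members), x$task))
  invisible(x)
}

#' Predict with the elite-mask ensemble
#'
#' Classification is decided by the mode of the member votes, ties broken by
#' the vote of the highest-ranked member among the tied choices' voters;
#' regression returns the member median.
#'
#' @param ens A [train_ensemble()] model.
#' @param ctx Fit context holding the trajectories to predict.
#' @param indices Rows of `ctx` to predict (default all).
#' @return Character labels or numeric predictions.
#' @export
predict_ensemble <- function(ens, ctx, indices = seq_len(ctx$n_traj)) {
  sub <- subset_context(ctx, indices)
  preds <- lapply(ens$members, function(mb) {
    rf_predict(mb$model, features_for_mask(sub, mb$mask))
  })
  ranks <- vapply(ens$members, function(mb) mb$rank, numeric(1))
  if (ens$task == "regress") {
    return(apply(do.call(cbind, preds), 1L, stats::median))
  }
  votes <- do.call(cbind, lapply(preds, as.character))
  vote_mode(votes, ranks)
}

# majority vote per row; ties broken by the highest-ranked member voting for
# one of the tied choices
vote_mode <- function(votes, ranks) {
  vapply(seq_len(nrow(votes)), function(i) {
    tab <- table(votes[i, ])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    tied <- votes[i, ] %in% top
    votes[i, which(tied)[which.max(ranks[tied])]]
  }, character(1))
}

subset_context <- function(ctx, idx) {
  structure(list(entries = ctx$entries[idx], lib = ctx$lib,
                 trial_id = ctx$trial_id[idx],
                 stimulus_index = ctx$stimulus_index[idx],
                 n_traj = length(idx)),
            class = "dd_fit_context")
}

decode_result <- function(mode, predictions, labels_universe, n_reps) {
  sc <- score_classification(predictions$truth, predictions$pred,
                             labels = labels_universe)
  structure(list(mode = mode, ccr = sc$ccr, macro_f1 = sc$macro_f1,
                 per_label = tibble::tibble(label = names(sc$f1), f1 = sc$f1),
                 predictions = predictions, n_reps = n_reps),
            class = "dd_decode_result")
}

#' @export
print.dd_decode_result <- function(x, ...) {
  cat(sprintf("<dd_decode_result> mode=%s, CCR=%.4f, macro-F1=%.4f (%d reps, %d predictions)\n",
              x$mode, x$ccr, x$macro_f1, x$n_reps, nrow(x$predictions)))
  invisible(x)
}

#' Outer hold-one-out evaluation of the full pipeline
#'
#' The overfitting-controlled protocol: per repetition one randomly chosen
#' example of every stimulus is held out and never touched by seeding,
#' evolution, or ensemble training; the remaining trials run the entire
#' genetic search and ensemble, which then predicts the held-out trials.
#' Results are aggregated over `outer_reps` repetitions. With
#' `surrogate = TRUE` the stimulus labels are scrambled first, which must
#' bring performance down to chance if overfitting is controlled.
#'
#' @param cell Trial tibble for one cell and signal kind (`>= 3` examples
#'   per stimulus).
#' @param mode `"dynamical"` (classification objective), `"best-fit"`
#'   (goodness-of-fit objective), or `"state-variable"` (ensemble
#'   regressors for reliability and deflection feeding a final classifier).
#' @param config A [dd_config()] list (GA scale, forest sizes, epoch, ...).
#' @param surrogate Scramble labels before the run (overfitting control).
#' @param seed RNG seed for the whole protocol.
#' @return A `dd_decode_result`.
#' @export
outer_holdout <- function(cell, mode = c("dynamical", "best-fit",
                                         "state-variable"),
                          config = dd_config(), surrogate = FALSE,
                          seed = config$seed) {
  mode <- match.arg(mode)
  counts <- table(cell$stimulus_index)
  if (any(counts < 3)) stop("need >= 3 examples per stimulus")
  emb <- expand_and_center(cell, epoch = config$epoch,
                           n_delays = config$n_delays, d = config$d)
  ctx <- prepare_sindy_data(emb$trajectories)
  defl <- if (mode == "state-variable") deflection_table(cell, config$epoch) else NULL
  with_seed(seed, {
    labels <- factor(cell$stimulus_index)
    if (surrogate) labels <- sample(labels)
    preds <- lapply(seq_len(config$outer_reps), function(rep) {
      te <- vapply(levels(labels), function(l) {
        idx <- which(labels == l); idx[sample.int(length(idx), 1L)]
      }, integer(1))
      tr <- setdiff(seq_along(labels), te)
      pred <- fit_and_predict_pipeline(ctx, labels, tr, te, mode, config, defl)
      tibble::tibble(rep = rep, trial_id = ctx$trial_id[te],
                     truth = as.character(labels[te]), pred = pred)
    })
    decode_result(mode, dplyr::bind_rows(preds), levels(labels),
                  config$outer_reps)
  })
}

# run seeding + evolution + ensemble on the training rows, predict test rows
fit_and_predict_pipeline <- function(ctx, labels, tr, te, mode, config, defl) {
  sub <- subset_context(ctx, tr)
  obj <- switch(mode,
    "dynamical" = classification_objective(sub, labels[tr],
                                           config$interim_trees,
                                           config$rounds, config$holdout_frac),
    "best-fit" = gof_objective(sub),
    "state-variable" = classification_objective(sub, labels[tr],
                                                config$interim_trees,
                                                config$rounds,
                                                config$holdout_frac))
  evo <- run_evolution(sub, obj, generations = config$generations,
                       population = config$population,
                       n_elites = config$n_elites, seed = NULL)
  if (mode == "state-variable") {
    return(state_variable_predict(evo$elites, ctx, labels, tr, te, config, defl))
  }
  ens <- train_ensemble(evo$elites, sub, droplevels(labels[tr]),
                        config$final_trees)
  predict_ensemble(ens, ctx, te)
}

# ensemble regressors Xi -> (reliability, deflection); final forest on the two
# predicted state variables -> stimulus label
state_variable_predict <- function(elites, ctx, labels, tr, te, config, defl) {
  ts_ <- tuning_summary(defl$deflection, as.integer(as.character(labels)))
  key <- match(as.integer(as.character(labels)), ts_$stimulus_index)
  rel <- ts_$reliability[key]; mdefl <- ts_$mean_deflection[key]
  rel[!is.finite(rel)] <- 0
  sub <- subset_context(ctx, tr)
  ens_r <- train_ensemble(elites, sub, rel[tr], config$final_trees)
  ens_d <- train_ensemble(elites, sub, mdefl[tr], config$final_trees)
  sv_tr <- cbind(r = predict_ensemble(ens_r, ctx, tr),
                 d = predict_ensemble(ens_d, ctx, tr))
  sv_te <- cbind(r = predict_ensemble(ens_r, ctx, te),
                 d = predict_ensemble(ens_d, ctx, te))
  final <- rf_fit(sv_tr, droplevels(labels[tr]), config$final_trees)
  as.character(rf_predict(final, sv_te))
}

#' Deflection tuning-curve decoder
#'
#' The baseline decoder: a random forest on the single per-trial deflection
#' value, evaluated under the same outer hold-one-out protocol as the
#' dynamical pipeline.
#'
#' @param deflections Per-trial deflection values.
#' @param labels Per-trial stimulus labels.
#' @param reps Outer repetitions (default 20).
#' @param trees Forest size (default 51).
#' @param surrogate Scramble labels first.
#' @param seed RNG seed.
#' @return A `dd_decode_result`.
#' @export
deflection_decoder <- function(deflections, labels, reps = 20L, trees = 51L,
                               surrogate = FALSE, seed = NULL) {
  labels <- factor(labels)
  if (any(table(labels) < 3)) stop("need >= 3 examples per stimulus")
  with_seed(seed, {
    if (surrogate) labels <- sample(labels)
    preds <- lapply(seq_len(reps), function(rep) {
      te <- vapply(levels(labels), function(l) {
        idx <- which(labels == l); idx[sample.int(length(idx), 1L)]
      }, integer(1))
      fit <- rf_fit(matrix(deflections[-te], ncol = 1),
                    droplevels(labels[-te]), trees)
      tibble::tibble(rep = rep,
                     truth = as.character(labels[te]),
                     pred = as.character(rf_predict(
                       fit, matrix(deflections[te], ncol = 1))))
    })
    decode_result("deflection", dplyr::bind_rows(preds), levels(labels), reps)
  })
}
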