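# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# derive a distinct child seed from a base seed, kept inside 32-bit range
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483647
}

#' Macro-averaged F1 score and correct classification rate
#'
#' Per-label F1 is `2 TP / (2 TP + FP + FN)`; a label absent from both truth
#' and prediction contributes F1 = 1 by convention (no possible errors), and
#' a label present but never predicted correctly contributes 0. The macro
#' mean is the average over the label universe.
#'
#' @param truth,pred Vectors of labels (coerced to character).
#' @param labels Label universe; defaults to the labels present in `truth`.
#' @return List with `f1` (named per-label), `macro_f1`, `ccr`.
#' @export
score_classification <- function(truth, pred, labels = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (is.null(labels)) labels <- sort(unique(truth))
  f1 <- vapply(labels, function(l) {
    tp <- sum(truth == l & pred == l)
    fp <- sum(truth != l & pred == l)
    fn <- sum(truth == l & pred != l)
    if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(f1 = f1, macro_f1 = mean(f1), ccr = mean(truth == pred))
}

# exact binomial two-sided chance interval for n trials at probability p
chance_interval <- function(n, p, level = 0.95) {
  a <- (1 - level) / 2
  c(lower = stats::qbinom(a, n, p) / n,
    upper = stats::qbinom(1 - a, n, p) / n)
}

mask_hash <- function(mask) paste(as.integer(mask != 0), collapse = "")
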