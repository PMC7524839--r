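#' Tuning-curve summary: deflection, reliability, least/most similarity
#'
#' Per stimulus ordinal `i` of `N`: the mean absolute deflection `D_i`, its
#' reliability `R_i = mean/sd` across repeats (flagged `NA` when the
#' deflections are constant), the least/most similarity
#' `S_i = min(|i - argmin D|, |i - argmax D|) / N`, and the key distance
#' (the unscaled ordinal distance to the nearer of the least/most preferred
#' stimulus). Argmin/argmax ties break to the lower ordinal.
#'
#' @param deflections Per-trial absolute deflection values.
#' @param stimulus_index Per-trial stimulus ordinal (1..N).
#' @return Tibble: `stimulus_index`, `n`, `mean_deflection`,
#'   `sd_deflection`, `reliability`, `similarity`, `key_distance`.
#' @export
tuning_summary <- function(deflections, stimulus_index) {
  stimulus_index <- as.integer(stimulus_index)
  stopifnot(length(deflections) == length(stimulus_index))
  ords <- sort(unique(stimulus_index))
  if (length(ords) < 2) stop("need >= 2 stimuli")
  N <- length(ords)
  D <- vapply(ords, function(i) mean(abs(deflections[stimulus_index == i])),
              numeric(1))
  s <- vapply(ords, function(i) stats::sd(abs(deflections[stimulus_index == i])),
              numeric(1))
  n <- vapply(ords, function(i) sum(stimulus_index == i), numeric(1))
  i_min <- ords[which.min(D)]; i_max <- ords[which.max(D)]
  key <- pmin(abs(ords - i_min), abs(ords - i_max))
  rel <- ifelse(is.finite(s) & s > 0, D / s, NA_real_)
  tibble::tibble(stimulus_index = ords, n = n, mean_deflection = D,
                 sd_deflection = s, reliability = rel,
                 similarity = key / N, key_distance = key)
}

#' Fluctuation and noise summary per trial
#'
#' Fluctuation size is the coefficient of variation of each recording
#' (sd/mean of the series). Noise is measured against the cross-trial mean
#' response of the same stimulus (the trial itself included in the mean):
#' the residual series `(trial - mean response)/mean response`, summarized
#' by its mean and mean absolute value. Samples where the mean response is
#' within `eps` of zero are excluded and the excluded fraction reported.
#'
#' @param cell Trial tibble for one cell and signal kind, `>= 2` trials per
#'   stimulus.
#' @param eps Exclusion threshold on `|mean response|`.
#' @return Tibble: `trial_id`, `stimulus_index`, `cv`,
#'   `mean_norm_residual`, `mean_abs_norm_residual`, `frac_excluded`.
#' @export
noise_summary <- function(cell, eps = 1e-9) {
  if (any(table(cell$stimulus_index) < 2)) stop("need >= 2 trials per stimulus")
  n <- min(lengths(cell$samples))
  out <- lapply(seq_len(nrow(cell)), function(i) {
    x <- cell$samples[[i]][seq_len(n)]
    same <- which(cell$stimulus_index == cell$stimulus_index[i])
    m <- rowMeans(vapply(cell$samples[same], function(s) s[seq_len(n)],
                         numeric(n)))
    ok <- abs(m) >= eps
    res <- (x[ok] - m[ok]) / m[ok]
    tibble::tibble(trial_id = cell$trial_id[i],
                   stimulus_index = cell$stimulus_index[i],
                   cv = stats::sd(x) / mean(x),
                   mean_norm_residual = mean(res),
                   mean_abs_norm_residual = mean(abs(res)),
                   frac_excluded = 1 - mean(ok))
  })
  dplyr::bind_rows(out)
}

#' Association statistics between two performance sets
#'
#' Pearson correlation with its two-sided p-value, the simple-difference-
#' formula effect size `r_SDF = P(x > y) - P(x < y)` over matched pairs,
#' and a one-tailed Wilcoxon p-value (signed-rank for paired data, rank-sum
#' otherwise) whose direction is chosen by the median difference.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @param paired Matched pairs?
#' @return Tibble: `pearson_r`, `pearson_p`, `r_sdf`, `wilcoxon_p`,
#'   `direction`.
#' @export
association_stats <- function(x, y, paired = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ct <- stats::cor.test(x, y)
  r_sdf <- if (paired) mean(x > y) - mean(x < y) else NA_real_
  med_diff <- if (paired) stats::median(x - y) else stats::median(x) - stats::median(y)
  alt <- if (med_diff >= 0) "greater" else "less"
  wp <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, alternative = alt, exact = FALSE)$p.value)
  tibble::tibble(pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
                 r_sdf = r_sdf, wilcoxon_p = wp, direction = alt)
}
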