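#' Build a trial-store tibble
#'
#' A trial store is a tibble with one row per recorded trial and columns
#' `cell_id`, `trial_id`, `signal_kind`, `stimulus_axis`, `stimulus_index`,
#' `t_on`, `t_off` (ms) and `samples` (list-column of 1 kHz numeric series;
#' sample `k` is time `k - 1` ms). All of a cell's trials share one stimulus
#' axis and stimulus ordinals are contiguous integers starting at 1.
#'
#' @param cell_id,trial_id Character identifiers.
#' @param signal_kind One of `"excitatory_current"`, `"inhibitory_current"`,
#'   `"potential_spikes_kept"`, `"potential_spikes_removed"`.
#' @param stimulus_axis One of `"orientation"`, `"size"`, `"contrast"`,
#'   `"rho"`.
#' @param stimulus_index Stimulus ordinal (`>= 1`).
#' @param t_on,t_off Stimulus on/off times in ms.
#' @param samples List of numeric series.
#' @return A validated trial-store tibble.
#' @export
trial_store <- function(cell_id, trial_id, signal_kind, stimulus_axis,
                        stimulus_index, t_on, t_off, samples) {
  out <- tibble::tibble(cell_id = as.character(cell_id),
                        trial_id = as.character(trial_id),
                        signal_kind = as.character(signal_kind),
                        stimulus_axis = as.character(stimulus_axis),
                        stimulus_index = as.integer(stimulus_index),
                        t_on = as.numeric(t_on), t_off = as.numeric(t_off),
                        samples = samples)
  validate_trial_store(out)
}

signal_kinds <- c("excitatory_current", "inhibitory_current",
                  "potential_spikes_kept", "potential_spikes_removed")
stimulus_axes <- c("orientation", "size", "contrast", "rho")

#' Validate a trial-store tibble
#'
#' Enforces the store invariants: known signal kinds and stimulus axes, one
#' stimulus axis per cell, contiguous stimulus ordinals starting at 1 with
#' at least 2 distinct ordinals per cell, `t_on < t_off < series end`, and
#' finite samples. Warns when a stimulus has fewer than 3 or more than 21
#' examples (outside the range this analysis was designed around).
#'
#' @param store A trial-store tibble.
#' @return The store, invisibly passed through.
#' @export
validate_trial_store <- function(store) {
  req <- c("cell_id", "trial_id", "signal_kind", "stimulus_axis",
           "stimulus_index", "t_on", "t_off", "samples")
  miss <- setdiff(req, names(store))
  if (length(miss)) stop("trial store missing columns: ", paste(miss, collapse = ", "))
  if (nrow(store) == 0) return(store)
  if (!all(store$signal_kind %in% signal_kinds)) stop("unknown signal_kind")
  if (!all(store$stimulus_axis %in% stimulus_axes)) stop("unknown stimulus_axis")
  if (anyNA(store$t_on) || anyNA(store$t_off)) stop("missing t_on/t_off")
  bad_na <- vapply(store$samples, anyNA, logical(1))
  if (any(bad_na)) {
    stop("NaN/NA samples in trial(s): ",
         paste(store$trial_id[bad_na], collapse = ", "))
  }
  bad_t <- store$t_on >= store$t_off | store$t_off >= lengths(store$samples)
  if (any(bad_t)) {
    stop("require t_on < t_off < series end; violated by trial(s): ",
         paste(store$trial_id[bad_t], collapse = ", "))
  }
  for (cid in unique(store$cell_id)) {
    cell <- store[store$cell_id == cid, ]
    if (length(unique(cell$stimulus_axis)) != 1) {
      stop("cell ", cid, " mixes stimulus axes")
    }
    ords <- sort(unique(cell$stimulus_index))
    if (!identical(ords, seq_along(ords)) || length(ords) < 2) {
      stop("non-contiguous ordinals in cell ", cid,
           " (need contiguous integers 1..k, k >= 2)")
    }
    cnt <- table(cell$stimulus_index)
    if (any(cnt < 3 | cnt > 21)) {
      warning("cell ", cid, ": examples per stimulus outside the expected 3-21 range")
    }
  }
  store
}

#' Write a trial store to disk
#'
#' On-disk layout: a directory holding one CSV per trial (single `sample`
#' column, full 17-digit precision so the round trip is bit-exact) and a
#' `manifest.json` with the per-trial metadata and format version.
#'
#' @param store A validated trial-store tibble.
#' @param path Directory to create/overwrite.
#' @export
write_trial_store <- function(store, path) {
  validate_trial_store(store)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- if (nrow(store)) sprintf("trial_%04d.csv", seq_len(nrow(store))) else character(0)
  for (i in seq_len(nrow(store))) {
    writeLines(c("sample", sprintf("%.17g", store$samples[[i]])),
               file.path(path, files[i]))
  }
  meta <- list(format_version = "1.0",
               trials = lapply(seq_len(nrow(store)), function(i) {
                 list(cell_id = store$cell_id[i], trial_id = store$trial_id[i],
                      signal_kind = store$signal_kind[i],
                      stimulus_axis = store$stimulus_axis[i],
                      stimulus_index = store$stimulus_index[i],
                      t_on = store$t_on[i], t_off = store$t_off[i],
                      file = files[i])
               }))
  jsonlite::write_json(meta, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial store from disk
#'
#' @param path Directory written by [write_trial_store()] (CSV files plus a
#'   JSON manifest).
#' @return A validated trial-store tibble.
#' @export
read_trial_store <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  meta <- jsonlite::read_json(mf)
  trials <- meta$trials
  if (length(trials) == 0) {
    return(trial_store(character(0), character(0), character(0), character(0),
                       integer(0), numeric(0), numeric(0), list()))
  }
  g <- function(f, cast) cast(vapply(trials, function(t) t[[f]], numeric(1)))
  gc_ <- function(f) vapply(trials, function(t) as.character(t[[f]]), character(1))
  samples <- lapply(trials, function(t) {
    lns <- readLines(file.path(path, t$file))
    as.numeric(lns[-1])
  })
  trial_store(gc_("cell_id"), gc_("trial_id"), gc_("signal_kind"),
              gc_("stimulus_axis"), g("stimulus_index", as.integer),
              g("t_on", as.numeric), g("t_off", as.numeric), samples)
}
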