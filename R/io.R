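#' Write a recording container
#'
#' Serialises a recording plus its event table to the package's single-file
#' container (an RDS file holding the signal matrix with root metadata
#' `fs_hz`, `subject_id`, `pitch_um`, `n_contacts` and the events table).
#' All invariants of both inputs are validated before anything is written.
#'
#' @param rec a [new_recording()].
#' @param events an [event_table()].
#' @param path output file path (conventionally `.lrec.rds`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, events, path) {
  if (!inherits(rec, "laminar_recording")) stop("rec must be a laminar_recording")
  if (nrow(rec$signal) != rec$geometry$n_contacts)
    stop("validation error: signal rows do not match probe contacts")
  if (!all(is.finite(rec$signal))) stop("validation error: non-finite signal values")
  validate_events(events)
  obj <- list(
    lfp = rec$signal,
    fs_hz = rec$fs,
    subject_id = rec$subject_id,
    pitch_um = rec$geometry$pitch_um,
    n_contacts = rec$geometry$n_contacts,
    events = as.data.frame(events),
    events_fs = attr(events, "fs") %||% rec$fs
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Read a recording container
#'
#' Inverse of [write_recording()]; round-trips exactly.
#'
#' @param path container path.
#' @return list with elements `recording` and `events`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  required <- c("lfp", "fs_hz", "subject_id", "pitch_um", "n_contacts", "events")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("format error: container is missing ", paste(sQuote(missing), collapse = ", "))
  if (obj$fs_hz <= 0) stop("validation error: fs_hz must be positive")
  geom <- probe_geometry(obj$n_contacts, obj$pitch_um)
  rec <- new_recording(obj$lfp, obj$fs_hz, geom, obj$subject_id)
  ev <- obj$events
  attr(ev, "fs") <- obj$events_fs %||% obj$fs_hz
  class(ev) <- c("event_table", "data.frame")
  validate_events(ev)
  list(recording = rec, events = ev)
}

#' Export events as CSV
#'
#' Plain CSV with columns onset_sample, orientation_deg, context, run,
#' duration_samples.
#'
#' @param events an [event_table()].
#' @param path output path.
#' @export
export_events_csv <- function(events, path) {
  validate_events(events)
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Match trial counts across contexts
#'
#' Subsamples every context to the smallest per-context trial count (optionally
#' capped at `n_max`) with a seeded uniform draw without replacement, so that
#' all downstream contrasts compare equal numbers of trials.
#'
#' @param epochs_by_context named list of [epoch_tensor()]s.
#' @param seed RNG seed for the draw.
#' @param n_max optional cap on the matched count.
#' @return named list of epoch tensors, all with the same trial count; the
#'   selected indices are attached as attribute `"selected"`.
#' @export
match_trial_counts <- function(epochs_by_context, seed = 1, n_max = NULL) {
  counts <- vapply(epochs_by_context, n_trials, integer(1))
  empty <- names(counts)[counts == 0]
  if (length(empty)) stop("context(s) with no trials: ", paste(empty, collapse = ", "))
  n <- min(counts)
  if (!is.null(n_max)) n <- min(n, n_max)
  seeds <- derive_seeds(seed, length(counts))
  out <- epochs_by_context
  sel_log <- list()
  for (i in seq_along(out)) {
    ni <- counts[i]
    sel <- if (ni == n) seq_len(ni) else sort(with_seed(seeds[i], sample.int(ni, n)))
    sel_log[[names(counts)[i]]] <- sel
    ep <- out[[i]]
    ep$data <- ep$data[sel, , , drop = FALSE]
    out[[i]] <- ep
  }
  attr(out, "selected") <- sel_log
  out
}
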