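#' Linear probe geometry
#'
#' Contact 1 is the most superficial contact; indices increase with depth.
#'
#' @param n_contacts number of contacts (>= 4).
#' @param pitch_um inter-contact distance in micrometres.
#' @return list of class `"probe_geometry"` with fields `n_contacts`,
#'   `pitch_um` and derived `span_um = (n_contacts - 1) * pitch_um`.
#' @export
probe_geometry <- function(n_contacts = 16, pitch_um = 50) {
  n_contacts <- as.integer(n_contacts)
  if (n_contacts < 4) stop("n_contacts must be >= 4")
  if (pitch_um <= 0) stop("pitch_um must be > 0")
  structure(list(n_contacts = n_contacts, pitch_um = pitch_um,
                 span_um = (n_contacts - 1) * pitch_um),
            class = "probe_geometry")
}

#' Multichannel recording
#'
#' @param signal contacts x samples voltage matrix (microvolts). Row 1 is the
#'   most superficial contact.
#' @param fs sampling rate, Hz.
#' @param geometry a [probe_geometry()].
#' @param subject_id label.
#' @param domain signal domain label, `"lfp"` (raw/filtered voltage) or
#'   `"mua"` (rectified envelope).
#' @return list of class `"laminar_recording"`.
#' @export
new_recording <- function(signal, fs, geometry = probe_geometry(),
                          subject_id = "subject", domain = "lfp") {
  signal <- as.matrix(signal)
  if (nrow(signal) != geometry$n_contacts)
    stop("signal has ", nrow(signal), " rows but the probe has ",
         geometry$n_contacts, " contacts")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  structure(list(signal = signal, fs = fs, geometry = geometry,
                 subject_id = subject_id, domain = domain),
            class = "laminar_recording")
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat(sprintf("<laminar_recording '%s'> %d contacts x %d samples @ %g Hz (%s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs, x$domain))
  invisible(x)
}

#' Event table
#'
#' Per-trial stimulus events. Onsets are sample indices at `fs` (stored as an
#' attribute). Contexts are `control`, `redundant`, `deviant`; runs are
#' `control`, `oddball_A`, `oddball_B`.
#'
#' @param onset_sample,orientation_deg,context,run,duration_samples columns.
#' @param fs sampling rate the onsets refer to.
#' @return data.frame of class `"event_table"`.
#' @export
event_table <- function(onset_sample, orientation_deg, context, run,
                        duration_samples, fs = 10000) {
  ev <- data.frame(onset_sample = as.integer(onset_sample),
                   orientation_deg = as.numeric(orientation_deg),
                   context = as.character(context),
                   run = as.character(run),
                   duration_samples = as.integer(duration_samples),
                   stringsAsFactors = FALSE)
  attr(ev, "fs") <- fs
  class(ev) <- c("event_table", "data.frame")
  validate_events(ev)
  ev
}

#' Validate an event table
#'
#' Checks onsets strictly increasing within each run, control context confined
#' to the control run, and that each oddball run carries exactly one deviant
#' and one redundant orientation that are orthogonal (90 degrees apart).
#'
#' @param ev an [event_table()].
#' @return the table, invisibly; errors describe the violated invariant.
#' @export
validate_events <- function(ev) {
  ok_ctx <- c("control", "redundant", "deviant")
  if (!all(ev$context %in% ok_ctx))
    stop("unknown context value(s): ", paste(setdiff(ev$context, ok_ctx), collapse = ", "))
  allowed <- c(0, 30, 45, 60, 90, 120, 135, 150, 180)
  if (!all(ev$orientation_deg %in% allowed))
    stop("orientation_deg outside the allowed set")
  for (r in unique(ev$run)) {
    on <- ev$onset_sample[ev$run == r]
    if (any(diff(on) <= 0)) stop("onsets not strictly increasing within run '", r, "'")
  }
  if (any(ev$context == "control" & ev$run != "control"))
    stop("context 'control' appears outside the control run")
  if (any(ev$run == "control" & ev$context != "control"))
    stop("the control run must contain only control-context trials")
  for (r in setdiff(unique(ev$run), "control")) {
    sub <- ev[ev$run == r, ]
    dev <- unique(sub$orientation_deg[sub$context == "deviant"])
    red <- unique(sub$orientation_deg[sub$context == "redundant"])
    if (length(dev) != 1 || length(red) != 1)
      stop("oddball run '", r, "' must have exactly one deviant and one redundant orientation")
    if (abs(dev - red) %% 180 != 90)
      stop("deviant and redundant orientations in run '", r, "' are not orthogonal")
  }
  invisible(ev)
}

#' Epoch tensor
#'
#' Trials x contacts x time array in a named signal domain, with a time axis
#' in milliseconds relative to stimulus onset.
#'
#' @param data 3-D array (trials x contacts x timepoints).
#' @param time_ms monotone increasing time axis, ms.
#' @param domain one of `lfp`, `csd`, `mua`, `tf_complex`.
#' @param context context label (or `"all"`).
#' @param fs sampling rate of the time axis, Hz.
#' @param contact_labels optional labels (defaults to contact indices).
#' @return list of class `"epoch_tensor"`.
#' @export
epoch_tensor <- function(data, time_ms, domain, context = "all", fs = NULL,
                         contact_labels = NULL) {
  stopifnot(length(dim(data)) == 3, length(time_ms) == dim(data)[3])
  if (any(diff(time_ms) <= 0)) stop("time_ms must be monotone increasing")
  structure(list(data = data, time_ms = time_ms, domain = domain,
                 context = context, fs = fs,
                 contact_labels = contact_labels %||% seq_len(dim(data)[2])),
            class = "epoch_tensor")
}

#' @export
print.epoch_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_tensor %s/%s> %d trials x %d contacts x %d timepoints [%g, %g] ms\n",
              x$domain, x$context, d[1], d[2], d[3], min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]
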