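mua_smooth_kernel <- function(fs, fwhm_ms = 10, is_sd = FALSE) {
  sigma_ms <- if (is_sd) fwhm_ms else fwhm_ms / (2 * sqrt(2 * log(2)))
  sigma <- sigma_ms * fs / 1000
  half <- ceiling(3 * sigma)
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Multiunit activity envelope
#'
#' Per contact: zero-phase 500--4000 Hz band-pass; common average reference
#' against the mean of the other n-1 band-passed contacts (removes EMG-like
#' common-mode artifacts); full-wave rectification; smoothing with a 10 ms
#' FWHM Gaussian kernel (truncated at 3 SD; set `is_sd` in the config to read
#' the 10 ms as the Gaussian SD instead); decimation to 1000 Hz. The Gaussian
#' itself suppresses content near and above the output Nyquist (its gain at
#' 400 Hz is below 10^-24), so it doubles as the anti-alias filter.
#'
#' @param rec a [new_recording()] at >= 10 kHz.
#' @param band band edges, Hz.
#' @param smooth_fwhm_ms Gaussian width, ms.
#' @param is_sd interpret `smooth_fwhm_ms` as the SD rather than the FWHM.
#' @param out_rate envelope output rate, Hz.
#' @return a recording in the `mua` domain at `out_rate`.
#' @export
compute_mua <- function(rec, band = c(500, 4000), smooth_fwhm_ms = 10,
                        is_sd = FALSE, out_rate = 1000) {
  stopifnot(inherits(rec, "laminar_recording"))
  if (rec$fs < 8000) stop("fs below 8 kHz: the 500-4000 Hz band is unattainable")
  env <- mua_envelope_mat(t(rec$signal), rec$fs, band, smooth_fwhm_ms, is_sd,
                          out_rate)
  out <- rec
  out$signal <- t(env)
  out$fs <- out_rate
  out$domain <- "mua"
  out
}

# Core MUA chain on a samples x contacts matrix (avoids re-transposing the
# full-rate signal when the caller already holds it in this orientation).
mua_envelope_mat <- function(X, fs, band = c(500, 4000), smooth_fwhm_ms = 10,
                             is_sd = FALSE, out_rate = 1000) {
  bt <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- .filtfilt_sos_mat(X, ba_to_sos(bt$b, bt$a))
  n <- ncol(x)
  if (n > 1) {
    tot <- rowSums(x)
    x <- x - (tot - x) / (n - 1)  # common average reference excluding self
  }
  kern <- mua_smooth_kernel(fs, smooth_fwhm_ms, is_sd)
  # rectification happens inside the fused smoother (|x| then Gaussian)
  .smooth_decimate_mat(x, kern, round(fs / out_rate), rectify = TRUE)
}

#' Normalise MUA to the ongoing standard deviation
#'
#' Divides by a single scalar per recording: the SD of the continuous MUA
#' envelope pooled over all channels and timepoints. The scalar is stored on
#' the output (`attr(, "ongoing_sd")`).
#'
#' @param epochs an [epoch_tensor()] in the `mua` domain (or a list of them).
#' @param continuous the continuous `mua` recording the epochs were cut from;
#'   if omitted, the pooled SD of the epochs themselves is used.
#' @return the normalised input, same shape.
#' @export
normalize_mua <- function(epochs, continuous = NULL) {
  s <- if (!is.null(continuous)) sd(continuous$signal)
       else if (inherits(epochs, "epoch_tensor")) sd(epochs$data)
       else sd(unlist(lapply(epochs, function(e) as.numeric(e$data))))
  if (!is.finite(s) || s == 0) stop("ongoing MUA standard deviation is zero")
  scale1 <- function(e) { e$data <- e$data / s; attr(e, "ongoing_sd") <- s; e }
  if (inherits(epochs, "epoch_tensor")) scale1(epochs)
  else { out <- lapply(epochs, scale1); attr(out, "ongoing_sd") <- s; out }
}

#' Select the analysis orientation
#'
#' Returns the orientation with the strongest normalised MUA response in the
#' first 100 ms after stimulus onset, averaged over trials, kept contacts and
#' contexts. If even the best response stays below the floor the subject is
#' flagged as having "no clear response" and should be excluded from MUA
#' statistics.
#'
#' @param mua_by_orientation named list (orientation -> `mua` epoch tensor,
#'   pooled over contexts).
#' @param kept_contacts contacts entering the average (default all).
#' @param window_ms response window, ms.
#' @param floor "no clear response" threshold in normalised units.
#' @return list with `orientation`, `response` (per-orientation means),
#'   `no_clear_response` and `tie` flags.
#' @export
select_best_orientation <- function(mua_by_orientation, kept_contacts = NULL,
                                    window_ms = c(0, 100), floor = 0.5) {
  stopifnot(length(mua_by_orientation) >= 1)
  oris <- names(mua_by_orientation)[order(as.numeric(names(mua_by_orientation)))]
  resp <- vapply(oris, function(o) {
    e <- mua_by_orientation[[o]]
    sel_t <- e$time_ms >= window_ms[1] & e$time_ms <= window_ms[2]
    sel_c <- if (is.null(kept_contacts)) seq_len(dim(e$data)[2])
             else match(kept_contacts, e$contact_labels)
    mean(e$data[, sel_c, sel_t, drop = FALSE])
  }, numeric(1))
  best <- oris[which.max(resp)]
  tie <- sum(abs(resp - max(resp)) < 1e-12) > 1
  if (tie) best <- oris[which(abs(resp - max(resp)) < 1e-12)[1]]
  list(orientation = as.numeric(best), response = resp,
       no_clear_response = max(resp) < floor, tie = tie)
}
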