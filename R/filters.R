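# Butterworth low-pass as cascaded biquads (even order only). Designing in
# second-order sections keeps narrow-band high-order filters numerically
# stable, which a single b/a polynomial at 110 Hz / 10 kHz is not.
butter_lowpass_sos <- function(order, fc, fs) {
  stopifnot(order %% 2 == 0, fc > 0, fc < fs / 2)
  wc <- 2 * fs * tan(pi * fc / fs)  # pre-warped analog cutoff
  K <- 2 * fs
  k <- seq_len(order / 2)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  sos <- t(vapply(theta, function(th) {
    a <- -2 * cos(th) * wc   # s^2 + a s + wc^2
    b <- wc^2
    d0 <- K^2 + a * K + b
    c(b / d0, 2 * b / d0, b / d0, 1, (2 * b - 2 * K^2) / d0, (K^2 - a * K + b) / d0)
  }, numeric(6)))
  sos
}

# Factor a transfer function b/a into second-order sections (conjugate pole
# pairs matched with the nearest zero pair). Used so high-order band-pass
# designs from signal::butter run through the fast biquad cascade.
ba_to_sos <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  z <- polyroot(rev(b))
  p <- polyroot(rev(a))
  gain <- b[1]
  pair_up <- function(r) {
    r <- r[order(-Mod(r), Arg(r))]
    used <- rep(FALSE, length(r))
    pairs <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      cand <- which(!used)
      if (length(cand)) {
        j <- cand[which.min(abs(r[cand] - Conj(r[i])))]  # nearest conjugate
        used[j] <- TRUE
        pairs[[length(pairs) + 1]] <- c(r[i], r[j])
      } else pairs[[length(pairs) + 1]] <- c(r[i], 0 + 0i)
    }
    pairs
  }
  pp <- pair_up(p)
  zp <- pair_up(z)
  sos <- matrix(0, length(pp), 6)
  for (s in seq_along(pp)) {
    # nearest remaining zero pair
    if (length(zp)) {
      dd <- vapply(zp, function(q) min(Mod(q[1] - pp[[s]][1])), numeric(1))
      q <- zp[[which.min(dd)]]
      zp <- zp[-which.min(dd)]
      num <- Re(c(1, -(q[1] + q[2]), q[1] * q[2]))
    } else num <- c(1, 0, 0)
    den <- Re(c(1, -(pp[[s]][1] + pp[[s]][2]), pp[[s]][1] * pp[[s]][2]))
    sos[s, ] <- c(num, den)
  }
  sos[1, 1:3] <- sos[1, 1:3] * Re(gain)
  sos
}

# Magnitude response of a zero-phase (squared) SOS cascade at frequencies f.
sos_mag2 <- function(sos, f, fs) {
  z <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    h <- h * num / den
  }
  Mod(h)^2  # forward-backward application squares the magnitude
}

zero_phase_sos <- function(x_mat_contacts_by_samples, sos) {
  t(.filtfilt_sos_mat(t(x_mat_contacts_by_samples), sos))
}

zero_phase_ba <- function(x_mat_contacts_by_samples, b, a) {
  t(.filtfilt_mat(t(x_mat_contacts_by_samples), b, a))
}

#' Low-pass filter the LFP
#'
#' Zero-phase (forward-backward) Butterworth low-pass applied per contact.
#' The cutoff is treated as the passband edge: the -3 dB point sits ~22%
#' above it so that the passband stays flat (< 0.1 dB ripple below 100 Hz at
#' the default 110 Hz cutoff) while attenuation reaches 40 dB well before
#' 200 Hz.
#'
#' @param rec a [new_recording()] in the `lfp` domain.
#' @param cutoff_hz passband edge, Hz.
#' @param order filter order (even; applied twice, so the effective roll-off
#'   doubles).
#' @return a filtered recording.
#' @export
lowpass_lfp <- function(rec, cutoff_hz = 110, order = 8) {
  stopifnot(inherits(rec, "laminar_recording"))
  if (cutoff_hz >= rec$fs / 2) stop("cutoff must be below the Nyquist frequency")
  sos <- butter_lowpass_sos(order, cutoff_hz * 1.22, rec$fs)
  out <- rec
  out$signal <- zero_phase_sos(rec$signal, sos)
  out
}

# Fused low-pass + decimation used by the pipeline (samples x contacts in).
lowpass_decimate_mat <- function(X, fs, cutoff_hz, out_rate, order = 8) {
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  factor <- round(fs / out_rate)
  sos <- butter_lowpass_sos(order, cutoff_hz * 1.22, fs)
  X <- .filtfilt_sos_mat(X, sos)
  X[seq(1, nrow(X), by = factor), , drop = FALSE]
}

#' Decimate a recording
#'
#' Integer-factor downsampling. The caller is expected to have band-limited
#' the signal (e.g. [lowpass_lfp()]); an optional guard low-pass at 0.4 times
#' the output rate is applied first.
#'
#' @param rec a recording.
#' @param out_rate target rate, Hz (must divide `rec$fs`).
#' @param guard apply the anti-alias guard filter.
#' @return a recording at `out_rate`.
#' @export
decimate_recording <- function(rec, out_rate = 1000, guard = TRUE) {
  factor <- rec$fs / out_rate
  if (abs(factor - round(factor)) > 1e-9) stop("out_rate must divide fs")
  factor <- round(factor)
  if (factor == 1) return(rec)
  x <- rec$signal
  if (guard) x <- zero_phase_sos(x, butter_lowpass_sos(4, 0.4 * out_rate, rec$fs))
  out <- rec
  out$signal <- x[, seq(1, ncol(x), by = factor), drop = FALSE]
  out$fs <- out_rate
  out
}

#' Epoch a recording around stimulus events
#'
#' Cuts a trials x contacts x time tensor from a continuous recording, with
#' the time axis in ms relative to stimulus onset. Event onsets may be at a
#' different (original) sampling rate; they are mapped onto the recording's
#' rate.
#'
#' @param rec a recording.
#' @param events an [event_table()] (onsets at `attr(events, "fs")`).
#' @param window_ms c(pre, post) epoch window, ms relative to onset.
#' @param context context label stored on the tensor.
#' @return an [epoch_tensor()].
#' @export
epoch_recording <- function(rec, events, window_ms = c(-250, 750),
                            context = "all") {
  ev_fs <- attr(events, "fs") %||% rec$fs
  onset <- round((events$onset_sample - 1) * rec$fs / ev_fs) + 1
  o0 <- round(window_ms[1] * rec$fs / 1000)
  o1 <- round(window_ms[2] * rec$fs / 1000)
  n <- ncol(rec$signal)
  bad <- which(onset + o0 < 1 | onset + o1 > n)
  if (length(bad))
    stop("epoch window exceeds recording bounds for trial(s): ",
         paste(bad, collapse = ", "))
  nt <- o1 - o0 + 1
  nc <- nrow(rec$signal)
  dat <- array(0, c(length(onset), nc, nt))
  for (i in seq_along(onset))
    dat[i, , ] <- rec$signal[, (onset[i] + o0):(onset[i] + o1)]
  epoch_tensor(dat, time_ms = seq(o0, o1) / rec$fs * 1000,
               domain = rec$domain, context = context, fs = rec$fs)
}
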