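#' Morlet wavelet grid
#'
#' 100 equally spaced wavelets from 2 to 101 Hz (1 Hz resolution), with the
#' number of cycles increasing linearly from 0.5 at 2 Hz to 20 at 101 Hz,
#' evaluated every 4 ms.
#'
#' @param n number of wavelets.
#' @param fmin,fmax frequency range, Hz.
#' @param cycles c(first, last) cycle counts.
#' @param hop_ms coefficient spacing, ms.
#' @return list of class `"wavelet_grid"` with `freqs`, `cycles`, `hop_ms`
#'   and per-wavelet temporal SD `sigma_t` (s).
#' @export
wavelet_grid <- function(n = 100, fmin = 2, fmax = 101, cycles = c(0.5, 20),
                         hop_ms = 4) {
  freqs <- seq(fmin, fmax, length.out = n)
  cyc <- seq(cycles[1], cycles[2], length.out = n)
  structure(list(freqs = freqs, cycles = cyc, hop_ms = hop_ms,
                 sigma_t = cyc / (2 * pi * freqs)),
            class = "wavelet_grid")
}

#' Morlet wavelet decomposition of epoched LFP
#'
#' Convolves every trial and contact with complex Morlet wavelets
#' (complex exponential under a Gaussian envelope of SD
#' `cycles / (2 pi f)`), amplitude-normalised so that a unit-amplitude
#' sinusoid at a grid frequency yields coefficient magnitude 1. Coefficients
#' are returned on the hop grid inside `out_window_ms`; output bins whose
#' wavelet support (3 SD) is not fully covered by the epoch are flagged in
#' the `edge_flag` attribute.
#'
#' @param epochs an [epoch_tensor()] in the `lfp` domain.
#' @param grid a [wavelet_grid()].
#' @param out_window_ms output time range, ms (default -250 ms pre-onset to
#'   250 ms post-offset of a 500 ms stimulus).
#' @return list of class `"tf_tensor"`: complex array trials x contacts x
#'   frequency x time, plus `freqs`, `time_ms`, `context`.
#' @export
morlet_decompose <- function(epochs, grid = wavelet_grid(),
                             out_window_ms = c(-250, 750)) {
  stopifnot(inherits(epochs, "epoch_tensor"))
  fs <- epochs$fs
  hop <- grid$hop_ms * fs / 1000
  if (abs(hop - round(hop)) > 1e-9)
    stop("hop is not a multiple of the sample interval at fs = ", fs, " Hz")
  hop <- round(hop)
  tm <- epochs$time_ms
  dt <- 1000 / fs
  t_out <- seq(max(out_window_ms[1], tm[1]), min(out_window_ms[2], tm[length(tm)]),
               by = grid$hop_ms)
  idx_out <- round((t_out - tm[1]) / dt) + 1

  d <- dim(epochs$data)
  nf <- length(grid$freqs)
  n <- d[3]
  max_half <- ceiling(3 * max(grid$sigma_t) * fs)
  nfft <- nextn(n + 2 * max_half + 1)
  # kernel spectra, centred so that convolution output aligns with the input
  KF <- matrix(0 + 0i, nfft, nf)
  for (j in seq_len(nf)) {
    half <- ceiling(3 * grid$sigma_t[j] * fs)
    tt <- (-half:half) / fs
    env <- exp(-tt^2 / (2 * grid$sigma_t[j]^2))
    kern <- env * exp(2i * pi * grid$freqs[j] * tt) * (2 / sum(env))
    buf <- complex(length.out = nfft)
    buf[c(nfft - half + seq_len(half), seq_len(half + 1))] <-
      kern  # wrap: negative lags at the tail
    KF[, j] <- fft(buf)
  }

  out <- array(0i, c(d[1], d[2], nf, length(idx_out)))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      xf <- fft(c(epochs$data[tr, ch, ], numeric(nfft - n)))
      W <- mvfft(KF * xf, inverse = TRUE) / nfft
      out[tr, ch, , ] <- t(W[idx_out, , drop = FALSE])
    }
  }
  edge <- outer(3 * grid$sigma_t * 1000, t_out,
                function(supp, t0) t0 - supp < tm[1] | t0 + supp > tm[length(tm)])
  structure(list(coef = out, freqs = grid$freqs, time_ms = t_out,
                 context = epochs$context, contact_labels = epochs$contact_labels,
                 edge_flag = edge, normalization = "unit response to unit sinusoid"),
            class = "tf_tensor")
}
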