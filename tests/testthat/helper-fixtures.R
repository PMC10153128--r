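# Small fixtures shared across the suite. Everything is generated in code.

tiny_geometry <- function() probe_geometry(16, 50)

tiny_recording <- function(n = 10000, fs = 10000, seed = 1, nc = 16) {
  set.seed(seed)
  new_recording(matrix(rnorm(nc * n), nc, n), fs, probe_geometry(nc, 50), "tiny")
}

tiny_events <- function(n_trials = 3, fs = 10000, start = 5000, step = 10000) {
  event_table(onset_sample = start + (0:(n_trials - 1)) * step,
              orientation_deg = rep(45, n_trials),
              context = rep("control", n_trials),
              run = rep("control", n_trials),
              duration_samples = 5000, fs = fs)
}

# A tf_tensor with prescribed phases (unit magnitude), for synchrony tests.
phase_tensor <- function(phase_fun, nt = 10, nc = 2, nf = 1, nT = 20,
                         freqs = seq_len(nf)) {
  coef <- array(0i, c(nt, nc, nf, nT))
  for (tr in seq_len(nt)) for (ch in seq_len(nc))
    for (f in seq_len(nf)) for (tt in seq_len(nT))
      coef[tr, ch, f, tt] <- exp(1i * phase_fun(tr, ch, f, tt))
  structure(list(coef = coef, freqs = freqs,
                 time_ms = seq(0, by = 4, length.out = nT),
                 context = "test", contact_labels = seq_len(nc)),
            class = "tf_tensor")
}

# Sinusoidal single-channel epoch at a given frequency.
sine_epochs <- function(f_hz, fs = 1000, window_s = c(-0.4, 0.9), amp = 1) {
  t <- seq(window_s[1], window_s[2], by = 1 / fs)
  epoch_tensor(array(amp * sin(2 * pi * f_hz * t), c(1, 1, length(t))),
               t * 1000, "lfp", fs = fs)
}
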