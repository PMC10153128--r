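#' Forward LFP profile of a current source density depth profile
#'
#' One-dimensional volume conductor with unit conductivity: the voltage is the
#' double cumulative sum of the current density along depth (times the squared
#' contact pitch, with the sign chosen so that the sinks-negative second
#' spatial difference estimator recovers the profile exactly at interior
#' contacts).
#'
#' @param profile current density per contact (zero net sum for a physical
#'   dipole).
#' @param pitch_um contact pitch, micrometres.
#' @return voltage per contact.
#' @export
csd_forward_lfp <- function(profile, pitch_um = 50) {
  w <- cumsum(cumsum(profile))
  -pitch_um^2 * c(0, w[-length(w)])
}

# 1/f (and band-limited) Gaussian noise, two independent channels per inverse
# FFT via the real/imaginary parts of a circularly-symmetric complex spectrum.
shaped_noise <- function(n, n_channels, fs, shape_fun) {
  npad <- nextn(n)
  f <- (seq_len(npad) - 1) * fs / npad
  f_fold <- pmin(f, fs - f)
  amp <- shape_fun(f_fold)
  amp[1] <- 0
  out <- matrix(0, n_channels, n)
  for (j in seq_len(ceiling(n_channels / 2))) {
    spec <- complex(real = rnorm(npad), imaginary = rnorm(npad)) * amp
    x <- fft(spec, inverse = TRUE) / sqrt(npad)
    out[2 * j - 1, ] <- Re(x[seq_len(n)])
    if (2 * j <= n_channels) out[2 * j, ] <- Im(x[seq_len(n)])
  }
  out
}

scale_rows_sd <- function(x, sd_target) {
  s <- apply(x, 1, sd)
  s[s == 0] <- 1
  x * (sd_target / s)
}

# Linear interpolation upsampling by an integer factor (content is band
# limited far below the original Nyquist, so images are negligible). The
# index/weight plan is precomputed once and shared across contacts.
upsample_plan <- function(n_in, factor, n_out) {
  pos <- (seq_len(n_out) - 1) / factor
  i <- pmin(floor(pos) + 1, n_in)
  list(i = i, i2 = pmin(i + 1, n_in), w = pos - (i - 1))
}

upsample_linear <- function(x, plan) {
  x[plan$i] * (1 - plan$w) + x[plan$i2] * plan$w
}

# Accumulate waveform instances at integer sample indices, duplicate-safe.
add_events <- function(signal_row, idx, amps, wave) {
  nw <- length(wave)
  n <- length(signal_row)
  keep <- idx >= 1 & idx + nw - 1 <= n
  idx <- as.integer(idx[keep]); amps <- amps[keep]
  if (!length(idx)) return(signal_row)
  all_idx <- rep(idx, each = nw) + rep(seq_len(nw) - 1L, times = length(idx))
  all_val <- rep(amps, each = nw) * rep(wave, times = length(idx))
  .add_at(signal_row, all_idx, all_val)
}

# Biphasic extracellular spike waveform, ~1 ms, energy in the 500-4000 Hz band.
spike_waveform <- function(fs) {
  t <- (0:round(0.0012 * fs)) / fs * 1000  # ms
  w <- -exp(-((t - 0.25) / 0.12)^2) + 0.55 * exp(-((t - 0.65) / 0.2)^2)
  w / max(abs(w))
}

#' Simulate a laminar oddball recording
#'
#' Forward model with four additive components: (i) spatially-correlated 1/f
#' background plus depth-profiled gamma/alpha-beta band noise (the spectral
#' gradient used by layer-4 alignment), (ii) a stimulus-evoked laminar dipole
#' built by double spatial integration of a zero-sum current profile, (iii)
#' Hann-windowed oscillatory bursts with per-trial random phase (induced, not
#' evoked) whose power follows the per-context gains in `truth`, and (iv)
#' Poisson-timed biphasic spiking transients with 500--4000 Hz energy whose
#' rate follows the gains. Fully reproducible from `seed`.
#'
#' @param events an [event_table()].
#' @param truth a [ground_truth()].
#' @param geometry a [probe_geometry()].
#' @param fs sampling rate, Hz (>= 10000 when spiking effects are present).
#' @param seed RNG seed.
#' @param subject_id label.
#' @return a [new_recording()].
#' @export
simulate_recording <- function(events, truth, geometry = probe_geometry(),
                               fs = 10000, seed = 1, subject_id = "sim") {
  validate_events(events)
  stopifnot(inherits(truth, "ground_truth"))
  has_mua <- truth$spikes$background_hz > 0 || truth$spikes$evoked_hz > 0 ||
    any(vapply(truth$effects, function(e) e$kind == "mua_rate", logical(1)))
  if (has_mua && fs < 10000) stop("fs must be >= 10000 for spiking effects")
  nc <- geometry$n_contacts
  n <- max(events$onset_sample + events$duration_samples) + fs  # 1 s tail
  ms <- fs / 1000
  sd0 <- truth$noise$sd_uv

  with_seed(seed, {
    ## --- background noise (generated at 1 kHz, upsampled) ------------------
    fs1 <- 1000
    factor <- round(fs / fs1)
    n1 <- ceiling(n / factor) + 2
    sig1 <- matrix(0, nc, n1)
    if (sd0 > 0) {
      alpha <- truth$noise$exponent
      pink <- shaped_noise(n1, nc, fs1, function(f) ifelse(f > 0.5, f^(-alpha / 2), 0))
      pink <- scale_rows_sd(pink, sd0)
      cl <- truth$noise$corr_length
      if (cl > 0) {
        K <- outer(seq_len(nc), seq_len(nc), function(i, j) exp(-(i - j)^2 / (2 * cl^2)))
        K <- K / sqrt(rowSums(K^2))  # unit-energy rows preserve per-contact SD
        pink <- K %*% pink
      }
      sig1 <- sig1 + pink
    }
    band_shape <- function(lo, hi) {
      mid <- (lo + hi) / 2; sg <- (hi - lo) / 4
      function(f) exp(-(f - mid)^2 / (2 * sg^2))
    }
    k4 <- truth$l4_contact
    if (truth$noise$gamma_sd > 0) {
      g <- scale_rows_sd(shaped_noise(n1, nc, fs1, band_shape(30, 80)), truth$noise$gamma_sd)
      sig1 <- sig1 + g * as.numeric(seq_len(nc) <= k4 + 1)
    }
    if (truth$noise$albeta_sd > 0) {
      b <- scale_rows_sd(shaped_noise(n1, nc, fs1, band_shape(8, 30)), truth$noise$albeta_sd)
      sig1 <- sig1 + b * as.numeric(seq_len(nc) >= k4 + 2)
    }
    signal <- matrix(0, nc, n)
    if (any(sig1 != 0)) {
      plan <- upsample_plan(n1, factor, n)
      for (k in seq_len(nc)) signal[k, ] <- upsample_linear(sig1[k, ], plan)
    }
    rm(sig1)
    if (truth$noise$mua_floor_sd > 0) {
      floor_seed <- runif(1, 1, 2^31)  # drawn from the seeded R stream
      signal <- .add_white_noise(signal, truth$noise$mua_floor_sd, floor_seed)
    }

    amp_unit <- if (sd0 > 0) sd0 else 1  # baseline-SD unit

    ## --- stimulus-evoked laminar dipole ------------------------------------
    ev <- as.data.frame(events)
    ntr <- nrow(ev)
    if (truth$evoked$amp > 0 || truth$evoked$sup_amp > 0) {
      dip_profile <- function(center) {
        sink <- exp(-((seq_len(nc) - center) / 0.7)^2)
        src <- exp(-((seq_len(nc) - center + 2.2) / 1.1)^2) +
               exp(-((seq_len(nc) - center - 2.2) / 1.1)^2)
        p <- -sink / sum(sink) + src / sum(src)  # zero net current
        v <- csd_forward_lfp(p, geometry$pitch_um)
        v / max(abs(v))
      }
      tcourse <- function(lat, width) {
        tt <- seq(0, 200 * ms - 1) / ms
        exp(-(tt - lat)^2 / (2 * width^2))
      }
      comps <- list()
      if (truth$evoked$amp > 0)
        comps[[1]] <- truth$evoked$amp * amp_unit *
          outer(dip_profile(k4), tcourse(truth$evoked$latency_ms, truth$evoked$width_ms))
      if (truth$evoked$sup_amp > 0)
        comps[[length(comps) + 1]] <- truth$evoked$sup_amp * amp_unit *
          outer(dip_profile(k4 - 4), tcourse(truth$evoked$sup_latency_ms,
                                             truth$evoked$width_ms * 1.4))
      patch <- Reduce(`+`, comps)
      npt <- ncol(patch)
      gains_tr <- rlnorm(ntr, 0, 0.1)
      for (i in seq_len(ntr)) {
        a <- ev$onset_sample[i]
        if (a + npt - 1 <= n) signal[, a:(a + npt - 1)] <-
            signal[, a:(a + npt - 1)] + gains_tr[i] * patch
      }
    }

    ## --- induced oscillatory bursts and phase coupling ----------------------
    for (e in truth$effects) {
      if (e$kind == "burst" && e$amplitude > 0) {
        w0 <- round(e$window_ms[1] * ms); w1 <- round(e$window_ms[2] * ms)
        tt <- seq(w0, w1) / ms / 1000  # seconds relative to onset
        hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(tt)))
        g <- context_gain(e, ev$context)
        phi <- runif(ntr, 0, 2 * pi)
        aj <- rlnorm(ntr, 0, 0.1)
        for (i in seq_len(ntr)) {
          a <- ev$onset_sample[i] + w0
          if (a < 1 || a + length(tt) - 1 > n) next
          wave <- e$amplitude * amp_unit * sqrt(g[i]) * aj[i] * hann *
            sin(2 * pi * e$f0 * tt + phi[i])
          rng <- a:(a + length(tt) - 1)
          signal[e$contacts, rng] <- signal[e$contacts, rng] +
            rep(wave, each = length(e$contacts))
        }
      } else if (e$kind == "coupling" && e$amplitude > 0) {
        w0 <- round(e$window_ms[1] * ms); w1 <- round(e$window_ms[2] * ms)
        tt <- seq(w0, w1) / ms / 1000
        hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(tt)))
        g <- context_gain(e, ev$context)  # coupling probability
        phi_s <- runif(ntr, 0, 2 * pi)
        phi_ind <- runif(ntr, 0, 2 * pi)
        coupled <- runif(ntr) < g
        for (i in seq_len(ntr)) {
          a <- ev$onset_sample[i] + w0
          if (a < 1 || a + length(tt) - 1 > n) next
          amp <- e$amplitude * amp_unit
          ws <- amp * hann * sin(2 * pi * e$f0 * tt + phi_s[i])
          phit <- if (coupled[i]) phi_s[i] else phi_ind[i]
          wt <- amp * hann * sin(2 * pi * e$f0 * tt + phit)
          rng <- a:(a + length(tt) - 1)
          signal[e$seed_contacts, rng] <- signal[e$seed_contacts, rng] +
            rep(ws, each = length(e$seed_contacts))
          signal[e$target_contacts, rng] <- signal[e$target_contacts, rng] +
            rep(wt, each = length(e$target_contacts))
        }
      }
    }

    ## --- spiking transients --------------------------------------------------
    sw <- spike_waveform(fs)
    sp <- truth$spikes
    if (sp$amp_uv > 0) {
      ori_gain <- ifelse(ev$orientation_deg == truth$target_orientation,
                         truth$orientation_gain, 1)
      depth_gain <- exp(-((seq_len(nc) - k4) / 3)^2)
      for (k in seq_len(nc)) {
        times <- numeric(0)
        if (sp$background_hz > 0) {
          nb <- rpois(1, sp$background_hz * n / fs)
          times <- c(times, runif(nb, 1, n))
        }
        if (sp$evoked_hz > 0) {
          lat <- sp$latency_ms + sp$latency_step_ms * abs(k - k4)
          expected <- sp$evoked_hz * depth_gain[k] * ori_gain *
            sp$width_ms / 1000 * sqrt(2 * pi)
          cnt <- rpois(ntr, expected)
          for (i in seq_len(ntr)) {
            if (cnt[i] == 0) next
            t_ms <- rnorm(cnt[i], lat, sp$width_ms)
            t_ms <- t_ms[t_ms > 0 & t_ms < 400]
            times <- c(times, ev$onset_sample[i] + t_ms * ms)
          }
        }
        for (e in truth$effects) {
          if (e$kind != "mua_rate" || !(k %in% e$contacts) || e$amplitude <= 0) next
          g <- context_gain(e, ev$context)
          dur_s <- diff(e$window_ms) / 1000
          cnt <- rpois(ntr, e$amplitude * g * dur_s)
          for (i in seq_len(ntr)) {
            if (cnt[i] == 0) next
            times <- c(times, ev$onset_sample[i] +
                         runif(cnt[i], e$window_ms[1], e$window_ms[2]) * ms)
          }
        }
        if (length(times)) {
          amps <- sp$amp_uv * rlnorm(length(times), 0, 0.25)
          signal[k, ] <- add_events(signal[k, ], round(times), amps, sw)
        }
      }
    }
    new_recording(signal, fs, geometry, subject_id)
  })
}

# Per-subject truths with log-normal between-subject amplitude variation and
# deterministic derived seeds.
cohort_subject_truths <- function(n_subjects, truth, between_subject_sd, seed) {
  seeds <- derive_seeds(seed, 2 * n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    tr <- truth
    if (between_subject_sd > 0) {
      jit <- with_seed(seeds[n_subjects + i],
                       rlnorm(length(tr$effects) + 2, 0, between_subject_sd))
      for (j in seq_along(tr$effects))
        tr$effects[[j]]$amplitude <- tr$effects[[j]]$amplitude * jit[j]
      tr$evoked$amp <- tr$evoked$amp * jit[length(tr$effects) + 1]
      tr$spikes$evoked_hz <- tr$spikes$evoked_hz * jit[length(tr$effects) + 2]
    }
    list(truth = tr, seed = seeds[i], subject_id = sprintf("sim%02d", i))
  })
}

# Events for one simulated session: many-standards control run followed by a
# flip-flop oddball pair built around the truth's target orientation.
cohort_session_events <- function(truth, n_control, n_oddball, fs, seed) {
  ctrl_spec <- sequence_spec("many_standards", n_trials = n_control, fs = fs,
                             seed = seed)
  ctrl <- generate_stimulus_sequence(ctrl_spec)
  odd_spec <- sequence_spec("oddball", n_trials = n_oddball,
                            deviant_orientation = truth$target_orientation,
                            redundant_orientation = (truth$target_orientation + 90) %% 180,
                            fs = fs, seed = seed + 2L)
  end_c <- max(ctrl$onset_sample + ctrl$duration_samples)
  odd_spec$lead_in_ms <- end_c / fs * 1000 + 2000
  a <- generate_stimulus_sequence(odd_spec, run = "oddball_A",
                                  t0_ms = odd_spec$lead_in_ms)
  spec_b <- odd_spec
  spec_b$deviant_orientation <- odd_spec$redundant_orientation
  spec_b$redundant_orientation <- odd_spec$deviant_orientation
  spec_b$seed <- odd_spec$seed + 1L
  end_a <- max(a$onset_sample + a$duration_samples)
  b <- generate_stimulus_sequence(spec_b, run = "oddball_B",
                                  t0_ms = end_a / fs * 1000 + 2000)
  bind_events(ctrl, a, b)
}

#' Generate a synthetic cohort
#'
#' Simulates `n_subjects` independent sessions (many-standards control run
#' plus a flip-flop oddball pair) around a common truth catalogue, with
#' per-subject effect amplitudes drawn log-normally around the truth values
#' and per-subject seeds derived deterministically from the master seed.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param truth a [ground_truth()].
#' @param between_subject_sd log-scale SD of the amplitude variation
#'   (0 gives identical effect parameters in every subject).
#' @param seed master seed.
#' @param n_control,n_oddball trials in the control run and in each oddball
#'   run.
#' @param fs sampling rate, Hz.
#' @param geometry a [probe_geometry()].
#' @param out_dir if given, each subject is written as a recording container
#'   (`subNN.lrec.rds`) plus a `ground_truth.json` manifest, and file paths
#'   are returned instead of in-memory recordings.
#' @return list of per-subject lists `(recording, events, truth)`, or file
#'   paths when `out_dir` is given.
#' @export
generate_cohort <- function(n_subjects = 10, truth = default_ground_truth(),
                            between_subject_sd = 0.2, seed = 1,
                            n_control = 250, n_oddball = 150, fs = 10000,
                            geometry = probe_geometry(), out_dir = NULL) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  subs <- cohort_subject_truths(n_subjects, truth, between_subject_sd, seed)
  res <- vector("list", n_subjects)
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(n_subjects)) {
    s <- subs[[i]]
    evs <- cohort_session_events(s$truth, n_control, n_oddball, fs, s$seed)
    rec <- simulate_recording(evs, s$truth, geometry, fs, s$seed, s$subject_id)
    if (is.null(out_dir)) {
      res[[i]] <- list(recording = rec, events = evs, truth = s$truth)
    } else {
      path <- file.path(out_dir, sprintf("sub%02d.lrec.rds", i))
      write_recording(rec, evs, path)
      res[[i]] <- path
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(seed = seed, n_subjects = n_subjects,
           between_subject_sd = between_subject_sd,
           effects = lapply(truth$effects, function(e)
             e[c("name", "kind", "layer", "window_ms", "gains", "amplitude")])),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
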