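test_that("many-standards sequences are balanced and oddball proportions match", {
  ev <- generate_stimulus_sequence(sequence_spec("many_standards", n_trials = 250,
                                                 seed = 4))
  counts <- table(ev$orientation_deg)
  expect_length(counts, 8)
  expect_lte(diff(range(counts)), 1)
  expect_true(all(abs(counts / 250 - 0.125) <= 0.004))

  odd <- generate_stimulus_sequence(sequence_spec("oddball", n_trials = 150, seed = 5))
  expect_equal(sum(odd$context == "deviant"), 19)   # round(0.125 * 150)
  expect_equal(sum(odd$context == "redundant"), 131)
  expect_equal(odd$context[1], "redundant")
  expect_error(sequence_spec("oddball", deviant_orientation = 45,
                             redundant_orientation = 60), "orthogonal")
})

test_that("flip-flop pair exchanges deviant and redundant roles", {
  pair <- generate_oddball_pair(sequence_spec("oddball", n_trials = 40, seed = 6))
  a <- pair[pair$run == "oddball_A", ]
  b <- pair[pair$run == "oddball_B", ]
  expect_equal(unique(a$orientation_deg[a$context == "deviant"]),
               unique(b$orientation_deg[b$context == "redundant"]))
  expect_equal(unique(a$orientation_deg[a$context == "redundant"]),
               unique(b$orientation_deg[b$context == "deviant"]))
})

test_that("sequence generation is deterministic in the seed", {
  s <- sequence_spec("oddball", n_trials = 80, seed = 12)
  expect_identical(generate_stimulus_sequence(s), generate_stimulus_sequence(s))
})

test_that("zero-amplitude, zero-noise truth yields an all-zero recording", {
  ev <- tiny_events(n_trials = 2, start = 2000, step = 12000)
  rec <- simulate_recording(ev, zero_truth(), tiny_geometry(), 10000, 1)
  expect_true(all(rec$signal == 0))
})

test_that("simulation is bit-identical under the same seed", {
  ev <- tiny_events(n_trials = 2, start = 2000, step = 12000)
  tr <- default_ground_truth()
  r1 <- simulate_recording(ev, tr, tiny_geometry(), 10000, 33)
  r2 <- simulate_recording(ev, tr, tiny_geometry(), 10000, 33)
  expect_identical(r1$signal, r2$signal)
})

test_that("an injected granular sink is recovered by the CSD at the right place/time", {
  ev <- tiny_events(n_trials = 3, start = 6000, step = 12000)
  tr <- zero_truth()
  tr$evoked <- list(amp = 1, latency_ms = 65, width_ms = 10, sup_amp = 0,
                    sup_latency_ms = 85)
  tr$noise$sd_uv <- 0
  rec <- simulate_recording(ev, tr, tiny_geometry(), 10000, 2)
  lfp <- decimate_recording(lowpass_lfp(rec), 1000, guard = FALSE)
  ep <- epoch_recording(lfp, ev, c(-100, 300))
  csd <- compute_csd(ep, tiny_geometry())
  m <- colMeans(csd$data, dims = 1)
  idx <- which(m == min(m), arr.ind = TRUE)
  expect_equal(unname(idx[1]), 8)                      # sink contact = true l4
  t_at <- csd$time_ms[idx[2]]
  expect_true(t_at >= 50 && t_at <= 80)                # near the 65 ms latency
})

test_that("injected current profiles conserve charge and invert through the forward model", {
  set.seed(8)
  for (i in 1:5) {
    prof <- rnorm(16)
    prof <- prof - mean(prof)                          # zero net current
    v <- csd_forward_lfp(prof, 50)
    ep <- epoch_tensor(array(v, c(1, 16, 1)), 1, "lfp", fs = 1000)
    rec <- compute_csd(ep, tiny_geometry(), smoothing = "none")
    expect_equal(rec$data[1, 2:15, 1], prof[2:15], tolerance = 1e-10)
  }
})

test_that("burst energy concentrates in the stated band for adequate durations", {
  # 37.5 Hz Hann burst, 400 ms: time-bandwidth product large enough that
  # >= 80% of its energy sits inside 34-41 Hz +/- 2 Hz
  fs <- 1000
  tt <- seq(0, 0.4, by = 1 / fs)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(tt)))
  burst <- hann * sin(2 * pi * 37.5 * tt)
  spec <- (Mod(fft(c(burst, numeric(4096 - length(burst)))))^2)[1:2048]
  f <- (0:2047) * fs / 4096
  inband <- sum(spec[f >= 32 & f <= 43]) / sum(spec)
  expect_gte(inband, 0.8)
})

test_that("context gains act multiplicatively on induced band power", {
  mk <- function(gain) {
    tr <- zero_truth()
    tr$effects <- list(list(name = "g", kind = "burst", layer = "L2/3",
                            contacts = 5, window_ms = c(100, 400),
                            band_hz = c(35, 45), f0 = 40,
                            gains = c(control = 1, redundant = 1, deviant = gain),
                            amplitude = 1))
    tr
  }
  ctxs <- c("redundant", rep(c("deviant", "redundant"), 3), "deviant")
  ev <- event_table(onset_sample = seq(6000, by = 12000, length.out = 8),
                    orientation_deg = ifelse(ctxs == "deviant", 45, 135),
                    context = ctxs,
                    run = "oddball_A", duration_samples = 5000, fs = 10000)
  pow_diff <- vapply(c(2, 4), function(g) {
    rec <- simulate_recording(ev, mk(g), tiny_geometry(), 10000, 99)
    lfp <- decimate_recording(lowpass_lfp(rec), 1000, guard = FALSE)
    band_power <- function(ctx) {
      ep <- epoch_recording(lfp, ev[ev$context == ctx, ], c(0, 500))
      x <- ep$data[, 5, ep$time_ms >= 100 & ep$time_ms <= 400]
      mean(x^2)
    }
    band_power("deviant") - band_power("redundant")
  }, numeric(1))
  # doubling the (power) gain from 2 to 4 doubles the 1-vs-gain difference:
  # (4-1)/(2-1) = 3 within Monte-Carlo tolerance (identical noise seed)
  expect_equal(pow_diff[2] / pow_diff[1], 3, tolerance = 0.15)
})

test_that("cohorts with zero between-subject SD share effect parameters", {
  tr <- default_ground_truth()
  subs0 <- laminarodd:::cohort_subject_truths(10, tr, 0, 1)
  amps <- vapply(subs0, function(s) s$truth$effects[[1]]$amplitude, numeric(1))
  expect_true(all(amps == amps[1]))
  subs <- laminarodd:::cohort_subject_truths(10, tr, 0.2, 1)
  amps2 <- vapply(subs, function(s) s$truth$effects[[1]]$amplitude, numeric(1))
  expect_gt(length(unique(amps2)), 1)
  expect_identical(vapply(laminarodd:::cohort_subject_truths(10, tr, 0.2, 1),
                          `[[`, integer(1), "seed"),
                   vapply(subs, `[[`, integer(1), "seed"))
})

test_that("generate_cohort writes readable containers and a truth manifest", {
  dir <- tempfile()
  paths <- generate_cohort(n_subjects = 2, truth = zero_truth(),
                           between_subject_sd = 0, seed = 3,
                           n_control = 8, n_oddball = 8, out_dir = dir)
  expect_length(paths, 2)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_recording(paths[[1]])
  expect_s3_class(back$recording, "laminar_recording")
  expect_equal(back$recording$fs, 10000)
  expect_equal(nrow(back$recording$signal), 16)
  unlink(dir, recursive = TRUE)
})
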