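test_that("low-pass filter meets its passband and stopband contract", {
  fs <- 10000
  t <- seq_len(30000) / fs
  mk <- function(f) new_recording(matrix(sin(2 * pi * f * t), 16, length(t),
                                         byrow = TRUE), fs)
  lp10 <- lowpass_lfp(mk(10))
  expect_equal(max(lp10$signal[1, 10000:20000]), 1, tolerance = 0.01)
  lp500 <- lowpass_lfp(mk(500))
  expect_lt(max(abs(lp500$signal[1, 10000:20000])), 10^(-40 / 20))
  expect_error(lowpass_lfp(mk(10), cutoff_hz = 6000), "Nyquist")
  # designed magnitude response: ripple and attenuation of the zero-phase filter
  sos <- laminarodd:::butter_lowpass_sos(8, 110 * 1.22, fs)
  m <- laminarodd:::sos_mag2(sos, c(50, 100, 200), fs)  # single-pass |H|^2
  ripple_db <- abs(20 * log10(m[1:2]))  # zero-phase amplitude = |H|^2
  expect_lt(max(ripple_db), 0.1)
  expect_gt(-20 * log10(m[3]), 40)
})

test_that("filtered white noise matches the designed magnitude response", {
  set.seed(3)
  fs <- 10000
  x <- rnorm(2^17)
  rec <- new_recording(matrix(x, 4, 2^17, byrow = TRUE), fs, probe_geometry(4, 50))
  y <- lowpass_lfp(rec)$signal[1, ]
  pg <- function(v) Mod(fft(v))^2
  f <- (0:(2^17 - 1)) * fs / 2^17
  sel <- f > 5 & f < 400
  bands <- cut(f[sel], seq(0, 400, by = 25))
  emp <- tapply(pg(y)[sel] / pg(x)[sel], bands, mean)
  sos <- laminarodd:::butter_lowpass_sos(8, 110 * 1.22, fs)
  theo <- tapply(laminarodd:::sos_mag2(sos, f[sel], fs)^2, bands, mean)
  expect_equal(as.numeric(emp), as.numeric(theo), tolerance = 0.05)
})

test_that("epoching produces the documented tensor and errors on bounds", {
  rec <- tiny_recording(n = 40000)
  ev <- tiny_events(n_trials = 3, start = 5000, step = 11000)
  ep <- epoch_recording(rec, ev, c(-250, 750))
  expect_equal(dim(ep$data), c(3, 16, 10001))
  expect_equal(range(ep$time_ms), c(-250, 750))
  ev0 <- tiny_events(n_trials = 1, start = 100)
  expect_error(epoch_recording(rec, ev0, c(-250, 750)), "trial\\(s\\): 1")
  # constant signal -> identical epochs
  recc <- new_recording(matrix(5, 16, 40000), 10000)
  epc <- epoch_recording(recc, ev, c(0, 100))
  expect_true(all(epc$data == 5))
})

test_that("CSD of a depth-affine voltage is zero and matches the brute-force oracle", {
  geom <- tiny_geometry()
  # affine in depth: V_k = a + b k, any time course
  tc <- sin(seq(0, 4 * pi, length.out = 50))
  V <- outer(2 + 0.3 * (1:16), tc)
  ep <- epoch_tensor(array(V, c(1, 16, 50)), 1:50, "lfp", fs = 1000)
  cs <- compute_csd(ep, geom, smoothing = "none")
  expect_lt(max(abs(cs$data[1, 2:15, ])), 1e-12)

  # unsmoothed unit-pitch impulse: -d2V/dz2 of (0,0,1,0,0) at contacts 2-4
  g5 <- probe_geometry(5, 1)
  epi <- epoch_tensor(array(c(0, 0, 1, 0, 0), c(1, 5, 1)), 1, "lfp", fs = 1000)
  ci <- compute_csd(epi, g5, smoothing = "none")
  expect_equal(ci$data[1, 2:4, 1], c(-1, 2, -1))

  # random voltages against an explicit finite-difference + kernel loop oracle
  set.seed(5)
  V2 <- array(rnorm(2 * 16 * 200), c(2, 16, 200))
  ep2 <- epoch_tensor(V2, 1:200, "lfp", fs = 1000)
  cs2 <- compute_csd(ep2, geom, smoothing = "hamming")
  k5 <- laminarodd:::csd_depth_kernel("hamming")
  oracle <- array(0, dim(V2))
  for (tr in 1:2) for (tt in 1:200) {
    v <- V2[tr, , tt]
    vp <- c(v[1], v, v[16])
    raw <- vapply(1:16, function(k) -(vp[k] - 2 * vp[k + 1] + vp[k + 2]) / 50^2,
                  numeric(1))
    oracle[tr, , tt] <- vapply(1:16, function(k) {
      sum(k5 * raw[pmin(pmax(k + (-2:2), 1), 16)])
    }, numeric(1))
  }
  expect_lt(max(abs(cs2$data - oracle)) / max(abs(oracle)), 1e-10)
  expect_error(compute_csd(epoch_tensor(array(0, c(1, 4, 3)), 1:3, "lfp"),
                           probe_geometry(4, 50)), "5 contacts")
})

test_that("layer partition follows the 7-above/5-below, 2/5/2/3 rule", {
  lm8 <- layer_partition(8, tiny_geometry())
  expect_equal(lm8$kept_contacts, 1:12)
  expect_equal(unname(lm8$layer_of_contact),
               rep(c("L1", "L2/3", "L4", "L5"), c(2, 5, 2, 3)))
  expect_equal(laminarodd:::layer_contacts(lm8, "L4"), c(8L, 9L))
  expect_error(layer_partition(7, tiny_geometry()), "does not fit")
  expect_error(layer_partition(13, tiny_geometry()), "does not fit")
  for (k in 8:12) expect_length(layer_partition(k, tiny_geometry())$kept_contacts, 12)
})

test_that("av-rec rectifies before layer averaging and matches a loop oracle", {
  geom <- tiny_geometry()
  layers <- layer_partition(8, geom)
  # constant positive CSD passes through unchanged
  cst <- epoch_tensor(array(2, c(3, 16, 10)), 1:10, "csd")
  avc <- avrec(cst, layers)
  expect_true(all(abs(avc$data - 2) < 1e-12))
  expect_true(all(avc$data >= 0))
  # equal and opposite trial-mean currents in one layer do not cancel
  dat <- array(0, c(1, 16, 4))
  dat[1, 8, ] <- 3; dat[1, 9, ] <- -3   # the two L4 contacts
  av2 <- avrec(epoch_tensor(dat, 1:4, "csd"), layers)
  expect_equal(unname(av2$data["L4", ]), rep(3, 4))
  # random tensor vs explicit order-of-operations oracle
  set.seed(6)
  arr <- array(rnorm(5 * 16 * 7), c(5, 16, 7))
  av3 <- avrec(epoch_tensor(arr, 1:7, "csd"), layers)
  for (ly in c("L1", "L2/3", "L4", "L5")) {
    ks <- laminarodd:::layer_contacts(layers, ly)
    oracle <- colMeans(abs(colMeans(arr[, ks, , drop = FALSE], dims = 1)))
    expect_equal(unname(av3$data[ly, ]), unname(oracle), tolerance = 1e-12)
  }
  # sign-flip invariance of whole channels
  arr2 <- arr; arr2[, 3, ] <- -arr2[, 3, ]
  av4 <- avrec(epoch_tensor(arr2, 1:7, "csd"), layers)
  expect_equal(av4$data, av3$data, tolerance = 1e-12)
})

test_that("layer-4 alignment follows its rank-sum and tie-break rules", {
  nc <- 16
  tm <- seq(0, 200, by = 1)
  flat_mua <- matrix(0, nc, length(tm))
  # single informative criterion: CSD sink at contact 7 dominates
  csd <- matrix(0, nc, length(tm))
  csd[7, 60] <- -5
  pw <- matrix(1, nc, 100)
  expect_warning(
    l4 <- align_layer4(flat_mua, csd, pw, tm, freqs = 1:100),
    regexp = NA)
  expect_equal(as.integer(l4), 7L)
  # all criteria tied between two contacts -> superficial wins
  mua2 <- flat_mua; mua2[8, 50] <- 1; mua2[9, 50] <- 1
  csd2 <- matrix(0, nc, length(tm)); csd2[8, 40] <- -1; csd2[9, 40] <- -1
  l42 <- align_layer4(mua2, csd2, pw, tm, freqs = 1:100)
  expect_equal(as.integer(l42), 8L)
})
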