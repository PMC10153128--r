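test_that("wavelet grid matches the documented parameterisation", {
  g <- wavelet_grid()
  expect_length(g$freqs, 100)
  expect_equal(g$freqs, 2:101)
  expect_equal(g$cycles[1], 0.5)
  expect_equal(g$cycles[100], 20)
  expect_true(all(diff(g$cycles) > 0))
  expect_equal(g$hop_ms, 4)
})

test_that("a unit sinusoid yields |W| = 1 at its grid frequency", {
  g <- wavelet_grid()
  ep <- sine_epochs(40)
  tf <- morlet_decompose(ep, g)
  mid <- tf$time_ms > 50 & tf$time_ms < 450
  m <- apply(Mod(tf$coef[1, 1, , mid]), 1, mean)
  expect_equal(m[which(g$freqs == 40)], 1, tolerance = 0.02)
  expect_equal(g$freqs[which.max(m)], 40)
  # zero signal -> all-zero coefficients
  ep0 <- ep; ep0$data[] <- 0
  expect_true(all(Mod(morlet_decompose(ep0, g)$coef) == 0))
  # scaling by c scales power by c^2 exactly
  ep3 <- ep; ep3$data <- ep$data * 3
  tf3 <- morlet_decompose(ep3, g)
  expect_equal(Mod(tf3$coef)^2, 9 * Mod(tf$coef)^2, tolerance = 1e-12)
  # hop must divide the sample interval
  ep_bad <- ep; ep_bad$fs <- 300
  expect_error(morlet_decompose(ep_bad, g), "hop")
})

test_that("white-noise wavelet power is flat across frequencies", {
  set.seed(11)
  g <- wavelet_grid()
  n_tr <- 30
  t <- seq(-0.4, 0.9, by = 1 / 1000)
  dat <- array(rnorm(n_tr * 1 * length(t)), c(n_tr, 1, length(t)))
  tf <- morlet_decompose(epoch_tensor(dat, t * 1000, "lfp", fs = 1000), g)
  mid <- tf$time_ms > 0 & tf$time_ms < 500
  pw <- apply(Mod(tf$coef[, 1, , mid, drop = FALSE])^2, 3, mean)
  # unit response to a unit sinusoid => power of white noise (variance 1,
  # bandwidth fs/2) is proportional to each wavelet's equivalent bandwidth;
  # normalised by that bandwidth the spectrum must be flat
  enbw <- 1 / (2 * sqrt(pi) * g$sigma_t)
  flat <- pw / enbw
  expect_lt(sd(flat[10:95]) / mean(flat[10:95]), 0.15)
})

test_that("induced power localises an injected deviant-only burst and baselines cancel", {
  g <- wavelet_grid()
  layers <- layer_partition(8, tiny_geometry())
  t <- seq(-0.4, 0.9, by = 1 / 1000)
  set.seed(12)
  mk_ctx <- function(burst_amp) {
    dat <- array(rnorm(6 * 12 * length(t), sd = 0.5), c(6, 12, length(t)))
    if (burst_amp > 0) {
      sel <- t >= 0.1 & t <= 0.15
      for (tr in 1:6) {
        ph <- runif(1, 0, 2 * pi)
        wave <- burst_amp * sin(2 * pi * 5 * t[sel] + ph)
        for (ch in 3:7) dat[tr, ch, sel] <- dat[tr, ch, sel] + wave
      }
    }
    morlet_decompose(epoch_tensor(dat, t * 1000, "lfp", fs = 1000,
                                  contact_labels = 1:12), g)
  }
  tfs <- list(control = mk_ctx(0), redundant = mk_ctx(0), deviant = mk_ctx(2))
  tfp <- induced_power(tfs, layers)
  fsel <- tfp$freqs >= 2 & tfp$freqs <= 7
  tsel <- tfp$time_ms >= 100 & tfp$time_ms <= 150
  dd <- tfp$power$deviant - tfp$power$control
  expect_gt(mean(dd["L2/3", fsel, tsel]), 0.5)
  expect_lt(abs(mean(dd["L4", fsel, tsel])), 0.5)
  expect_lt(abs(mean(dd["L2/3", tfp$freqs >= 60, tsel])), 0.1)
  # the baseline shift is context-shared: differences identical to raw power
  raw_c <- colMeans(Mod(tfs$control$coef)^2, dims = 1)
  raw_d <- colMeans(Mod(tfs$deviant$coef)^2, dims = 1)
  raw_dd_l23 <- colMeans(raw_d[3:7, , ] - raw_c[3:7, , ], dims = 1)
  expect_equal(dd["L2/3", , ], raw_dd_l23, tolerance = 1e-12)
})

test_that("stationary noise has near-zero baseline-corrected post-onset power", {
  set.seed(13)
  g <- wavelet_grid()
  layers <- layer_partition(8, tiny_geometry())
  t <- seq(-0.4, 0.9, by = 1 / 1000)
  tfs <- lapply(setNames(nm = c("control", "redundant", "deviant")), function(ctx)
    morlet_decompose(epoch_tensor(array(rnorm(8 * 12 * length(t)),
                                        c(8, 12, length(t))),
                                  t * 1000, "lfp", fs = 1000,
                                  contact_labels = 1:12), g))
  tfp <- induced_power(tfs, layers)
  post <- tfp$time_ms > 0 & tfp$time_ms < 500
  base <- tfp$time_ms >= -200 & tfp$time_ms <= -50
  for (ctx in names(tfp$power)) {
    m <- mean(tfp$power[[ctx]][, , post])
    s <- sd(apply(tfp$power[[ctx]][, , base], 3, mean)) /
      sqrt(sum(post) / 10)  # coarse Monte-Carlo SE on correlated bins
    expect_lt(abs(m), max(3 * s, 0.02))
  }
})

test_that("phase-locking factor R behaves as the circular resultant", {
  # constant lag pi/3 on every trial and timepoint -> raw R exactly 1
  set.seed(14)
  ph <- matrix(runif(10 * 20, 0, 2 * pi), 10)
  tf <- phase_tensor(function(tr, ch, f, tt) ph[tr, tt] + (ch - 1) * pi / 3)
  sp <- compute_ies(tf, c(0, 80))
  expect_equal(sp$R[1, 2, 1], 1, tolerance = 1e-12)
  expect_true(all(is.na(diag(sp$ies[, , 1]))))
  expect_error(compute_ies(phase_tensor(function(...) 0, nt = 3), c(0, 80)),
               "4 trials")
  # R bounded in [0, 1] for arbitrary phases
  tfr <- phase_tensor(function(tr, ch, f, tt) runif(1, 0, 2 * pi), nt = 6, nc = 4)
  spr <- compute_ies(tfr, c(0, 80))
  expect_true(all(spr$R[!is.na(spr$R)] >= 0 & spr$R[!is.na(spr$R)] <= 1))
  expect_true(all(abs(spr$ies[!is.na(spr$ies)]) <= 1))
})

test_that("the surrogate cancels stimulus-locked lags but keeps trial-wise coupling", {
  set.seed(15)
  # lag identical in every trial AND timepoint pattern (purely stimulus locked)
  base <- runif(20, 0, 2 * pi)
  tf_lock <- phase_tensor(function(tr, ch, f, tt) base[tt] + (ch - 1) * 0.8)
  sp_lock <- compute_ies(tf_lock, c(0, 80))
  expect_equal(sp_lock$ies[1, 2, 1], 0, tolerance = 1e-12)
  # shared per-trial random phase (trial-wise coupling) survives the surrogate
  phs <- runif(10, 0, 2 * pi)
  tf_cpl <- phase_tensor(function(tr, ch, f, tt) phs[tr])
  sp_cpl <- compute_ies(tf_cpl, c(0, 80))
  expect_gt(sp_cpl$ies[1, 2, 1], 0.4)
})

test_that("independent phases match the Monte-Carlo resultant expectation", {
  set.seed(16)
  reps <- 400
  rv <- iv <- numeric(reps)
  for (r in seq_len(reps)) {
    phs <- runif(10, 0, 2 * pi); pht <- runif(10, 0, 2 * pi)
    tf <- phase_tensor(function(tr, ch, f, tt) if (ch == 1) phs[tr] else pht[tr],
                       nT = 4)
    s <- compute_ies(tf, c(0, 80))
    rv[r] <- s$R[1, 2, 1]; iv[r] <- s$ies[1, 2, 1]
  }
  # direct Monte-Carlo oracle for E[R] at n = 10 (asymptotically sqrt(pi)/(2 sqrt(n)))
  oracle <- replicate(4000, Mod(mean(exp(1i * runif(10, 0, 2 * pi)))))
  se <- sqrt(sd(rv)^2 / reps + sd(oracle)^2 / 4000)
  expect_lt(abs(mean(rv) - mean(oracle)), 3 * se)
  expect_lt(abs(mean(oracle) - sqrt(pi) / (2 * sqrt(10))), 0.01)
  expect_lt(abs(mean(iv)), 3 * sd(iv) / sqrt(reps))
})

test_that("seed maps average the seed rows of the synchrony spectra", {
  set.seed(17)
  tf <- phase_tensor(function(tr, ch, f, tt) runif(1, 0, 2 * pi),
                     nt = 6, nc = 4, nf = 3)
  sp <- compute_ies(tf, c(0, 80))
  m1 <- ies_seed_map(sp, 1)
  expect_equal(m1[2, ], sp$ies[1, 2, ])
  m12 <- ies_seed_map(sp, c(1, 2))
  expect_equal(m12[3, ], colMeans(sp$ies[1:2, 3, ]))
  expect_error(ies_seed_map(sp, 99), "not in the kept set")
})
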