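# Morlet time-frequency power, baseline normalization, ROI aggregation,
# hemisphere flipping.

test_that("the mother wavelet has the closed-form shape", {
  wp <- wavelet_params()
  w0 <- morlet_mother(0, wp)
  expect_equal(Re(w0), pi^-0.5, tolerance = 1e-12)
  expect_equal(Im(w0), 0)
  t <- seq(-3, 3, by = 0.01)
  expect_equal(Mod(morlet_mother(t, wp)), Mod(morlet_mother(-t, wp)))
  # energy integral vs closed form: int |w|^2 dt = 1 / sqrt(2 pi f_b)
  tt <- seq(-8, 8, by = 1e-3)
  num <- sum(Mod(morlet_mother(tt, wp))^2) * 1e-3
  expect_equal(num, 1 / sqrt(2 * pi * wp$f_b), tolerance = 1e-6)
})

test_that("CWT energy localizes injected oscillations on the frequency grid", {
  ep <- signal_epochs(function(t) sin(2 * pi * 10 * t))
  wp <- wavelet_params(freqs = 5:20)
  tf <- cwt_power(ep, wp)
  prof <- apply(tf$energy[1, 1, , tf$times > -0.5 & tf$times < 1.5], 1, mean)
  expect_equal(wp$freqs[which.max(prof)], 10)
  # zero signal -> zero energy; amplitude doubling -> energy x4
  ep0 <- signal_epochs(function(t) rep(0, length(t)))
  expect_equal(max(cwt_power(ep0, wp)$energy), 0)
  ep2 <- signal_epochs(function(t) 2 * sin(2 * pi * 10 * t))
  tf2 <- cwt_power(ep2, wp)
  mid <- tf$times > 0 & tf$times < 1
  expect_equal(tf2$energy[1, 1, 6, mid], 4 * tf$energy[1, 1, 6, mid],
               tolerance = 1e-10)
})

test_that("wavelets that cannot fit the epoch are refused", {
  ep <- signal_epochs(function(t) sin(2 * pi * 10 * t))   # 3 s epoch
  expect_error(cwt_power(ep, wavelet_params(freqs = c(0.5, 10))),
               "lowest usable frequency")
})

test_that("baseline normalization is exact on constructed energy", {
  ep <- signal_epochs(function(t) sin(2 * pi * 10 * t))
  tf <- cwt_power(ep, wavelet_params(freqs = c(9, 10, 11)))
  tfm <- tfr_condition_mean(tf, rep("a", 2))
  # P == B everywhere -> 0%
  tfc <- tfm; tfc$energy[] <- 5
  out <- baseline_normalize(tfc)
  expect_lt(max(abs(out$energy)), 1e-10)
  # P = 2B after t=0 -> +100%
  tfc2 <- tfm
  tfc2$energy[] <- 1
  tfc2$energy[, , , tfm$times >= 0] <- 2
  out2 <- baseline_normalize(tfc2)
  expect_equal(max(out2$energy), 100, tolerance = 1e-10)
  expect_equal(mean(out2$energy[, , , tfm$times >= 0.5]), 100, tolerance = 1e-10)
  # degenerate zero baseline errors
  tfc3 <- tfm; tfc3$energy[] <- 0
  expect_error(baseline_normalize(tfc3), "baseline")
})

test_that("normalized power is invariant to input scaling", {
  ep <- signal_epochs(function(t) sin(2 * pi * 10 * t) * (1 + 0.5 * (t > 0)))
  wp <- wavelet_params(freqs = 9:11)
  run <- function(scale) {
    e <- ep; e$data <- e$data * scale
    tfn <- baseline_normalize(tfr_condition_mean(cwt_power(e, wp), rep("a", 2)))
    tfn$energy
  }
  expect_equal(run(1), run(7.3), tolerance = 1e-9)
})

test_that("ROI/band aggregation equals a brute-force nested loop", {
  ep <- signal_epochs(function(t) rnorm(length(t)), n_trials = 3,
                      channels = c("C3", "C5", "CP3", "CP5"))
  set.seed(9)
  ep$data[] <- rnorm(length(ep$data))
  wp <- wavelet_params(freqs = 8:16)
  tf <- cwt_power(ep, wp)
  tc <- roi_band_timecourse(tf, c("C3", "CP5"), c(9, 14))
  ch <- match(c("C3", "CP5"), tf$channel_labels)
  fb <- which(tf$freqs >= 9 & tf$freqs <= 14)
  oracle <- matrix(0, 3, length(tf$times))
  for (i in 1:3) for (s in seq_along(tf$times))
    oracle[i, s] <- mean(tf$energy[i, ch, fb, s])
  expect_equal(tc, oracle, tolerance = 1e-12)
  # single electrode, single bin reduces to identity
  tc1 <- roi_band_timecourse(tf, "C3", c(10, 10))
  expect_equal(tc1[2, ], tf$energy[2, 1, 3, ], tolerance = 1e-12)
  expect_error(roi_band_timecourse(tf, "C3", c(100, 120)), "band")
})

test_that("hemisphere flipping swaps homologues and is an involution", {
  m <- test_montage()
  ep <- signal_epochs(function(t) rep(0, length(t)), n_trials = 2,
                      channels = m$labels)
  set.seed(10)
  ep$data[] <- rnorm(length(ep$data))
  f1 <- flip_hemispheres(ep, m, c(TRUE, FALSE))
  c3 <- match("C3", m$labels); c4 <- match("C4", m$labels)
  cz <- match("Cz", m$labels)
  expect_equal(f1$data[1, c4, ], ep$data[1, c3, ])
  expect_equal(f1$data[1, c3, ], ep$data[1, c4, ])
  expect_equal(f1$data[1, cz, ], ep$data[1, cz, ])
  expect_equal(f1$data[2, , ], ep$data[2, , ])   # unselected trial untouched
  f2 <- flip_hemispheres(f1, m, c(TRUE, FALSE))
  expect_equal(f2$data, ep$data)
  expect_identical(f2$flipped, ep$flipped)
})

test_that("hand-locked lateralization is restored by flipping mixed blocks", {
  m <- test_montage()
  sp <- design_spec(n_blocks = 2, trials_per_block = 12, seed = 31,
                    hand_switch_block = 2)
  tr <- generate_design(sp)
  env <- list(times = c(0.3, 0.5, 1.5, 1.7), amps = c(1, 2, 2, 1))
  envs <- list(go = env, `no-change` = env, change = env,
               `no-nogo` = env, nogo = env)
  src <- source_spec("C3", spatial_width = 0.3, band = c(9, 14),
                     amplitude = 6, envelope = envs, lateralization = "contra")
  raw <- simulate_session(tr, m, list(src), noise_scale = 0.2, seed = 32)
  ep <- epoch(rereference(raw), tr$cue_onset_s, meta = tr)
  lat_index <- function(e, sel) {
    c3 <- match("C3", e$channel_labels); c4 <- match("C4", e$channel_labels)
    win <- e$times > 0.6 & e$times < 1.4
    mean(e$data[sel, c3, win]^2) - mean(e$data[sel, c4, win]^2)
  }
  rhb <- tr$standard_hand == "right"
  flipped <- flip_hemispheres(ep, m, !rhb)
  li_rhb <- lat_index(ep, which(rhb))
  li_all <- lat_index(flipped, seq_len(nrow(tr)))
  expect_gt(li_rhb, 0)
  expect_equal(li_all, li_rhb, tolerance = 0.35 * abs(li_rhb))
})

test_that("white-noise wavelet energy grows linearly with trial count", {
  set.seed(12)
  wp <- wavelet_params(freqs = c(10, 15, 20))
  totals <- sapply(c(4, 8, 12, 16), function(n) {
    ep <- signal_epochs(function(t) rep(0, length(t)), n_trials = n)
    ep$data[] <- rnorm(length(ep$data))
    sum(cwt_power(ep, wp)$energy)
  })
  fit <- stats::lm(totals ~ c(4, 8, 12, 16))
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("TFR containers round-trip", {
  ep <- signal_epochs(function(t) sin(2 * pi * 10 * t))
  tf <- cwt_power(ep, wavelet_params(freqs = 9:11))
  base <- file.path(tempdir(), "tfr_test")
  write_tfr(tf, base)
  back <- read_tfr(base)
  expect_equal(dim(back$energy), dim(tf$energy))
  expect_equal(back$freqs, tf$freqs)
  expect_lt(max(abs(back$energy - tf$energy)) / max(tf$energy), 1e-6)
})
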