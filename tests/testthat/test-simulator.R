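# Synthetic EEG generation: topographies, noise spectrum, oscillatory
# sources, and phase-coupling calibration.

test_that("topography is Gaussian in angular distance with peak 1 at center", {
  m <- test_montage()
  src <- source_spec("C3", spatial_width = 0.6, band = c(9, 14))
  w <- topography(m, src)
  expect_equal(unname(w["C3"]), 1)
  d <- angular_distance(m, "C3", names(w))[1, ]
  expect_equal(unname(w), unname(exp(-d^2 / (2 * 0.6^2))), tolerance = 1e-12)
  # monotone non-increasing in distance
  ord <- order(d)
  expect_true(all(diff(w[ord]) <= 1e-12))
  # width -> 0 localizes at the center
  w0 <- topography(m, src, width = 1e-3)
  expect_lt(max(w0[names(w0) != "C3"]), 1e-10)
  expect_error(topography(m, src, center = "XX"), "unknown electrode")
})

test_that("von Mises coupling calibration matches Monte-Carlo resultants", {
  expect_equal(inject_coupling_level(0), 0)
  expect_equal(inject_coupling_level(Inf), 1)
  set.seed(11)
  draws <- oscmotor:::rvonmises(2e5, 2)
  mc <- Mod(mean(exp(1i * draws)))
  expect_equal(inject_coupling_level(2), mc, tolerance = 0.005)
  # inverse mapping
  expect_equal(inject_coupling_level(coupling_for_plv(0.6)), 0.6,
               tolerance = 1e-8)
})

test_that("sessions are deterministic and structurally correct", {
  m <- test_montage()
  tr <- small_trials(6)
  src <- source_spec("C3", band = c(9, 14), amplitude = 5)
  r1 <- simulate_session(tr, m, list(src), noise_scale = 1, seed = 5)
  r2 <- simulate_session(tr, m, list(src), noise_scale = 1, seed = 5)
  expect_identical(r1$data, r2$data)
  expect_equal(nrow(r1$events), 2 * nrow(tr))
  # no sources, zero noise -> all-zero record
  r0 <- simulate_session(tr, m, list(), noise_scale = 0, seed = 1)
  expect_true(all(r0$data == 0))
  # band above Nyquist is refused
  expect_error(
    simulate_session(tr, m, list(source_spec("C3", band = c(100, 130))),
                     seed = 1),
    "Nyquist")
})

test_that("a pure oscillatory source peaks at its band in the periodogram", {
  m <- test_montage()
  tr <- small_trials(6)
  src <- source_spec("Cz", band = c(9.5, 10.5), amplitude = 5)
  raw <- simulate_session(tr, m, list(src), noise_scale = 0, seed = 3)
  x <- raw$data["Cz", ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 250), plot = FALSE,
                          taper = 0, detrend = FALSE)
  expect_equal(sp$freq[which.max(sp$spec)], 10, tolerance = 0.06)
})

test_that("pink noise follows the configured 1/f^alpha spectrum", {
  set.seed(4)
  x <- pink_noise(2^14, 2, srate = 250, alpha = 1, scale = 1)
  sp <- stats::spec.pgram(stats::ts(x[1, ], frequency = 250), plot = FALSE,
                          taper = 0, detrend = FALSE, spans = 15)
  sel <- sp$freq > 1 & sp$freq < 100
  fit <- stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel]))
  expect_equal(unname(fit$coefficients[2]), -1, tolerance = 0.2)
  expect_equal(stats::sd(x[1, ]), 1, tolerance = 1e-6)
})

test_that("envelopes modulate band RMS as configured", {
  m <- test_montage()
  tr <- small_trials(6)
  env <- list(times = c(0.2, 0.3, 1.3, 1.4), amps = c(1, 2, 2, 1))
  envs <- list(go = env, `no-change` = env, change = env,
               `no-nogo` = env, nogo = env)
  src <- source_spec("Cz", band = c(9, 14), amplitude = 5, envelope = envs)
  raw <- simulate_session(tr, m, list(src), noise_scale = 0, seed = 8)
  x <- raw$data["Cz", ]
  r_win <- r_base <- numeric(0)
  for (i in seq_len(nrow(tr))) {
    c0 <- tr$cue_onset_s[i]
    wi <- round((c0 + 0.4) * 250):round((c0 + 1.2) * 250)
    bi <- round((c0 - 0.8) * 250):round((c0 - 0.05) * 250)
    r_win[i] <- mean(x[wi]^2); r_base[i] <- mean(x[bi]^2)
  }
  expect_equal(sqrt(mean(r_win) / mean(r_base)), 2, tolerance = 0.25)
})

test_that("infinite coupling concentration locks the phase difference", {
  m <- test_montage()
  tr <- small_trials(8)
  seed_src <- source_spec("C3", band = c(9, 14), amplitude = 5)
  coupled <- source_spec("F5", band = c(9, 14), amplitude = 5,
                         phase_mode = "coupled", seed_source = 1,
                         concentration = Inf)
  raw <- simulate_session(tr, m, list(seed_src, coupled), noise_scale = 0,
                          seed = 6)
  ep <- epoch(raw, tr$cue_onset_s, locking = "cue")
  ip <- instantaneous_phase(ep, band = c(9, 14),
                            channels = c("C3", "F5"))
  win <- which(ip$times >= 0.9 & ip$times <= 1.1)
  pv <- plv(matrix(ip$phase[, 1, win], nrow = nrow(tr)),
            matrix(ip$phase[, 2, win], nrow = nrow(tr)))
  expect_true(all(pv > 0.99))
})
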