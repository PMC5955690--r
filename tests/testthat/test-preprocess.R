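# Re-referencing, filtering, epoching, artifact rejection, exclusion.

test_that("re-referencing subtracts the earlobe mean and drops refs", {
  set.seed(1)
  x <- matrix(rnorm(5 * 400), 5, 400)
  raw <- raw_from_matrix(x, c("C3", "Cz", "C4", "A1", "A2"))
  out <- rereference(raw, c("A1", "A2"))
  expect_identical(out$channel_labels, c("C3", "Cz", "C4"))
  ref <- colMeans(x[4:5, ])
  for (i in 1:3) expect_equal(out$data[i, ], x[i, ] - ref, tolerance = 1e-12)
  # zero reference leaves data unchanged
  x2 <- x; x2[4:5, ] <- 0
  out2 <- rereference(raw_from_matrix(x2, c("C3", "Cz", "C4", "A1", "A2")),
                      c("A1", "A2"))
  expect_equal(out2$data[1, ], x2[1, ])
  # all-equal channels become zero
  x3 <- matrix(rep(rnorm(400), each = 5), 5, 400)
  out3 <- rereference(raw_from_matrix(x3, c("C3", "Cz", "C4", "A1", "A2")),
                      c("A1", "A2"))
  expect_lt(max(abs(out3$data)), 1e-12)
  expect_error(rereference(raw, c("A1", "XX")), "missing reference")
})

test_that("filtering meets the stop/pass-band requirements", {
  srate <- 250
  t <- seq(0, 20 - 1 / srate, by = 1 / srate)
  mk <- function(f) raw_from_matrix(matrix(sin(2 * pi * f * t), 1), "Cz",
                                    srate = srate)
  # 50 Hz notch: output RMS <= 10% of input
  y50 <- filter_raw(mk(50))$data[1, ]
  expect_lt(stats::sd(y50[500:4500]) / stats::sd(sin(2 * pi * 50 * t)), 0.10)
  # 10 Hz passband: amplitude preserved within 1 dB
  y10 <- filter_raw(mk(10))$data[1, ]
  ratio <- stats::sd(y10[500:4500]) / stats::sd(sin(2 * pi * 10 * t)[500:4500])
  expect_lt(abs(20 * log10(ratio)), 1)
  # DC rejected by the high-pass
  ydc <- filter_raw(raw_from_matrix(matrix(1, 1, length(t)), "Cz",
                                    srate = srate))$data[1, ]
  expect_lt(max(abs(ydc[500:4500])), 1e-3)
  expect_error(filter_raw(mk(10), highpass_hz = 130), "Nyquist")
})

test_that("linear preprocessing stages commute", {
  m <- test_montage()
  tr <- small_trials(4)
  raw <- simulate_session(tr, m, list(source_spec("Cz", band = c(9, 14))),
                          noise_scale = 1, seed = 2)
  a <- filter_raw(rereference(raw))
  b <- rereference(filter_raw(raw))
  expect_equal(a$data, b$data, tolerance = 1e-8)
})

test_that("epoching uses the half-open window with the onset at 1 s", {
  srate <- 250
  n <- srate * 10
  x <- matrix(0, 1, n)
  onset <- 4.0
  x[1, round(onset * srate) + 1] <- 1    # impulse exactly at the event onset
  raw <- raw_from_matrix(x, "Cz", srate = srate)
  ep <- epoch(raw, onset, window = c(-1, 2), baseline = NULL)
  expect_equal(dim(ep$data)[3], 750)
  expect_equal(unname(which(ep$data[1, 1, ] == 1)), 251)  # 0-based index 250
  # constant channel is zeroed by baseline correction
  ep2 <- epoch(raw_from_matrix(matrix(7, 1, n), "Cz"), onset)
  expect_lt(max(abs(ep2$data)), 1e-12)
  # events too close to the edge are marked rejected with a reason
  ep3 <- epoch(raw, c(0.5, onset))
  expect_true(ep3$rejected[1])
  expect_match(ep3$reject_reason[1], "outside record")
  expect_false(ep3$rejected[2])
})

test_that("amplitude rejection is exact at the threshold and idempotent", {
  ep <- signal_epochs(function(t) rep(0, length(t)), n_trials = 3)
  ep$data[1, 1, 100] <- 81
  ep$data[2, 1, 100] <- 79
  ep$data[3, 1, 100] <- -200
  out <- reject_amplitude(ep, 80)
  expect_identical(out$rejected, c(TRUE, FALSE, TRUE))
  expect_identical(reject_amplitude(out, 80)$rejected, out$rejected)
  # brute-force oracle on random data
  set.seed(3)
  epr <- signal_epochs(function(t) rep(0, length(t)), n_trials = 20)
  epr$data[] <- rnorm(length(epr$data), sd = 40)
  oracle <- apply(epr$data, 1, function(tr) max(abs(tr)) > 80)
  expect_identical(reject_amplitude(epr, 80)$rejected, unname(oracle))
})

test_that("subject exclusion is strict at 30%", {
  expect_identical(exclude_subjects(c(a = 0.31, b = 0.30, c = 0.29))$excluded, "a")
  fr <- c(rep(0.1, 23), rep(0.5, 5))
  names(fr) <- paste0("s", 1:28)
  expect_length(exclude_subjects(fr)$excluded, 5)
})

test_that("filtering before epoching preserves in-band power within 5%", {
  srate <- 250
  t <- seq(0, 30 - 1 / srate, by = 1 / srate)
  raw <- raw_from_matrix(matrix(sin(2 * pi * 10 * t), 1), "Cz", srate = srate)
  filt <- filter_raw(raw)
  ep <- epoch(filt, c(5, 10, 15), baseline = NULL)
  p_in <- mean(ep$data^2)
  expect_equal(p_in, 0.5, tolerance = 0.025)
})

test_that("epoch containers round-trip through the header+binary format", {
  m <- test_montage()
  tr <- small_trials(3)
  raw <- simulate_session(tr, m, list(source_spec("Cz", band = c(9, 14))),
                          noise_scale = 1, seed = 4)
  ep <- epoch(rereference(raw), tr$cue_onset_s, meta = tr)
  base <- file.path(tempdir(), "epochs_test")
  write_epochs(ep, base)
  back <- read_epochs(base)
  expect_equal(dim(back$data), dim(ep$data))
  expect_lt(max(abs(back$data - ep$data)), 1e-4)  # float32 payload
  expect_identical(back$channel_labels, ep$channel_labels)
  expect_identical(back$rejected, ep$rejected)
})
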