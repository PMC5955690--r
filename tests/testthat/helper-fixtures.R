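# Shared fixtures: built once per test run.

test_montage <- function() {
  m <- getOption("oscmotor.test.montage")
  if (is.null(m)) {
    m <- standard_montage()
    options(oscmotor.test.montage = m)
  }
  m
}

# a small session: 1 block, n trials, no hand switch; random allocation so
# any n is permitted
small_trials <- function(n = 24, seed = 42) {
  sp <- design_spec(n_blocks = 1, trials_per_block = n,
                    hand_switch_block = 2, seed = seed)
  generate_design(sp, exact_allocation = (n %% 12 == 0))
}

# epoch set built directly from a deterministic signal function of time (s)
signal_epochs <- function(f, n_trials = 2, channels = "C3", srate = 250,
                          window = c(-1, 2)) {
  times <- seq(window[1], window[2] - 1 / srate, by = 1 / srate)
  x <- f(times)
  data <- array(0, c(n_trials, length(channels), length(times)))
  for (i in seq_len(n_trials)) for (j in seq_along(channels))
    data[i, j, ] <- x
  structure(
    list(data = data, srate = srate, window = window, times = times,
         locking = "cue", channel_labels = channels,
         rejected = rep(FALSE, n_trials),
         reject_reason = rep(NA_character_, n_trials),
         meta = NULL, flipped = rep(FALSE, n_trials)),
    class = "epoch_set"
  )
}

# raw_eeg wrapper around an arbitrary channels x time matrix
raw_from_matrix <- function(x, labels, srate = 250, montage = NULL,
                            events = NULL) {
  rownames(x) <- labels
  structure(
    list(data = x, srate = srate,
         events = events %||% data.frame(onset_s = numeric(0),
                                         label = character(0)),
         montage = montage, channel_labels = labels),
    class = "raw_eeg"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unwrap_phase <- function(p) {
  out <- p
  for (i in 2:length(p)) {
    d <- p[i] - p[i - 1]
    out[i] <- out[i - 1] + oscmotor:::wrap_pi(d)
  }
  out
}
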