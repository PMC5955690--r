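# Morlet-wavelet time-frequency power.
#
# Mother wavelet (complex Morlet, bandwidth f_b, center frequency f_c):
#   w(t) = (pi f_b)^(-1/2) exp(2 pi i f_c t) exp(-t^2 / f_b)
# The daughter at analysis frequency f is the mother compressed by the scale
# a = f_c / f with 1/sqrt(a) normalization (the standard continuous-wavelet
# convention). Energy is the squared magnitude of the convolution, expressed
# as percent change from a pre-stimulus baseline.

#' Wavelet analysis parameters
#'
#' @param f_b bandwidth parameter (default 1).
#' @param f_c wavelet center frequency (default 1.5).
#' @param freqs analysis frequencies in Hz (default 1-40, 1 Hz linear grid).
#' @param baseline_window pre-stimulus baseline in seconds (default
#'   \[-0.25, -0.05\]).
#' @return a `wavelet_params` object.
#' @export
wavelet_params <- function(f_b = 1, f_c = 1.5, freqs = 1:40,
                           baseline_window = c(-0.25, -0.05)) {
  stopifnot(f_b > 0, f_c > 0, all(diff(freqs) > 0), all(freqs > 0))
  structure(list(f_b = f_b, f_c = f_c, freqs = freqs,
                 baseline_window = baseline_window),
            class = "wavelet_params")
}

#' Complex Morlet mother wavelet
#'
#' @param t time (s), vector.
#' @param params a [wavelet_params()] (only `f_b`, `f_c` used).
#' @return complex values `(pi f_b)^(-1/2) exp(2 pi i f_c t) exp(-t^2/f_b)`.
#' @export
#' @examples
#' morlet_mother(0, wavelet_params())   # (pi)^(-1/2) ~ 0.5642
morlet_mother <- function(t, params = wavelet_params()) {
  (pi * params$f_b)^(-0.5) * exp(2i * pi * params$f_c * t) *
    exp(-t^2 / params$f_b)
}

# sampled daughter kernel at frequency f; truncated at +/- 4 amplitude SDs
#' @noRd
morlet_kernel <- function(f, params, srate, trunc_sd = 4) {
  a <- params$f_c / f
  sigma_amp <- a * sqrt(params$f_b / 2)
  L <- ceiling(trunc_sd * sigma_amp * srate)
  tt <- (-L:L) / srate
  k <- morlet_mother(tt / a, params) / sqrt(a) / srate
  list(kernel = k, half = L, sigma_amp = sigma_amp)
}

#' Morlet time-frequency energy of an epoch set
#'
#' Convolves every trial and channel with the scaled wavelet at each
#' analysis frequency (FFT convolution, 'same' alignment) and returns the
#' squared magnitude. Edge samples where less than `edge_coverage` of the
#' wavelet energy overlaps the epoch are reported per frequency in
#' `edge_margin` (number of contaminated samples at each end).
#'
#' @param epochs an `epoch_set`.
#' @param params a [wavelet_params()].
#' @param channels channel subset to analyze (default all).
#' @param keep_rejected include rejected trials (default FALSE).
#' @param edge_coverage minimum fraction of wavelet energy that must lie
#'   inside the epoch for a sample to be unflagged.
#' @return a `tfr` object: `energy` (trials x channels x freqs x time),
#'   `freqs`, `times`, `srate`, `channel_labels`, `edge_margin`, `meta`
#'   (per-trial metadata of retained trials), `normalized = FALSE`.
#' @export
cwt_power <- function(epochs, params = wavelet_params(),
                      channels = epochs$channel_labels,
                      keep_rejected = FALSE, edge_coverage = 0.95) {
  srate <- epochs$srate
  ch_idx <- match(channels, epochs$channel_labels)
  stopifnot(!anyNA(ch_idx))
  keep <- if (keep_rejected) seq_along(epochs$rejected) else which(!epochs$rejected)
  n_tr <- length(keep)
  n_ch <- length(ch_idx)
  n_t <- dim(epochs$data)[3]
  freqs <- params$freqs

  # precondition: the central 95% energy span of the lowest-frequency
  # wavelet must fit into the epoch
  spans <- 2 * 1.96 * (params$f_c / freqs) * sqrt(params$f_b) / 2
  bad <- spans > n_t / srate
  if (any(bad)) {
    stop(sprintf(
      "wavelet support exceeds epoch length below %g Hz; lowest usable frequency on this epoch is %g Hz",
      max(freqs[bad]), min(freqs[!bad])))
  }

  kernels <- lapply(freqs, morlet_kernel, params = params, srate = srate)
  max_half <- max(vapply(kernels, function(k) k$half, 0))
  nfft <- next_fast_len(n_t + 2 * max_half)

  # signal spectra: one matrix FFT over all trial-channel columns
  X <- matrix(0, nfft, n_tr * n_ch)
  flat <- matrix(aperm(epochs$data[keep, ch_idx, , drop = FALSE], c(3, 1, 2)),
                 nrow = n_t)
  X[seq_len(n_t), ] <- flat
  FX <- stats::mvfft(X)

  energy <- array(NA_real_, c(n_tr, n_ch, length(freqs), n_t))
  edge_margin <- integer(length(freqs))
  for (fi in seq_along(freqs)) {
    k <- kernels[[fi]]
    kpad <- complex(length.out = nfft)
    kpad[seq_along(k$kernel)] <- k$kernel
    FK <- stats::fft(kpad)
    conv <- stats::mvfft(FX * FK, inverse = TRUE) / nfft
    # 'same' alignment: kernel center sits at offset half+1
    seg <- conv[k$half + seq_len(n_t), , drop = FALSE]
    e <- Mod(seg)^2
    energy[, , fi, ] <- aperm(array(e, c(n_t, n_tr, n_ch)), c(2, 3, 1))
    # edge flagging from cumulative kernel energy
    ke <- Mod(k$kernel)^2
    cum <- cumsum(ke) / sum(ke)
    # coverage at distance d from the edge: energy within the first half+1+d taps
    cover <- cum[pmin(length(ke), k$half + 1 + (0:(n_t - 1)))]
    edge_margin[fi] <- sum(cover < edge_coverage)
  }

  structure(
    list(energy = energy, freqs = freqs, times = epochs$times, srate = srate,
         channel_labels = channels, edge_margin = edge_margin,
         meta = if (!is.null(epochs$meta)) epochs$meta[keep, , drop = FALSE] else NULL,
         locking = epochs$locking, normalized = FALSE,
         params = params),
    class = "tfr"
  )
}

#' Average TFR energy within condition groups
#'
#' @param tfr an unnormalized `tfr` with per-trial energy.
#' @param conditions character vector, one entry per retained trial.
#' @return a `tfr` whose first dimension indexes the sorted unique
#'   conditions (`tfr$conditions`).
#' @export
tfr_condition_mean <- function(tfr, conditions) {
  stopifnot(length(conditions) == dim(tfr$energy)[1])
  conds <- sort(unique(conditions))
  d <- dim(tfr$energy)
  out <- array(NA_real_, c(length(conds), d[2], d[3], d[4]))
  for (ci in seq_along(conds)) {
    sel <- which(conditions == conds[ci])
    m <- tfr$energy[sel, , , , drop = FALSE]
    out[ci, , , ] <- colMeans(m, dims = 1)
  }
  res <- tfr
  res$energy <- out
  res$conditions <- conds
  res$meta <- NULL
  res
}

#' Baseline normalization to percent signal change
#'
#' Per channel and frequency, the baseline `B` is the mean energy inside the
#' baseline window (computed on whatever the first dimension holds:
#' condition-averaged energy for the grand-average convention, single trials
#' for per-trial normalization); the output is `100 (P - B) / B`.
#'
#' @param tfr a `tfr` (energy). Pass condition means ([tfr_condition_mean()])
#'   for the grand-average convention, or per-trial energy for single-trial
#'   normalization; each entry of the leading dimension is normalized by its
#'   own baseline.
#' @param baseline_window length-2 window in seconds; defaults to the
#'   params' baseline.
#' @param baseline_from optional `tfr` to take the baseline from instead
#'   (typically the energy pooled over all trials): its per-channel,
#'   per-frequency baseline is averaged over its leading dimension and
#'   applied to every entry of `tfr`. Because a pre-stimulus baseline
#'   cannot differ between conditions in expectation, pooling removes the
#'   small-sample ratio bias that per-condition baselines acquire when
#'   condition trial counts are very unequal.
#' @return a `tfr` with `normalized = TRUE`, values in percent change.
#' @export
baseline_normalize <- function(tfr, baseline_window = tfr$params$baseline_window,
                               baseline_from = NULL) {
  stopifnot(!isTRUE(tfr$normalized))
  src <- baseline_from %||% tfr
  bl <- which(src$times >= baseline_window[1] & src$times < baseline_window[2])
  if (!length(bl)) stop("baseline window outside the epoch")
  B <- apply(src$energy[, , , bl, drop = FALSE], c(2, 3), mean)
  if (any(B <= 0))
    stop("non-positive baseline energy; degenerate (zero) input signal")
  d <- dim(tfr$energy)
  if (is.null(baseline_from)) {
    # per-entry baseline (per condition / per trial)
    Bm <- apply(tfr$energy[, , , bl, drop = FALSE], c(1, 2, 3), mean)
  } else {
    Bm <- aperm(array(B, c(d[2], d[3], d[1])), c(3, 1, 2))
  }
  out <- 100 * (tfr$energy - as.vector(Bm)) / as.vector(Bm)
  res <- tfr
  res$energy <- out
  res$normalized <- TRUE
  res
}

#' Region-of-interest electrode clusters and analysis bands
#'
#' The four clusters (left/right prefrontal, left/right central) and the two
#' bands (mu/alpha 9-14 Hz, beta 15-25 Hz) used throughout the analysis.
#' @return list with `rois` (named electrode vectors) and `bands` (named
#'   length-2 vectors).
#' @export
roi_set <- function() {
  list(
    rois = list(
      prefrontal_left = c("F3", "F5", "FC3", "FC5"),
      prefrontal_right = c("F4", "F6", "FC4", "FC6"),
      central_left = c("C3", "C5", "CP3", "CP5"),
      central_right = c("C4", "C6", "CP4", "CP6")
    ),
    bands = list(mu = c(9, 14), beta = c(15, 25))
  )
}

#' ROI x band time course
#'
#' Mean normalized power over a cluster's electrodes and a band's frequency
#' bins, per entry of the leading (trial or condition) dimension.
#'
#' @param tfr a `tfr`.
#' @param roi electrode labels of the cluster.
#' @param band length-2 frequency interval (Hz), inclusive.
#' @return matrix `leading dimension x time`.
#' @export
roi_band_timecourse <- function(tfr, roi, band) {
  ch <- match(roi, tfr$channel_labels)
  if (anyNA(ch)) stop("ROI electrodes missing from the TFR")
  fb <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(fb)) stop("band does not intersect the analysis frequencies")
  x <- tfr$energy[, ch, fb, , drop = FALSE]
  apply(x, c(1, 4), mean)
}

#' Swap left/right homologous channels for selected trials
#'
#' Midline electrodes are unchanged; flipping twice is the identity. Used to
#' map left-standard-hand blocks onto the right-standard-hand layout so
#' ipsi/contralateral sides are comparable across blocks.
#'
#' @param x an `epoch_set` or `tfr`.
#' @param montage a `montage` (provides `lr_pairs`).
#' @param which_trials logical or integer selection along the leading
#'   dimension.
#' @return the same type, with `flipped` status toggled for those trials.
#' @export
flip_hemispheres <- function(x, montage, which_trials) {
  labs <- x$channel_labels
  hom <- montage$lr_pairs[labs]
  if (anyNA(hom) || !all(hom %in% labs))
    stop("channel without a left/right homologue in the analysis set")
  perm <- match(hom, labs)
  if (is.logical(which_trials)) which_trials <- which(which_trials)
  if (inherits(x, "epoch_set")) {
    x$data[which_trials, , ] <- x$data[which_trials, perm, , drop = FALSE]
  } else if (inherits(x, "tfr")) {
    x$energy[which_trials, , , ] <- x$energy[which_trials, perm, , , drop = FALSE]
  } else stop("unsupported type")
  if (!is.null(x$flipped)) x$flipped[which_trials] <- !x$flipped[which_trials]
  x
}

#' Write / read a TFR (JSON header + float32 binary)
#' @param tfr a `tfr`; @param path basename.
#' @export
write_tfr <- function(tfr, path) {
  d <- dim(tfr$energy)
  hdr <- list(dims = d, freqs = tfr$freqs, times = tfr$times,
              srate = tfr$srate, channel_labels = tfr$channel_labels,
              edge_margin = tfr$edge_margin, normalized = tfr$normalized,
              conditions = tfr$conditions, locking = tfr$locking)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(tfr$energy), con, size = 4, endian = "little")
  close(con)
  invisible(path)
}

#' @rdname write_tfr
#' @export
read_tfr <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  x <- readBin(con, "numeric", prod(hdr$dims), size = 4, endian = "little")
  close(con)
  structure(
    list(energy = array(x, hdr$dims), freqs = hdr$freqs, times = hdr$times,
         srate = hdr$srate, channel_labels = hdr$channel_labels,
         edge_margin = hdr$edge_margin, normalized = hdr$normalized,
         conditions = hdr$conditions, locking = hdr$locking,
         params = NULL, meta = NULL),
    class = "tfr"
  )
}
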