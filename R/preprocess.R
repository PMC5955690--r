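# Preprocessing: re-referencing to linked earlobes, zero-phase filtering,
# epoching with pre-stimulus baseline correction, amplitude-threshold
# artifact rejection, and the subject-exclusion rule.
#
# Pipeline order is fixed: re-reference -> filter -> epoch (baseline) ->
# reject. Filtering precedes epoching so filter edge effects stay outside
# the epochs.

#' Re-reference a raw record
#'
#' Subtracts the mean of the reference channels from every channel and drops
#' the reference channels from the analysis set (the offline equivalent of
#' linked-earlobe referencing).
#'
#' @param raw a `raw_eeg`.
#' @param ref_channels labels of the reference channels.
#' @return a `raw_eeg` without the reference channels.
#' @export
rereference <- function(raw, ref_channels = raw$montage$ref_labels) {
  miss <- setdiff(ref_channels, raw$channel_labels)
  if (length(miss))
    stop(sprintf("missing reference channel(s): %s", paste(miss, collapse = ", ")))
  ref <- colMeans(raw$data[ref_channels, , drop = FALSE])
  keep <- setdiff(raw$channel_labels, ref_channels)
  out <- raw
  out$data <- sweep(raw$data[keep, , drop = FALSE], 2, ref, "-")
  out$channel_labels <- keep
  out
}

# cascade of high-pass Butterworth and 50 Hz notch as a single IIR
#' @noRd
design_filters <- function(srate, highpass_hz, notch_hz, notch_q = 30) {
  nyq <- srate / 2
  filters <- list()
  if (!is.null(highpass_hz) && highpass_hz > 0) {
    if (highpass_hz >= nyq) stop("high-pass cutoff at or above Nyquist")
    filters$hp <- signal::butter(4, highpass_hz / nyq, type = "high")
  }
  if (!is.null(notch_hz) && notch_hz > 0) {
    if (notch_hz >= nyq) stop("notch frequency at or above Nyquist")
    w0 <- 2 * pi * notch_hz / srate
    alpha <- sin(w0) / (2 * notch_q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
    filters$notch <- list(b = b, a = a)
  }
  filters
}

#' Zero-phase filtering of a raw record
#'
#' 4th-order Butterworth high-pass plus a biquad 50 Hz notch (Q = 30), each
#' applied forward-backward (`filtfilt`), so the net filter is zero-phase
#' and the stopband attenuation doubles.
#'
#' @param raw a `raw_eeg`.
#' @param highpass_hz high-pass cutoff (Hz); `NULL` to skip.
#' @param notch_hz notch frequency (Hz); `NULL` to skip.
#' @return the filtered `raw_eeg`.
#' @export
filter_raw <- function(raw, highpass_hz = 0.5, notch_hz = 50) {
  filters <- design_filters(raw$srate, highpass_hz, notch_hz)
  out <- raw
  x <- t(out$data)
  if (!is.null(filters$hp))
    x <- filtfilt_mat(filters$hp$b, filters$hp$a, x)
  if (!is.null(filters$notch))
    x <- filtfilt_mat(filters$notch$b, filters$notch$a, x)
  out$data <- t(x)
  dimnames(out$data) <- dimnames(raw$data)
  out
}

#' Extract epochs around events
#'
#' Cuts half-open windows `[onset + window[1], onset + window[2])` around
#' each selected event (at 250 Hz and the default 3 s window: 750 samples,
#' event onset at sample index `srate * |window[1]| + 1`). The mean of the
#' pre-stimulus baseline window is subtracted per channel and trial. Events
#' whose window extends beyond the record are kept in the set but marked
#' rejected with a reason.
#'
#' @param raw a `raw_eeg` (after re-referencing/filtering).
#' @param onsets_s event onsets in seconds.
#' @param window length-2 window in seconds relative to the event.
#' @param baseline length-2 baseline window in seconds (default the 100 ms
#'   preceding the event); `NULL` to skip baseline correction.
#' @param locking `"cue"` or `"target"`, recorded as metadata.
#' @param meta optional data.frame of per-trial metadata (same order).
#' @return an `epoch_set`: `data` (trials x channels x time), `srate`,
#'   `window`, `times` (s, relative to the event), `locking`,
#'   `channel_labels`, `rejected` (logical), `reject_reason`, `meta`.
#' @export
epoch <- function(raw, onsets_s, window = c(-1, 2), baseline = c(-0.1, 0),
                  locking = c("cue", "target"), meta = NULL) {
  locking <- match.arg(locking)
  srate <- raw$srate
  n <- ncol(raw$data)
  n_ch <- nrow(raw$data)
  rel <- seq(round(window[1] * srate), round(window[2] * srate) - 1)
  n_t <- length(rel)
  n_tr <- length(onsets_s)

  data <- array(NA_real_, c(n_tr, n_ch, n_t))
  rejected <- logical(n_tr)
  reason <- rep(NA_character_, n_tr)
  onset_idx <- round(onsets_s * srate) + 1L
  if (!is.null(baseline)) {
    b0 <- round(baseline[1] * srate); b1 <- round(baseline[2] * srate) - 1
    bl_cols <- which(rel >= b0 & rel <= b1)
  }
  for (i in seq_len(n_tr)) {
    idx <- onset_idx[i] + rel
    if (idx[1] < 1 || idx[n_t] > n) {
      rejected[i] <- TRUE
      reason[i] <- "window outside record"
      next
    }
    seg <- raw$data[, idx, drop = FALSE]
    if (!is.null(baseline)) {
      seg <- seg - rowMeans(seg[, bl_cols, drop = FALSE])
    }
    data[i, , ] <- seg
  }
  structure(
    list(data = data, srate = srate, window = window, times = rel / srate,
         locking = locking, channel_labels = raw$channel_labels,
         rejected = rejected, reject_reason = reason,
         meta = meta, flipped = rep(FALSE, n_tr)),
    class = "epoch_set"
  )
}

#' Amplitude-threshold artifact rejection
#'
#' Marks a trial rejected iff any channel sample (post-baseline voltages)
#' exceeds the threshold in absolute value. Data are retained; only the mask
#' is updated. Idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection bound (microvolts).
#' @param channels channels to scan (default: all).
#' @return the `epoch_set` with an updated rejection mask.
#' @export
reject_amplitude <- function(epochs, threshold_uv = 80,
                             channels = epochs$channel_labels) {
  ch_idx <- match(channels, epochs$channel_labels)
  stopifnot(!anyNA(ch_idx))
  out <- epochs
  for (i in seq_len(dim(epochs$data)[1])) {
    if (out$rejected[i]) next
    m <- max(abs(epochs$data[i, ch_idx, ]))
    if (is.finite(m) && m > threshold_uv) {
      out$rejected[i] <- TRUE
      out$reject_reason[i] <- sprintf("amplitude > %g uV", threshold_uv)
    }
  }
  out
}

#' Subject exclusion by rejection fraction
#'
#' A subject is excluded iff strictly more than `threshold` of their trials
#' were rejected.
#'
#' @param rejection_fractions named numeric vector in [0, 1] per subject.
#' @param threshold exclusion bound (default 0.30).
#' @return list with `kept` and `excluded` subject names.
#' @export
exclude_subjects <- function(rejection_fractions, threshold = 0.30) {
  stopifnot(all(rejection_fractions >= 0), all(rejection_fractions <= 1))
  ex <- rejection_fractions > threshold
  nm <- names(rejection_fractions) %||% as.character(seq_along(rejection_fractions))
  list(kept = nm[!ex], excluded = nm[ex])
}

#' Subset an epoch set by trial
#' @param epochs an `epoch_set`; @param keep logical or integer index.
#' @return the subset `epoch_set`.
#' @export
subset_epochs <- function(epochs, keep) {
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$rejected <- epochs$rejected[keep]
  out$reject_reason <- epochs$reject_reason[keep]
  out$flipped <- epochs$flipped[keep]
  if (!is.null(epochs$meta)) out$meta <- epochs$meta[keep, , drop = FALSE]
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples, %s-locked, %d rejected\n",
              d[1], d[2], d[3], x$locking, sum(x$rejected)))
  invisible(x)
}

#' Write / read an epoch set (JSON header + float32 binary)
#'
#' The container is a JSON header (`<path>.json`) describing dimensions and
#' metadata plus a flat little-endian float32 payload (`<path>.bin`),
#' channel-major within trial, and a rejection-log TSV (`<path>.rejlog.tsv`).
#'
#' @param epochs an `epoch_set`; @param path basename (no extension).
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  hdr <- list(dims = d, srate = epochs$srate, window = epochs$window,
              locking = epochs$locking, channel_labels = epochs$channel_labels,
              rejected = epochs$rejected, flipped = epochs$flipped)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con, size = 4,
           endian = "little")
  close(con)
  log <- data.frame(trial = seq_len(d[1]), rejected = epochs$rejected,
                    reason = ifelse(is.na(epochs$reject_reason), "",
                                    epochs$reject_reason))
  utils::write.table(log, paste0(path, ".rejlog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(epochs$meta))
    utils::write.table(epochs$meta, paste0(path, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- hdr$dims
  con <- file(paste0(path, ".bin"), "rb")
  x <- readBin(con, "numeric", prod(d), size = 4, endian = "little")
  close(con)
  data <- aperm(array(x, c(d[3], d[2], d[1])), c(3, 2, 1))
  meta_path <- paste0(path, ".meta.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.table(meta_path, header = TRUE, sep = "\t") else NULL
  log <- utils::read.table(paste0(path, ".rejlog.tsv"), header = TRUE, sep = "\t",
                           na.strings = "")
  structure(
    list(data = data, srate = hdr$srate, window = hdr$window,
         times = seq(round(hdr$window[1] * hdr$srate),
                     round(hdr$window[2] * hdr$srate) - 1) / hdr$srate,
         locking = hdr$locking, channel_labels = hdr$channel_labels,
         rejected = hdr$rejected,
         reject_reason = ifelse(log$reason == "" | is.na(log$reason),
                                NA_character_, log$reason),
         meta = meta, flipped = hdr$flipped),
    class = "epoch_set"
  )
}
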