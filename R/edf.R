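# Minimal EDF+ (European Data Format) writer and reader for raw sessions:
# 16-bit samples, one data record per second, and an EDF Annotations signal
# carrying the cue/target events as time-stamped annotation lists (TALs).
# Covers the continuous (EDF+C) subset this package writes.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a raw EEG session as EDF+
#'
#' @param raw a `raw_eeg` object.
#' @param path output file path.
#' @param physical_range symmetric physical range (microvolts) mapped onto
#'   the 16-bit digital range; samples are clipped to it.
#' @return `path`, invisibly.
#' @export
write_edf <- function(raw, path, physical_range = 3200) {
  srate <- raw$srate
  n_sig <- nrow(raw$data)
  rec_dur <- 1                       # seconds per data record
  spr <- as.integer(srate * rec_dur) # samples per record per signal
  n_rec <- ceiling(ncol(raw$data) / spr)
  ann_spr <- 32L                     # 64 bytes of annotation per record

  # digital conversion
  dmin <- -32768; dmax <- 32767
  pmin <- -physical_range; pmax <- physical_range
  scale <- (dmax - dmin) / (pmax - pmin)

  con <- file(path, "wb")
  on.exit(close(con))
  ns_total <- n_sig + 1L

  hdr <- c(
    edf_pad("0", 8),
    edf_pad("synthetic subject", 80),
    edf_pad("synthetic recording", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns_total + 1), 8),
    edf_pad("EDF+C", 44),
    edf_pad(n_rec, 8),
    edf_pad(format(rec_dur), 8),
    edf_pad(ns_total, 4)
  )
  writeChar(paste(hdr, collapse = ""), con, eos = NULL)

  labels <- c(raw$channel_labels, "EDF Annotations")
  field <- function(values, width) {
    writeChar(paste(vapply(values, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(labels, 16)
  field(rep("", ns_total), 80)                       # transducer
  field(c(rep("uV", n_sig), ""), 8)                  # dimension
  field(c(rep(format(pmin), n_sig), "-1"), 8)
  field(c(rep(format(pmax), n_sig), "1"), 8)
  field(c(rep(format(dmin), n_sig), format(dmin)), 8)
  field(c(rep(format(dmax), n_sig), format(dmax)), 8)
  field(rep("", ns_total), 80)                       # prefiltering
  field(c(rep(spr, n_sig), ann_spr), 8)
  field(rep("", ns_total), 32)                       # reserved

  # pad data to whole records
  n_pad <- n_rec * spr
  X <- matrix(0, n_sig, n_pad)
  X[, seq_len(ncol(raw$data))] <- raw$data
  D <- round(pmin(pmax((X - pmin) * scale + dmin, dmin), dmax))

  ev <- raw$events
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(D[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
    # annotations: record-onset TAL, then one NUL-terminated TAL per event
    # starting in this record
    t0 <- (r - 1) * rec_dur
    tal <- c(charToRaw(sprintf("+%g\x14\x14", t0)), as.raw(0))
    sel <- which(ev$onset_s >= t0 & ev$onset_s < t0 + rec_dur)
    for (i in sel) {
      tal <- c(tal,
               charToRaw(sprintf("+%.6f\x14%s\x14", ev$onset_s[i], ev$label[i])),
               as.raw(0))
    }
    if (length(tal) > 2 * ann_spr)
      stop(sprintf("too many annotations in record %d for the annotation signal", r))
    writeBin(c(tal, rep(as.raw(0), 2 * ann_spr - length(tal))), con)
  }
  invisible(path)
}

#' Read an EDF+ file written by [write_edf()]
#'
#' @param path file path.
#' @param montage optional `montage` to attach.
#' @return a `raw_eeg` object (data in microvolts, events recovered from the
#'   annotations signal).
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16, useBytes = TRUE), ""))
  rd(80 * ns); rd(8 * ns)
  pmins <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmaxs <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmins <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmaxs <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  sprs <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)

  ann_idx <- which(labels == "EDF Annotations")
  sig_idx <- setdiff(seq_len(ns), ann_idx)
  spr <- sprs[sig_idx[1]]
  srate <- spr / rec_dur

  data <- matrix(0, length(sig_idx), n_rec * spr)
  ann_bytes <- raw(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (s %in% ann_idx) {
        ann_bytes <- c(ann_bytes, readBin(con, "raw", 2 * sprs[s]))
      } else {
        v <- readBin(con, "integer", sprs[s], size = 2, endian = "little")
        k <- match(s, sig_idx)
        g <- (pmaxs[s] - pmins[s]) / (dmaxs[s] - dmins[s])
        data[k, ((r - 1) * spr + 1):(r * spr)] <- pmins[s] + (v - dmins[s]) * g
      }
    }
  }
  rownames(data) <- labels[sig_idx]

  # TALs are NUL-terminated "+onset[\x15dur]\x14label\x14" blocks; bare
  # record-onset stamps carry an empty label and are skipped
  onsets <- numeric(0); labs_ev <- character(0)
  zero <- which(ann_bytes == as.raw(0))
  starts <- c(1L, zero[-length(zero)] + 1L)
  for (k in seq_along(zero)) {
    if (starts[k] > zero[k] - 1L) next
    tal <- rawToChar(ann_bytes[starts[k]:(zero[k] - 1L)])
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(parts[2])) next
    on_s <- suppressWarnings(as.numeric(sub("\x15.*$", "", sub("^\\+", "", parts[1]))))
    if (!is.na(on_s)) {
      onsets <- c(onsets, on_s)
      labs_ev <- c(labs_ev, parts[2])
    }
  }
  events <- data.frame(onset_s = onsets, label = labs_ev)
  events <- events[order(events$onset_s), ]
  rownames(events) <- NULL

  structure(
    list(data = data, srate = srate, events = events, montage = montage,
         channel_labels = rownames(data)),
    class = "raw_eeg"
  )
}
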