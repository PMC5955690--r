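# Alpha-band phase-locking value (PLV) connectivity.
#
#   PLV_{e1,e2}(t) = (1/N) | sum_trials exp(i [phi_e1(t) - phi_e2(t)]) |
#
# with phi the instantaneous phase from the analytic signal of the
# band-passed data. PLV is 1 for perfectly locked phase differences, and
# for independent phases decays toward 0 as trials accumulate (with the
# finite-N positive bias of the mean resultant length).

#' Instantaneous phase of band-passed epochs
#'
#' Zero-phase Butterworth band-pass followed by the analytic-signal
#' (Hilbert) phase, per trial and channel. The first and last
#' `ceil(order/2)` samples are reported as edge-distorted.
#'
#' @param epochs an `epoch_set`.
#' @param band length-2 frequency interval (Hz), default the 9-14 Hz alpha
#'   band.
#' @param order Butterworth order.
#' @param channels channel subset.
#' @return list with `phase` (trials x channels x time, in (-pi, pi]),
#'   `edge_margin` (samples), `band`, `channel_labels`, `times`.
#' @export
instantaneous_phase <- function(epochs, band = c(9, 14), order = 4,
                                channels = epochs$channel_labels) {
  nyq <- epochs$srate / 2
  stopifnot(band[1] > 0, band[1] < band[2], band[2] < nyq)
  w <- band / nyq
  if (diff(w) < 1e-3)
    stop("band too narrow for a stable filter design at this sampling rate")
  bf <- signal::butter(order, w, type = "pass")
  ch_idx <- match(channels, epochs$channel_labels)
  stopifnot(!anyNA(ch_idx))
  d <- dim(epochs$data)
  n_tr <- d[1]; n_t <- d[3]; n_ch <- length(ch_idx)

  # filter all trial-channel traces and take phases in one batch
  flat <- matrix(aperm(epochs$data[, ch_idx, , drop = FALSE], c(3, 1, 2)),
                 nrow = n_t)
  flat <- filtfilt_mat(bf$b, bf$a, flat)
  ph <- Arg(analytic_signal(flat))
  phase <- aperm(array(ph, c(n_t, n_tr, n_ch)), c(2, 3, 1))

  list(phase = phase, edge_margin = ceiling(order / 2), band = band,
       channel_labels = channels, times = epochs$times)
}

#' Phase-locking value between two phase series
#'
#' @param phase_a,phase_b trials x time matrices of instantaneous phase.
#' @return PLV time series (vector over time), in \[0, 1\].
#' @export
plv <- function(phase_a, phase_b) {
  if (!all(dim(phase_a) == dim(phase_b)))
    stop("phase arrays must have identical trial x time shape")
  if (nrow(phase_a) < 2) stop("PLV needs at least 2 trials")
  Mod(colMeans(exp(1i * (phase_a - phase_b))))
}

#' Seed-to-all-electrodes PLV map
#'
#' PLV from a seed electrode to every electrode, computed per time sample
#' and averaged over the analysis window (the window directly preceding the
#' target by default).
#'
#' @param epochs an `epoch_set` (typically CSD-transformed, cue-locked).
#' @param seed seed electrode label (e.g. C3 or C4).
#' @param band frequency interval for the phase (Hz).
#' @param window length-2 analysis window (s relative to the locking event),
#'   default 0.9-1.1 s after the cue.
#' @param trials optional trial subset (indices into non-rejected trials are
#'   taken after subsetting); defaults to all non-rejected trials.
#' @return a `plv_map`: `seed`, `plv` (named vector over electrodes),
#'   `n_trials`, `band`, `window`.
#' @export
seed_plv_map <- function(epochs, seed, band = c(9, 14), window = c(0.9, 1.1),
                         trials = NULL) {
  keep <- which(!epochs$rejected)
  if (!is.null(trials)) keep <- intersect(keep, trials)
  if (length(keep) < 2) stop("PLV needs at least 2 trials")
  ep <- subset_epochs(epochs, keep)
  ip <- instantaneous_phase(ep, band = band)
  win <- which(ip$times >= window[1] & ip$times <= window[2])
  if (!length(win)) stop("analysis window outside the epoch")
  margin <- ip$edge_margin
  if (min(win) <= margin || max(win) > dim(ip$phase)[3] - margin)
    stop("analysis window overlaps the edge-distorted margin")
  si <- match(seed, ip$channel_labels)
  if (is.na(si)) stop(sprintf("seed electrode '%s' not in the analysis set", seed))
  ph <- ip$phase[, , win, drop = FALSE]
  seed_ph <- ph[, si, , drop = FALSE]
  n_ch <- dim(ph)[2]
  vals <- vapply(seq_len(n_ch), function(ci) {
    mean(plv(matrix(ph[, ci, ], nrow = length(keep)),
             matrix(seed_ph[, 1, ], nrow = length(keep))))
  }, numeric(1))
  names(vals) <- ip$channel_labels
  structure(
    list(seed = seed, plv = vals, n_trials = length(keep), band = band,
         window = window),
    class = "plv_map"
  )
}

#' Write a set of PLV maps as TSV (electrode, condition, PLV)
#' @param maps named list (by condition) of `plv_map`s; @param path file.
#' @export
write_plv_maps <- function(maps, path) {
  rows <- do.call(rbind, lapply(names(maps), function(cond) {
    m <- maps[[cond]]
    data.frame(seed = m$seed, electrode = names(m$plv), condition = cond,
               plv = unname(m$plv), n_trials = m$n_trials)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
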