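# Synthetic multichannel EEG with known injected oscillatory structure.
#
# Each source is a band-limited stochastic oscillation (filtered Gaussian
# noise, so band power rather than a line spectrum carries the effect)
# projected onto the scalp through a Gaussian topography on the sphere and
# modulated by a condition-dependent piecewise-linear amplitude envelope.
# Sources can be phase-coupled to a seed source through per-trial von Mises
# phase offsets, giving a controllable ground-truth phase-locking value.
# Background activity is spatially independent 1/f^alpha (pink) noise.

#' Oscillatory source specification
#'
#' @param center_electrode electrode label at the topography peak.
#' @param spatial_width angular SD (radians) of the Gaussian topography.
#' @param band length-2 frequency interval (Hz).
#' @param amplitude baseline RMS amplitude (microvolts) at the center
#'   electrode.
#' @param envelope named list (by derived trial condition: go, `no-change`,
#'   change, `no-nogo`, nogo) of lists with `times` (s, relative to cue
#'   onset) and `amps` (relative amplitude multipliers, 1 = baseline);
#'   piecewise-linear, constant extrapolation outside the range. `NULL`
#'   means a flat envelope of 1 for every condition.
#' @param lateralization `"fixed"` (center as given), `"contra"` or `"ipsi"`:
#'   the center electrode is mirrored to the other hemisphere on trials where
#'   the standard hand makes the given side the wrong one (contra = opposite
#'   the standard hand, ipsi = same side). The `center_electrode` is
#'   interpreted as the location for right-hand-standard trials.
#' @param phase_mode `"independent"` or `"coupled"`.
#' @param seed_source index (into the source list) of the seed this source is
#'   coupled to; required when `phase_mode = "coupled"`.
#' @param concentration von Mises concentration of the per-trial phase offset
#'   to the seed; may be a single number or a named vector per derived
#'   condition. `Inf` means zero jitter.
#' @return a `source_spec` object.
#' @export
source_spec <- function(center_electrode, spatial_width = 0.5,
                        band = c(9, 14), amplitude = 5,
                        envelope = NULL,
                        lateralization = c("fixed", "contra", "ipsi"),
                        phase_mode = c("independent", "coupled"),
                        seed_source = NULL, concentration = Inf) {
  lateralization <- match.arg(lateralization)
  phase_mode <- match.arg(phase_mode)
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2],
            spatial_width > 0, amplitude >= 0, all(concentration >= 0))
  if (phase_mode == "coupled" && is.null(seed_source))
    stop("coupled source needs a seed_source index")
  if (!is.null(envelope)) {
    for (e in envelope) {
      stopifnot(length(e$times) == length(e$amps), all(e$amps >= 0),
                !is.unsorted(e$times))
    }
  }
  structure(
    list(center_electrode = center_electrode, spatial_width = spatial_width,
         band = band, amplitude = amplitude, envelope = envelope,
         lateralization = lateralization, phase_mode = phase_mode,
         seed_source = seed_source, concentration = concentration),
    class = "source_spec"
  )
}

#' Gaussian scalp topography of a source
#'
#' Weight at each electrode is `exp(-d^2 / (2 w^2))` with `d` the angular
#' (great-circle) distance to the center electrode; the center has weight 1.
#'
#' @param montage a `montage`.
#' @param source a [source_spec()] (or a center label with `width` given).
#' @param center,width optional overrides for the center label and angular SD.
#' @return named numeric vector over scalp electrodes (and reference
#'   electrodes, which get the same Gaussian rule).
#' @export
topography <- function(montage, source = NULL, center = NULL, width = NULL) {
  center <- center %||% source$center_electrode
  width <- width %||% source$spatial_width
  all_labs <- rownames(montage$pos)
  if (!center %in% all_labs) stop(sprintf("unknown electrode '%s'", center))
  d <- angular_distance(montage, center, all_labs)[1, ]
  w <- exp(-d^2 / (2 * width^2))
  names(w) <- all_labs
  w
}

#' 1/f^alpha (pink) background noise
#'
#' Spectral synthesis: independent complex Gaussian Fourier coefficients with
#' magnitude proportional to f^(-alpha/2), inverse transformed and scaled to
#' a target RMS. DC is excluded.
#'
#' @param n samples; @param n_channels channels; @param srate Hz;
#' @param alpha spectral exponent (power ~ 1/f^alpha); @param scale RMS in
#'   microvolts.
#' @return `n_channels` x `n` matrix.
#' @export
pink_noise <- function(n, n_channels, srate, alpha = 1, scale = 1) {
  if (scale == 0) return(matrix(0, n_channels, n))
  nf <- next_fast_len(n)
  freqs <- seq_len(floor(nf / 2)) * srate / nf
  mag <- freqs^(-alpha / 2)
  half <- length(freqs)
  # hermitian spectra for all channels, one batched inverse FFT
  coefs <- matrix(complex(real = stats::rnorm(half * n_channels),
                          imaginary = stats::rnorm(half * n_channels)),
                  half, n_channels) * mag
  spec <- matrix(complex(length.out = nf * n_channels), nf, n_channels)
  spec[2:(half + 1), ] <- coefs
  spec[nf:(nf - half + 2), ] <- Conj(coefs[1:(half - 1), , drop = FALSE])
  if (nf %% 2 == 0)
    spec[half + 1, ] <- complex(real = stats::rnorm(n_channels) * mag[half])
  x <- Re(stats::mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE]
  t(x) / apply(x, 2, stats::sd) * scale
}

# Unit-RMS band-limited Gaussian noise (hard FFT band mask), returned as the
# analytic signal so envelope/phase manipulation is direct.
#' @noRd
narrowband_analytic <- function(n, band, srate) {
  nf <- next_fast_len(n)
  f <- (seq_len(nf) - 1) * srate / nf
  f[f > srate / 2] <- f[f > srate / 2] - srate
  keep <- f >= band[1] & f <= band[2]
  spec <- complex(length.out = nf)
  nk <- sum(keep)
  spec[keep] <- complex(real = stats::rnorm(nk), imaginary = stats::rnorm(nk))
  z <- stats::fft(spec, inverse = TRUE)[seq_len(n)]
  z / stats::sd(Re(z))
}

#' Expected phase-locking value of a von Mises coupling
#'
#' The mean resultant length of a von Mises distribution with concentration
#' `kappa`: `I1(kappa) / I0(kappa)` (ratio of modified Bessel functions).
#' This is the asymptotic PLV of a source coupled with per-trial von Mises
#' phase jitter, so tests can target a known ground truth.
#'
#' @param kappa concentration (>= 0); `Inf` gives 1.
#' @return expected PLV in [0, 1].
#' @export
#' @examples
#' inject_coupling_level(0)    # 0: uniform phase
#' inject_coupling_level(2)    # ~0.70
inject_coupling_level <- function(kappa) {
  stopifnot(all(kappa >= 0))
  out <- ifelse(is.infinite(kappa), 1,
                besselI(kappa, 1, expon.scaled = TRUE) /
                  besselI(kappa, 0, expon.scaled = TRUE))
  out[kappa == 0] <- 0
  out
}

#' Concentration achieving a target expected PLV
#' @param plv target expected PLV in [0, 1).
#' @return von Mises concentration.
#' @export
coupling_for_plv <- function(plv) {
  stopifnot(plv >= 0, plv < 1)
  if (plv == 0) return(0)
  stats::uniroot(function(k) inject_coupling_level(k) - plv,
                 c(1e-6, 1e3), tol = 1e-10)$root
}

# von Mises sampler (Best & Fisher 1979 rejection method), mean 0
#' @noRd
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (is.infinite(kappa)) return(numeric(n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(max(-1, min(1, f)))
    }
  }
  out
}

#' @noRd
mirror_center <- function(montage, center, hand) {
  # center is the location under a right standard hand; mirror for left
  if (hand == "right") center else unname(montage$lr_pairs[center])
}

# amplitude envelope over the full record for one source
#' @noRd
source_envelope_track <- function(trials, source, n, srate) {
  amp <- rep(1, n)
  if (is.null(source$envelope)) return(amp)
  dcond <- derived_condition(trials)
  tgrid <- (seq_len(n) - 1) / srate
  for (i in seq_len(nrow(trials))) {
    env <- source$envelope[[dcond[i]]]
    if (is.null(env)) next
    t0 <- trials$cue_onset_s[i]
    i0 <- max(1L, floor((t0 + env$times[1]) * srate) + 1L)
    i1 <- min(n, ceiling((t0 + env$times[length(env$times)]) * srate) + 1L)
    if (i1 < i0) next
    amp[i0:i1] <- stats::approx(t0 + env$times, env$amps,
                                xout = tgrid[i0:i1], rule = 2)$y
  }
  amp
}

#' Simulate a raw EEG session
#'
#' Sums envelope-modulated band-limited sources (each projected through its
#' Gaussian topography) with pink-noise background, at 250 Hz by default.
#' Coupled sources share the seed source's per-trial phase trajectory,
#' rotated by a von Mises offset drawn once per trial (per-condition
#' concentration supported). Earlobe reference channels carry only a small
#' fraction of the noise, emulating electrically quiet reference sites.
#' Events (one per cue and per target) are attached for epoching and for
#' EDF+ annotation.
#'
#' @param trials trial table (cue/target onsets, conditions, hands).
#' @param montage a `montage`.
#' @param sources list of [source_spec()] objects.
#' @param noise_scale pink-noise RMS per channel (microvolts).
#' @param noise_alpha spectral exponent of the background.
#' @param srate sampling rate (Hz).
#' @param seed integer seed; the session is byte-identical under the same
#'   seed.
#' @param artifact_prob per-trial probability of a high-amplitude (120
#'   microvolt) square-pulse artifact, exercising amplitude rejection.
#' @param tail_s seconds of record appended after the last target.
#' @return a `raw_eeg` object: `data` (channels x time, microvolts; scalp
#'   electrodes then references), `srate`, `events` (data.frame: onset_s,
#'   label), `montage`, `channel_labels`.
#' @export
simulate_session <- function(trials, montage, sources, noise_scale = 1,
                             noise_alpha = 1, srate = 250, seed = 1L,
                             artifact_prob = 0, tail_s = 2.5) {
  rng <- local_rng(seed)
  on.exit(rng())
  nyq <- srate / 2
  for (s in sources) {
    if (s$band[2] >= nyq)
      stop(sprintf("source band [%g, %g] exceeds Nyquist (%g Hz)",
                   s$band[1], s$band[2], nyq))
  }
  labs <- c(montage$labels, montage$ref_labels)
  n_ch <- length(labs)
  dur <- max(trials$target_onset_s) + tail_s
  n <- ceiling(dur * srate)
  if (min(trials$cue_onset_s) < 1)
    stop("first cue onset must leave at least 1 s of record before it")

  data <- pink_noise(n, n_ch, srate, alpha = noise_alpha, scale = noise_scale)
  rownames(data) <- labs
  if (length(montage$ref_labels)) {
    ref_idx <- match(montage$ref_labels, labs)
    data[ref_idx, ] <- data[ref_idx, ] * 0.05   # near-quiet reference sites
  }

  n_trials <- nrow(trials)
  dcond <- derived_condition(trials)
  # trial ownership of each sample (for per-trial phase offsets): a trial
  # owns samples from its cue - 1 s up to the next trial's cue - 1 s
  bounds <- floor((trials$cue_onset_s - 1) * srate) + 1
  bounds <- c(bounds, n + 1L)

  carriers <- vector("list", length(sources))
  for (si in seq_along(sources)) {
    src <- sources[[si]]
    if (src$phase_mode == "coupled") {
      seedz <- carriers[[src$seed_source]]
      if (is.null(seedz)) stop("seed_source must precede coupled sources")
      kapv <- src$concentration
      z <- complex(length.out = n)
      for (i in seq_len(n_trials)) {
        kap <- if (length(kapv) > 1) kapv[[dcond[i]]] else kapv
        off <- rvonmises(1, kap)
        idx <- bounds[i]:(bounds[i + 1] - 1)
        z[idx] <- seedz[idx] * exp(1i * off)
      }
    } else {
      z <- narrowband_analytic(n, src$band, srate)
    }
    carriers[[si]] <- z

    amp <- source_envelope_track(trials, src, n, srate) * src$amplitude
    sig <- Re(z) * amp
    if (src$lateralization == "fixed") {
      w <- topography(montage, src)
      data <- data + outer(w[labs], sig)
    } else {
      # mirror the center electrode on left-standard-hand trials
      for (hand in unique(trials$standard_hand)) {
        ctr <- src$center_electrode
        if (src$lateralization %in% c("contra", "ipsi"))
          ctr <- mirror_center(montage, ctr, hand)
        w <- topography(montage, src, center = ctr)
        mask <- rep(0, n)
        for (i in which(trials$standard_hand == hand))
          mask[bounds[i]:(bounds[i + 1] - 1)] <- 1
        data <- data + outer(w[labs], sig * mask)
      }
    }
  }

  if (artifact_prob > 0) {
    hit <- which(stats::runif(n_trials) < artifact_prob)
    for (i in hit) {
      ch <- sample.int(length(montage$labels), 1)
      at <- floor(trials$cue_onset_s[i] * srate) + sample.int(srate, 1)
      idx <- at:min(n, at + srate %/% 10)
      data[ch, idx] <- data[ch, idx] + 120
    }
  }

  events <- rbind(
    data.frame(onset_s = trials$cue_onset_s,
               label = paste0("cue/", trials$condition)),
    data.frame(onset_s = trials$target_onset_s,
               label = paste0("target/", dcond))
  )
  events <- events[order(events$onset_s), ]
  rownames(events) <- NULL

  structure(
    list(data = data, srate = srate, events = events, montage = montage,
         channel_labels = labs),
    class = "raw_eeg"
  )
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("<raw_eeg> %d channels x %d samples (%.1f s @ %g Hz), %d events\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$srate, x$srate,
              nrow(x$events)))
  invisible(x)
}
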