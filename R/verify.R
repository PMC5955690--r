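# Self-contained verification runs with known injected ground truth, used
# by the test suite and the acceptance script.

#' Recover an injected mu-band power change
#'
#' Simulates a 200-trial session whose single mu-band source drops to 70%
#' power (-30%) inside the cue-target interval, runs the preprocessing and
#' Morlet pipeline, and returns the mean percent change in the effect
#' window. Background noise is kept small so the injected band-power change
#' is the measured quantity.
#'
#' @param montage a `montage`.
#' @param seed integer seed.
#' @param n_trials trials to simulate.
#' @param drop injected power ratio (default 0.7, i.e. -30%).
#' @return recovered percent change (scalar).
#' @export
erd_recovery_run <- function(montage, seed = 1L, n_trials = 200, drop = 0.7) {
  per_block <- 100
  sp <- design_spec(n_blocks = ceiling(n_trials / per_block),
                    trials_per_block = per_block,
                    hand_switch_block = ceiling(n_trials / per_block) + 1,
                    seed = seed)
  tr <- generate_design(sp, exact_allocation = FALSE)
  env <- list(times = c(0.2, 0.4, 1.6, 1.8),
              amps = c(1, sqrt(drop), sqrt(drop), 1))
  envs <- list(go = env, `no-change` = env, change = env,
               `no-nogo` = env, nogo = env)
  src <- source_spec("C3", spatial_width = 0.4, band = c(9, 14),
                     amplitude = 8, envelope = envs)
  raw <- simulate_session(tr, montage, list(src), noise_scale = 0.3,
                          seed = seed + 1000L)
  raw <- filter_raw(rereference(raw))
  ep <- epoch(raw, tr$cue_onset_s, locking = "cue", meta = tr)
  tf <- cwt_power(ep, wavelet_params(freqs = 9:14), channels = "C3")
  tfn <- baseline_normalize(tfr_condition_mean(tf, rep("all", dim(tf$energy)[1])))
  tc <- roi_band_timecourse(tfn, "C3", c(9, 14))
  mean(tc[1, tfn$times >= 0.6 & tfn$times <= 1.4])
}

#' Recover an injected phase-coupling level
#'
#' Simulates 200 trials with a central alpha seed source and a frontal
#' source coupled at the von Mises concentration whose expected PLV is
#' `target_plv` (see [inject_coupling_level()]), then estimates the seed
#' PLV map in the pre-target window.
#'
#' @param montage a `montage`.
#' @param target_plv ground-truth expected PLV.
#' @param seed integer seed.
#' @param n_trials trials to simulate.
#' @return list with `coupled` (PLV at the coupled electrode) and
#'   `uncoupled` (PLV at a distant uncoupled electrode, PO8).
#' @export
plv_recovery_run <- function(montage, target_plv = 0.6, seed = 1L,
                             n_trials = 200) {
  per_block <- 100
  sp <- design_spec(n_blocks = ceiling(n_trials / per_block),
                    trials_per_block = per_block,
                    hand_switch_block = ceiling(n_trials / per_block) + 1,
                    seed = seed)
  tr <- generate_design(sp, exact_allocation = FALSE)
  kap <- coupling_for_plv(target_plv)
  seed_src <- source_spec("C3", spatial_width = 0.25, band = c(9, 14),
                          amplitude = 6)
  coupled <- source_spec("F5", spatial_width = 0.25, band = c(9, 14),
                         amplitude = 6, phase_mode = "coupled",
                         seed_source = 1, concentration = kap)
  raw <- simulate_session(tr, montage, list(seed_src, coupled),
                          noise_scale = 0.3, seed = seed + 2000L)
  raw <- filter_raw(rereference(raw))
  ep <- epoch(raw, tr$cue_onset_s, locking = "cue", meta = tr)
  pm <- seed_plv_map(ep, "C3", band = c(9, 14), window = c(0.9, 1.1))
  list(coupled = unname(pm$plv["F5"]), uncoupled = unname(pm$plv["PO8"]),
       n_trials = pm$n_trials)
}
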