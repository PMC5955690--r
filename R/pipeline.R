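# End-to-end replica pipeline: simulate a virtual cohort, preprocess, CSD,
# time-frequency, PLV, and group statistics, with a known injected effect
# structure so every group-level result can be checked against ground truth.

#' Default ground-truth oscillatory sources
#'
#' Realizes the qualitative effect pattern of the task as simulator ground
#' truth: contralateral mu/beta desynchronization during the cue-target
#' interval in all conditions (strongest when expecting go); ipsilateral mu
#' increasing when expecting go, flat when expecting nogo and decreasing
#' when expecting change; ipsilateral beta decreasing only when expecting
#' change; a target-locked prefrontal beta burst scaling go < no-change /
#' no-nogo < change / nogo; and alpha-band coupling between the ipsilateral
#' motor cortex and ipsilateral frontal sites that drops when a change is
#' expected. Magnitudes are configurable ground truth, not empirical claims.
#'
#' @param effects `TRUE` for the default effect configuration, `FALSE` for
#'   the null configuration (identical envelopes and coupling across
#'   conditions; group contrasts should then show nothing).
#' @param mu_amp,beta_amp,alpha_amp source RMS amplitudes (microvolts).
#' @param kappa_high,kappa_low von Mises coupling concentrations for the
#'   coupled (high) and decoupled (low) states; see
#'   [inject_coupling_level()] for the PLV they imply.
#' @return list of [source_spec()] objects; the ipsilateral mu source (the
#'   PLV seed) is first.
#' @export
default_sources <- function(effects = TRUE, mu_amp = 6, beta_amp = 5,
                            alpha_amp = 3.5, kappa_high = 8, kappa_low = 1) {
  env_all <- function(go, ec, en) {
    # envelopes keyed by derived condition; EC cue covers no-change + change,
    # EN cue covers no-nogo + nogo
    list(go = go, `no-change` = ec, change = ec, `no-nogo` = en, nogo = en)
  }
  flat <- NULL
  ramp <- function(a_mid, a_end, t_on = 0.3, t_mid = 0.6) {
    list(times = c(0, t_on, t_mid, 1.1, 1.7, 2.0),
         amps = c(1, 1, a_mid, a_end, 1, 1))
  }
  burst <- function(peak) {
    list(times = c(1.1, 1.25, 1.35, 1.55, 1.75),
         amps = c(1, 1, peak, peak, 1))
  }

  if (effects) {
    mu_ipsi_env <- env_all(go = ramp(1.12, 1.15), ec = ramp(0.85, 0.76),
                           en = flat)
    mu_contra_env <- env_all(go = ramp(0.75, 0.65), ec = ramp(0.88, 0.8),
                             en = ramp(0.88, 0.8))
    beta_ipsi_env <- env_all(go = flat, ec = ramp(0.82, 0.75), en = flat)
    beta_contra_env <- env_all(go = ramp(0.78, 0.72), ec = ramp(0.9, 0.85),
                               en = ramp(0.9, 0.85))
    pf_env <- list(go = burst(1.15), `no-change` = burst(1.35),
                   `no-nogo` = burst(1.35), change = burst(1.65),
                   nogo = burst(1.65))
    kappa <- c(go = kappa_high, `no-change` = kappa_low, change = kappa_low,
               `no-nogo` = kappa_high, nogo = kappa_high)
  } else {
    mu_ipsi_env <- mu_contra_env <- beta_ipsi_env <- beta_contra_env <- NULL
    pf_env <- list(go = burst(1.3), `no-change` = burst(1.3),
                   `no-nogo` = burst(1.3), change = burst(1.3),
                   nogo = burst(1.3))
    kappa <- c(go = kappa_high, `no-change` = kappa_high, change = kappa_high,
               `no-nogo` = kappa_high, nogo = kappa_high)
  }

  list(
    # seed source first: ipsilateral sensorimotor mu (C4 under a right
    # standard hand, mirrored on left-hand blocks)
    source_spec("C4", spatial_width = 0.35, band = c(9, 14), amplitude = mu_amp,
                envelope = mu_ipsi_env, lateralization = "ipsi"),
    source_spec("C3", spatial_width = 0.35, band = c(9, 14), amplitude = mu_amp,
                envelope = mu_contra_env, lateralization = "contra"),
    source_spec("C4", spatial_width = 0.35, band = c(15, 25), amplitude = beta_amp,
                envelope = beta_ipsi_env, lateralization = "ipsi"),
    source_spec("C3", spatial_width = 0.35, band = c(15, 25), amplitude = beta_amp,
                envelope = beta_contra_env, lateralization = "contra"),
    source_spec("F3", spatial_width = 0.35, band = c(15, 25), amplitude = beta_amp,
                envelope = pf_env, lateralization = "fixed"),
    source_spec("F4", spatial_width = 0.35, band = c(15, 25), amplitude = beta_amp,
                envelope = pf_env, lateralization = "fixed"),
    # ipsilateral frontal alpha sources coupled to the motor seed
    source_spec("F4", spatial_width = 0.3, band = c(9, 14), amplitude = alpha_amp,
                lateralization = "ipsi", phase_mode = "coupled",
                seed_source = 1, concentration = kappa),
    source_spec("F6", spatial_width = 0.3, band = c(9, 14), amplitude = alpha_amp,
                lateralization = "ipsi", phase_mode = "coupled",
                seed_source = 1, concentration = kappa),
    source_spec("FC4", spatial_width = 0.3, band = c(9, 14), amplitude = alpha_amp,
                lateralization = "ipsi", phase_mode = "coupled",
                seed_source = 1, concentration = kappa)
  )
}

#' Replica study configuration
#'
#' Bundles every tunable of the pipeline. The default cohort is 22 virtual
#' subjects performing a scaled-down session (2 blocks of 12 trials, one
#' block per standard hand) that keeps the full design structure -
#' equiprobable cue conditions, 25% rare targets, the hand switch and
#' counterbalancing - at a size where a whole multi-seed cohort study runs
#' on a desktop; the full-length session (6 x 160 trials) is
#' [design_spec()]'s own default.
#'
#' @param n_subjects virtual subjects.
#' @param n_blocks,trials_per_block session size per subject.
#' @param effects effect (`TRUE`) or null (`FALSE`) configuration.
#' @param noise_scale pink-noise RMS (microvolts).
#' @param seed global seed; per-subject and per-stage substreams derive
#'   from it.
#' @param ... overrides stored verbatim into the config.
#' @return a `pipeline_config` list.
#' @export
replica_config <- function(n_subjects = 22, n_blocks = 2, trials_per_block = 12,
                           effects = TRUE, noise_scale = 1.5, seed = 1L, ...) {
  cfg <- list(
    n_subjects = n_subjects,
    design = list(n_blocks = n_blocks, trials_per_block = trials_per_block),
    behavior = behavior_params(),
    sources = default_sources(effects = effects),
    effects = effects,
    noise_scale = noise_scale, noise_alpha = 1, srate = 250,
    preprocess = list(highpass_hz = 0.5, notch_hz = 50, reject_uv = 80,
                      exclude_fraction = 0.30),
    csd = list(order_m = 4, n_terms = 50, lambda_reg = 1e-5),
    wavelet = list(f_b = 1, f_c = 1.5),
    analysis_freqs = seq(9, 25, by = 2),
    epoch_window = c(-1, 2),
    roi = roi_set(),
    cue_bins = seq(0.2, 1.1, by = 0.1),
    target_window = c(0.2, 0.5),
    plv = list(band = c(9, 14), window = c(0.9, 1.1)),
    stats = list(q = 0.05),
    artifact_prob = 0.02,
    seed = as.integer(seed)
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  class(cfg) <- "pipeline_config"
  cfg
}

# deterministic substream seed below 2^31
#' @noRd
substream_seed <- function(seed, stage, subject = 0L) {
  stage_id <- sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) * 48271 + stage_id * 100003 + subject * 7919) %%
               2147483647)
}

#' Simulate one virtual subject
#'
#' @param cfg a [replica_config()].
#' @param subject subject index (also selects the counterbalance order).
#' @param montage a `montage` (defaults to the packaged one).
#' @return list with `trials` (responded trial table) and `raw` (`raw_eeg`).
#' @export
simulate_subject <- function(cfg, subject, montage = load_montage()) {
  spec <- design_spec(
    n_blocks = cfg$design$n_blocks,
    trials_per_block = cfg$design$trials_per_block,
    hand_switch_block = cfg$design$n_blocks / 2 + 1,
    counterbalance_order = if (subject %% 2 == 1) "RHB_first" else "LHB_first",
    seed = substream_seed(cfg$seed, "design", subject)
  )
  trials <- generate_design(spec)
  trials <- simulate_behavior(trials, cfg$behavior, subject = subject)
  raw <- simulate_session(
    trials, montage, cfg$sources, noise_scale = cfg$noise_scale,
    noise_alpha = cfg$noise_alpha, srate = cfg$srate,
    seed = substream_seed(cfg$seed, "eeg", subject),
    artifact_prob = cfg$artifact_prob
  )
  list(trials = trials, raw = raw, spec = spec)
}

#' Preprocess one subject's raw record
#'
#' Re-reference to linked earlobes, zero-phase filter, epoch cue-locked and
#' target-locked, baseline-correct, and apply amplitude rejection.
#'
#' @param raw a `raw_eeg`; @param trials its trial table;
#' @param cfg a [replica_config()].
#' @return list with `cue` and `target` `epoch_set`s and the rejection
#'   fraction.
#' @export
preprocess_subject <- function(raw, trials, cfg) {
  raw <- rereference(raw)
  raw <- filter_raw(raw, cfg$preprocess$highpass_hz, cfg$preprocess$notch_hz)
  cue <- epoch(raw, trials$cue_onset_s, window = cfg$epoch_window,
               locking = "cue", meta = trials)
  tgt <- epoch(raw, trials$target_onset_s, window = cfg$epoch_window,
               locking = "target", meta = trials)
  cue <- reject_amplitude(cue, cfg$preprocess$reject_uv)
  tgt <- reject_amplitude(tgt, cfg$preprocess$reject_uv)
  list(cue = cue, target = tgt,
       rejection_fraction = mean(cue$rejected | tgt$rejected))
}

#' Analyze one preprocessed subject
#'
#' CSD transform; hemisphere flipping of left-hand blocks for the
#' sensorimotor path; Morlet power with grand-average baseline
#' normalization; ROI band time courses; target-locked prefrontal beta; and
#' flip-corrected seed PLV maps with trial counts equalized across
#' conditions.
#'
#' @param prep output of [preprocess_subject()].
#' @param cfg a [replica_config()]; @param basis a [build_csd_basis()];
#' @param montage the `montage`; @param subject subject index (seeds the
#'   PLV subsampling).
#' @return list of per-subject results (see source).
#' @export
analyze_subject <- function(prep, cfg, basis, montage, subject = 1L) {
  cue <- csd_transform(prep$cue, basis)
  tgt <- csd_transform(prep$target, basis)
  c(subject_tfr_features(cue, tgt, cfg, montage),
    subject_plv_features(cue, cfg, montage, subject))
}

#' Time-frequency features of one subject (CSD-space epochs)
#'
#' Sensorimotor path on hemisphere-flipped data (so `central_right` is
#' ipsilateral to the standard hand), prefrontal target-locked path
#' unflipped, grand-average baseline normalization per condition.
#'
#' @param cue,tgt CSD-transformed cue-/target-locked `epoch_set`s carrying
#'   trial metadata.
#' @param cfg a [replica_config()]; @param montage the `montage`.
#' @return list with `cue_timecourses` (per ROI.band: condition x time),
#'   `times`, `pf_target` (condition x hemisphere mean percent change).
#' @export
subject_tfr_features <- function(cue, tgt, cfg, montage) {
  roi <- cfg$roi
  wp <- wavelet_params(f_b = cfg$wavelet$f_b, f_c = cfg$wavelet$f_c,
                       freqs = cfg$analysis_freqs)
  central <- c(roi$rois$central_left, roi$rois$central_right)
  pf_channels <- c(roi$rois$prefrontal_left, roi$rois$prefrontal_right)
  beta_freqs <- cfg$analysis_freqs[cfg$analysis_freqs >= roi$bands$beta[1] &
                                     cfg$analysis_freqs <= roi$bands$beta[2]]
  wp_beta <- wavelet_params(f_b = cfg$wavelet$f_b, f_c = cfg$wavelet$f_c,
                            freqs = beta_freqs)

  # sensorimotor path: flip left-standard-hand trials onto the right-hand
  # layout so central_right is ipsilateral, central_left contralateral
  lhb <- cue$meta$standard_hand == "left"
  cue_f <- flip_hemispheres(cue, montage, lhb)

  cue_tc <- list()
  tf_cue <- cwt_power(cue_f, wp, channels = central)
  tfm <- tfr_condition_mean(tf_cue, tf_cue$meta$condition)  # EC, EG, EN
  # per-condition baselines: cue conditions have near-equal trial counts,
  # and a condition's own baseline cancels condition-linked multiplicative
  # power (e.g. phase-coupling interference) common to baseline and window
  tfn <- baseline_normalize(tfm)
  for (rn in c("central_left", "central_right")) {
    for (bn in names(roi$bands)) {
      tc <- roi_band_timecourse(tfn, roi$rois[[rn]], roi$bands[[bn]])
      rownames(tc) <- tfn$conditions
      cue_tc[[paste(rn, bn, sep = ".")]] <- tc
    }
  }

  # prefrontal cue-interval path: no hand-locked lateralization is expected
  # frontally, so data stay unflipped and hemispheres are compared as-is;
  # only the beta band is analyzed over prefrontal clusters
  tf_pf <- cwt_power(cue, wp_beta, channels = pf_channels)
  pfm <- baseline_normalize(tfr_condition_mean(tf_pf, tf_pf$meta$condition))
  for (rn in c("prefrontal_left", "prefrontal_right")) {
    tc <- roi_band_timecourse(pfm, roi$rois[[rn]], roi$bands$beta)
    rownames(tc) <- pfm$conditions
    cue_tc[[paste(rn, "beta", sep = ".")]] <- tc
  }
  tf_tgt <- cwt_power(tgt, wp_beta, channels = pf_channels)
  dcond <- derived_condition(tf_tgt$meta)
  tgm <- tfr_condition_mean(tf_tgt, dcond)
  # pooled baseline: derived-condition trial counts are strongly unequal
  # (rare change/nogo trials), and a per-condition baseline would inject a
  # count-dependent ratio bias into the condition contrasts
  pooled_tgt <- tfr_condition_mean(tf_tgt, rep("all", dim(tf_tgt$energy)[1]))
  tgn <- baseline_normalize(tgm, baseline_from = pooled_tgt)
  twin <- tgn$times >= cfg$target_window[1] & tgn$times < cfg$target_window[2]
  pf_target <- sapply(list(left = roi$rois$prefrontal_left,
                           right = roi$rois$prefrontal_right),
                      function(el) {
    tc <- roi_band_timecourse(tgn, el, roi$bands$beta)
    rowMeans(tc[, twin, drop = FALSE])
  })
  rownames(pf_target) <- tgn$conditions

  list(cue_timecourses = cue_tc, times = tfn$times, pf_target = pf_target)
}

#' Seed PLV features of one subject (CSD-space cue epochs)
#'
#' Flip-corrected pooling (ipsilateral seed maps to C4 in the flipped
#' layout), with trial counts equalized across cue conditions by seeded
#' random subsampling, since the PLV estimator is biased by trial count.
#'
#' @param cue CSD-transformed cue-locked `epoch_set` with metadata.
#' @param cfg a [replica_config()]; @param montage the `montage`;
#' @param subject subject index (seeds the subsampling substream).
#' @return list with `plv` (named `plv_map`s, `<side>.<condition>`) and
#'   `n_trials_eq`.
#' @export
subject_plv_features <- function(cue, cfg, montage, subject = 1L) {
  lhb <- cue$meta$standard_hand == "left"
  cue_f <- flip_hemispheres(cue, montage, lhb)
  conds <- c("EG", "EC", "EN")
  keep <- which(!cue_f$rejected)
  counts <- table(factor(cue_f$meta$condition[keep], levels = conds))
  n_eq <- min(counts)
  if (n_eq < 2) stop("too few clean trials for PLV estimation")
  rng <- local_rng(substream_seed(cfg$seed, "plvsub", subject))
  sel <- lapply(conds, function(cc) {
    idx <- keep[cue_f$meta$condition[keep] == cc]
    sort(idx[sample.int(length(idx), n_eq)])
  })
  rng()
  names(sel) <- conds

  # phases once for all retained trials; maps per seed x condition
  all_sel <- sort(unique(unlist(sel)))
  ep <- subset_epochs(cue_f, all_sel)
  ip <- instantaneous_phase(ep, band = cfg$plv$band)
  win <- which(ip$times >= cfg$plv$window[1] & ip$times <= cfg$plv$window[2])
  plv_maps <- list()
  seeds <- c(ipsi = "C4", contra = "C3")  # flip-corrected layout
  for (side in names(seeds)) {
    si <- match(seeds[[side]], ip$channel_labels)
    for (cc in conds) {
      rows <- match(sel[[cc]], all_sel)
      ph <- ip$phase[rows, , win, drop = FALSE]
      seed_ph <- matrix(ph[, si, ], nrow = length(rows))
      vals <- vapply(seq_len(dim(ph)[2]), function(ci) {
        mean(plv(matrix(ph[, ci, ], nrow = length(rows)), seed_ph))
      }, numeric(1))
      names(vals) <- ip$channel_labels
      plv_maps[[paste(side, cc, sep = ".")]] <- structure(
        list(seed = seeds[[side]], plv = vals, n_trials = length(rows),
             band = cfg$plv$band, window = cfg$plv$window),
        class = "plv_map")
    }
  }
  list(plv = plv_maps, n_trials_eq = n_eq)
}

#' Run the full replica study
#'
#' Simulates `cfg$n_subjects` virtual subjects, runs the complete analysis
#' path for each, applies the subject-exclusion rule, and computes the
#' group-level statistics: binned cue-interval contrasts (mu/beta, ipsi- and
#' contralateral, plus prefrontal beta), the target-locked prefrontal beta
#' repeated-measures ANOVAs, PLV contrasts, the behavioral summaries, and
#' the power-RT correlation.
#'
#' @param cfg a [replica_config()].
#' @param montage a `montage`.
#' @param progress print per-subject progress.
#' @return a `replica_result` list (subjects, group, config echoes).
#' @export
run_replica_study <- function(cfg, montage = load_montage(), progress = FALSE) {
  basis <- build_csd_basis(montage, cfg$csd$order_m, cfg$csd$n_terms,
                           cfg$csd$lambda_reg)
  subj_res <- list(); behav <- list(); rej_frac <- numeric(0)
  for (s in seq_len(cfg$n_subjects)) {
    sim <- simulate_subject(cfg, s, montage)
    prep <- preprocess_subject(sim$raw, sim$trials, cfg)
    rej_frac[as.character(s)] <- prep$rejection_fraction
    subj_res[[s]] <- analyze_subject(prep, cfg, basis, montage, subject = s)
    tb <- sim$trials; tb$subject <- s
    behav[[s]] <- tb
    if (progress) message(sprintf("subject %d/%d done", s, cfg$n_subjects))
  }
  excl <- exclude_subjects(rej_frac, cfg$preprocess$exclude_fraction)
  kept <- as.integer(excl$kept)

  group <- group_statistics(subj_res[kept], do.call(rbind, behav[kept]), cfg)
  structure(
    list(subjects = subj_res, behavior = do.call(rbind, behav),
         rejection_fractions = rej_frac, excluded = excl$excluded,
         kept = kept, group = group, config = cfg),
    class = "replica_result"
  )
}

#' Group-level statistics of a replica cohort
#'
#' @param subj_res list of [analyze_subject()] outputs (kept subjects).
#' @param behavior combined responded trial table with a `subject` column.
#' @param cfg the [replica_config()].
#' @return list with `binned` (per family), `target_anova`, `plv`,
#'   `behavior`, `power_rt`.
#' @export
group_statistics <- function(subj_res, behavior, cfg) {
  n <- length(subj_res)
  q <- cfg$stats$q
  times <- subj_res[[1]]$times
  conds <- rownames(subj_res[[1]]$cue_timecourses[[1]])

  stack_tc <- function(key, cond) {
    t(vapply(subj_res, function(r) r$cue_timecourses[[key]][cond, ],
             numeric(length(times))))
  }

  contrasts <- list(`EC-EG` = c("EC", "EG"), `EN-EG` = c("EN", "EG"),
                    `EC-EN` = c("EC", "EN"))
  binned <- list()
  fam_keys <- c(central_right = "ipsi", central_left = "contra")
  for (rn in names(subj_res[[1]]$cue_timecourses)) {
    for (cn in names(contrasts)) {
      a <- stack_tc(rn, contrasts[[cn]][1])
      b <- stack_tc(rn, contrasts[[cn]][2])
      binned[[paste(rn, cn, sep = ":")]] <-
        binned_contrast(a, b, times, bin_edges = cfg$cue_bins, q = q,
                        contrast = paste(rn, cn, sep = ":"))
    }
  }

  # target-locked prefrontal beta: subjects x condition x hemisphere
  pf_conds <- rownames(subj_res[[1]]$pf_target)
  pf <- array(NA_real_, c(n, length(pf_conds), 2),
              dimnames = list(NULL, pf_conds, c("left", "right")))
  for (s in seq_len(n)) pf[s, , ] <- subj_res[[s]]$pf_target
  cells <- function(cset) {
    # cells ordered hemisphere fastest within condition
    do.call(cbind, lapply(cset, function(cc) pf[, cc, ]))
  }
  proactive <- c("go", "no-change", "no-nogo")
  reactive3 <- c("go", "change", "nogo")
  target_anova <- list(
    proactive = rm_anova(cells(proactive), k_a = 3, k_b = 2,
                         factor_names = c("Condition", "Hemisphere")),
    reactive = rm_anova(cells(reactive3), k_a = 3, k_b = 2,
                        factor_names = c("Condition", "Hemisphere")),
    update_vs_no_update = {
      upd <- rowMeans(pf[, c("change", "nogo"), ], dims = 1)
      noupd <- rowMeans(pf[, c("no-change", "no-nogo"), ], dims = 1)
      rm_anova(cbind(upd, noupd), k_a = 2, factor_names = "Condition")
    },
    means = apply(pf, 2, mean)
  )

  # PLV contrasts per seed
  plv_el <- names(subj_res[[1]]$plv[[1]]$plv)
  plv_stats <- list()
  for (seed_side in c("ipsi", "contra")) {
    mats <- lapply(c("EG", "EC", "EN"), function(cc) {
      m <- t(vapply(subj_res, function(r)
        r$plv[[paste(seed_side, cc, sep = ".")]]$plv, numeric(length(plv_el))))
      colnames(m) <- plv_el
      m
    })
    names(mats) <- c("EG", "EC", "EN")
    seed_el <- subj_res[[1]]$plv[[paste(seed_side, "EG", sep = ".")]]$seed
    for (cn in names(contrasts)) {
      a <- mats[[contrasts[[cn]][1]]]; b <- mats[[contrasts[[cn]][2]]]
      plv_stats[[paste(seed_side, cn, sep = ":")]] <-
        plv_contrast(a, b, q = q, exclude = seed_el)
    }
    plv_stats[[paste0(seed_side, ":means")]] <-
      vapply(mats, function(m) mean(m), numeric(1))
  }

  # behavior
  bs <- behavioral_summary(behavior)
  rt_cols <- paste0("rt_", c("go", "no-change", "no-nogo", "change"))
  rt <- as.matrix(bs[, rt_cols])
  # subjects may lack valid RTs in a rare condition; tests use complete pairs
  pt_pairs <- function(a, b) {
    ok <- stats::complete.cases(a, b)
    if (sum(ok) >= 2) paired_t(a[ok], b[ok]) else NULL
  }
  behav_stats <- list(
    summary_means = colMeans(bs[, -1], na.rm = TRUE),
    rt_anova = if (!anyNA(rt)) rm_anova(rt, k_a = 4, factor_names = "Condition")
               else NULL,
    rt_tests = list(
      go_vs_nochange = pt_pairs(rt[, 2], rt[, 1]),
      go_vs_nonogo = pt_pairs(rt[, 3], rt[, 1]),
      go_vs_change = pt_pairs(rt[, 4], rt[, 1]),
      change_vs_nochange = pt_pairs(rt[, 4], rt[, 2]),
      change_vs_nonogo = pt_pairs(rt[, 4], rt[, 3]),
      nochange_vs_nonogo = pt_pairs(rt[, 2], rt[, 3])
    ),
    premature = {
      pm <- as.matrix(bs[, paste0("premature_", c("EG", "EC", "EN"))])
      if (!anyNA(pm)) rm_anova(pm, k_a = 3, factor_names = "Condition") else NULL
    }
  )

  # prefrontal beta vs RT across subjects
  pf_mean <- rowMeans(pf[, c("no-change", "no-nogo"), ], dims = 1)
  rt_mean <- rowMeans(rt[, 2:3])
  power_rt <- if (n >= 3 && !anyNA(rt_mean) && stats::sd(pf_mean) > 0 &&
                  stats::sd(rt_mean) > 0)
    power_rt_correlation(pf_mean, rt_mean) else NULL

  list(binned = binned, target_anova = target_anova, plv = plv_stats,
       behavior = behav_stats, power_rt = power_rt, n_subjects = n)
}

#' Qualitative pattern checks of a replica run
#'
#' Evaluates whether a run reproduces the injected group-level pattern:
#' ipsilateral mu ordering EC < EN < EG over 0.5-1.1 s with at least one
#' FDR-significant EC-EG bin in that range; the target-locked prefrontal
#' beta ordering go < no-change/no-nogo < change/nogo with a significant
#' Condition effect; and at least one significantly reduced
#' ipsilateral-seed frontal PLV connection for EC vs EG.
#'
#' @param res a `replica_result`.
#' @param alpha significance level for the ANOVA condition effects.
#' @return named logical vector (`mu_ordering`, `mu_bins`, `beta_target`,
#'   `plv_decoupling`, `all`).
#' @export
replica_pattern_check <- function(res, alpha = 0.05) {
  g <- res$group
  times <- res$subjects[[res$kept[1]]]$times
  win <- times >= 0.5 & times < 1.1

  mu_key <- "central_right.mu"
  tc <- lapply(c("EC", "EN", "EG"), function(cc) {
    rowMeans(t(vapply(res$subjects[res$kept],
                      function(r) r$cue_timecourses[[mu_key]][cc, win],
                      numeric(sum(win)))))
  })
  m <- vapply(tc, mean, numeric(1))
  mu_ordering <- m[1] < m[2] && m[2] < m[3]

  bc <- g$binned[[paste0(mu_key, ":EC-EG")]]
  late <- bc$t_start >= 0.5
  mu_bins <- any(bc$significant[late] & bc$mean_diff[late] < 0)

  am <- g$target_anova$means
  ord <- am["go"] < mean(am[c("no-change", "no-nogo")]) &&
    mean(am[c("no-change", "no-nogo")]) < mean(am[c("change", "nogo")])
  pa <- g$target_anova$proactive
  cond_sig <- pa$p[pa$effect == "Condition"] < alpha
  upd_sig <- g$target_anova$update_vs_no_update$p[1] < alpha
  beta_target <- ord && cond_sig && upd_sig

  roi <- res$config$roi
  frontal <- unique(c(roi$rois$prefrontal_left, roi$rois$prefrontal_right))
  pc <- g$plv[["ipsi:EC-EG"]]
  sel <- pc$electrode %in% frontal
  plv_decoupling <- any(pc$significant[sel] & pc$median_diff[sel] < 0)

  out <- c(mu_ordering = mu_ordering, mu_bins = mu_bins,
           beta_target = beta_target, plv_decoupling = plv_decoupling)
  c(out, all = all(out))
}

#' Count statistical families with any significant result
#'
#' Used for the null-configuration calibration: with no injected condition
#' differences, the fraction of families showing anything significant
#' should stay near the FDR level.
#'
#' @param res a `replica_result`.
#' @param alpha level for the ANOVA effects.
#' @return list with `n_families`, `n_significant`, `fraction`.
#' @export
replica_family_significance <- function(res, alpha = 0.05) {
  g <- res$group
  fams <- logical(0)
  for (nm in names(g$binned)) fams[nm] <- any(g$binned[[nm]]$significant)
  for (nm in names(g$plv)) {
    if (grepl(":E", nm)) fams[nm] <- any(g$plv[[nm]]$significant)
  }
  pa <- g$target_anova$proactive
  fams["anova_proactive"] <- pa$p[pa$effect == "Condition"] < alpha
  ra <- g$target_anova$reactive
  fams["anova_reactive"] <- ra$p[ra$effect == "Condition"] < alpha
  fams["anova_update"] <- g$target_anova$update_vs_no_update$p[1] < alpha
  list(n_families = length(fams), n_significant = sum(fams),
       fraction = mean(fams))
}

#' Human-readable replica report
#'
#' @param res a `replica_result`.
#' @param file optional path to write the report to.
#' @return the report lines, invisibly.
#' @export
replica_report <- function(res, file = NULL) {
  g <- res$group
  fmt <- function(...) sprintf(...)
  ln <- c(
    "Replica study report",
    "====================",
    fmt("Subjects analyzed: %d (excluded: %s)", g$n_subjects,
        if (length(res$excluded)) paste(res$excluded, collapse = ", ") else "none"),
    "",
    "Behavior (group means)",
    "----------------------"
  )
  bm <- g$behavior$summary_means
  rtc <- c("go", "no-change", "no-nogo", "change")
  ln <- c(ln, fmt("  mean RT (ms): %s",
                  paste(sprintf("%s %.0f", rtc, bm[paste0("rt_", rtc)]),
                        collapse = ", ")))
  ln <- c(ln, fmt("  premature rate: EG %.3f, EC %.3f, EN %.3f",
                  bm["premature_EG"], bm["premature_EC"], bm["premature_EN"]))
  ln <- c(ln, fmt("  failed inhibition: %.3f", bm["failed_inhibition"]))
  if (!is.null(g$behavior$rt_anova)) {
    ra <- g$behavior$rt_anova
    ln <- c(ln, fmt("  RT ANOVA Condition: F(%d,%d) = %.1f, p = %.2g",
                    ra$df1, ra$df2, ra$F, ra$p))
  }
  ln <- c(ln, "", "Cue-target interval (binned contrasts, FDR q = 0.05)",
          "----------------------------------------------------")
  for (nm in names(g$binned)) {
    b <- g$binned[[nm]]
    sig <- which(b$significant)
    ln <- c(ln, fmt("  %-28s significant bins: %s", nm,
                    if (length(sig))
                      paste(sprintf("%.1f-%.1fs", b$t_start[sig], b$t_end[sig]),
                            collapse = " ") else "none"))
  }
  ln <- c(ln, "", "Target-locked prefrontal beta (200-500 ms)",
          "------------------------------------------")
  am <- g$target_anova$means
  ln <- c(ln, fmt("  mean power change (%%): %s",
                  paste(sprintf("%s %.1f", names(am), am), collapse = ", ")))
  for (nm in c("proactive", "reactive")) {
    a <- g$target_anova[[nm]]
    ce <- a[a$effect == "Condition", ]
    ln <- c(ln, fmt("  %s ANOVA Condition: F(%d,%d) = %.1f, eps = %.2f, p = %.2g",
                    nm, ce$df1, ce$df2, ce$F, ce$epsilon, ce$p))
  }
  u <- g$target_anova$update_vs_no_update
  ln <- c(ln, fmt("  change/nogo vs no-change/no-nogo: F(%d,%d) = %.1f, p = %.2g",
                  u$df1[1], u$df2[1], u$F[1], u$p[1]))
  ln <- c(ln, "", "Alpha PLV (900-1100 ms, Wilcoxon + FDR)",
          "---------------------------------------")
  for (nm in names(g$plv)) {
    if (!grepl(":E", nm)) next
    p <- g$plv[[nm]]
    sig <- which(p$significant)
    ln <- c(ln, fmt("  %-16s significant connections: %s", nm,
                    if (length(sig))
                      paste(sprintf("%s(%+.2f)", p$electrode[sig],
                                    p$median_diff[sig]), collapse = " ")
                    else "none"))
  }
  if (!is.null(g$power_rt)) {
    ln <- c(ln, "", fmt("Prefrontal beta vs RT: r = %.2f, p = %.2g",
                        g$power_rt$r, g$power_rt$p))
  }
  if (!is.null(file)) writeLines(ln, file)
  ln
}
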