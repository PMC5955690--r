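# oscmotor

Simulation and analysis of EEG oscillatory correlates of **proactive motor
control** in a cued go-nogo-change task.

In this task a colored cue announces whether the upcoming target will
certainly require the standard button press (expecting go, EG), may require
switching to the other hand (expecting change, EC), or may require
withholding the response (expecting nogo, EN). The preparatory cue-target
interval isolates proactive control, whose EEG signatures are:

* **sensorimotor mu (9–14 Hz) and beta (15–25 Hz) power** changes relative
  to a pre-stimulus baseline (event-related desynchronization /
  synchronization), compared ipsi- and contralateral to the standard hand
  after flipping left-hand blocks across the midline;
* a **target-evoked prefrontal beta burst** indexing cognitive control,
  analyzed 200–500 ms post-target with repeated-measures ANOVA
  (Greenhouse–Geisser corrected);
* **alpha-band phase-locking value (PLV)** connectivity from sensorimotor
  seeds (C3/C4) to all electrodes in the 900–1100 ms pre-target window,

  `PLV = (1/N) |Σ_trials exp(i[φ_e1 − φ_e2])|`,

  tested with Wilcoxon signed-rank + FDR.

Because raw data for such studies are not packaged, the pipeline is
validated generatively: `simulate_session()` produces 64-channel raw EEG
(EDF+) with *known injected structure* — condition-dependent mu/beta
amplitude envelopes, controllable von Mises phase coupling with exact
expected PLV `I1(κ)/I0(κ)`, pink-noise background — and every analysis
stage (linked-earlobe re-referencing, zero-phase filtering, epoching,
±80 µV rejection, order-4 spherical-spline surface Laplacian, Morlet CWT
with `f_b = 1`, `f_c = 1.5`, percent-change baseline normalization, ROI
aggregation, PLV, binned paired t-tests with BH-FDR) must recover it.

## Worked example

Simulate one virtual subject, preprocess, and look at the ipsilateral
mu-band time course per cue condition:

```r
library(oscmotor)

montage <- load_montage()
cfg     <- replica_config(seed = 3)
basis   <- build_csd_basis(montage)

sim  <- simulate_subject(cfg, subject = 1, montage)
prep <- preprocess_subject(sim$raw, sim$trials, cfg)
res  <- analyze_subject(prep, cfg, basis, montage, subject = 1)

tc  <- res$cue_timecourses[["central_right.mu"]]   # ipsilateral after flipping
win <- res$times >= 0.5 & res$times < 1.1
round(rowMeans(tc[, win]), 1)
#>    EC    EG    EN
#> -27.7   4.6 -39.8
```

Single-subject estimates at this scaled-down session size are noisy (tens
of percent); inference lives at the group level. A full cohort study with
group statistics and a text report:

```r
res <- run_replica_study(replica_config(seed = 11))
replica_pattern_check(res)
#>    mu_ordering        mu_bins    beta_target plv_decoupling            all
#>           TRUE           TRUE           TRUE           TRUE           TRUE
cat(replica_report(res), sep = "\n")
```

The report lists group mean RTs per condition, FDR-significant 100-ms bins
for each cue-interval contrast, the prefrontal beta ANOVAs, and the
significant PLV connections. A file-based variant with hash-linked stage
manifests is available through `run_all_stages()` or the CLI script
`inst/scripts/oscmotor.R` (subcommands `simulate`, `preprocess`, `csd`,
`tfr`, `plv`, `stats`, `report`, `replica`).

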