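---
title: "Methods: simulating and analyzing oscillatory correlates of proactive motor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing oscillatory correlates of proactive motor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In a cued go-nogo-change task, a colored cue tells the participant whether
the upcoming target will certainly demand the standard button press
(expecting go, EG), may demand a switch to the other hand (expecting
change, EC), or may demand withholding the response altogether (expecting
nogo, EN). The cue-target interval therefore isolates *proactive* motor
control: the preparatory biasing of the motor system before the imperative
stimulus. Its electrophysiological signatures are band-limited power
changes of the sensorimotor mu (9-14 Hz) and beta (15-25 Hz) rhythms
relative to a pre-stimulus baseline (event-related
desynchronization/synchronization, ERD/ERS), a target-evoked prefrontal
beta burst indexing cognitive control, and alpha-band phase coupling
between motor and prefrontal cortex.

Because no raw data from such studies are packaged here, the pipeline is
validated the other way around: a generative EEG simulator injects a known
oscillatory structure, and every analysis stage must recover it. The
package is therefore both an analysis pipeline (EDF+ in, statistics out)
and a simulation laboratory with exact ground truth.

## The task generator

`design_spec()` defaults to the full session: 6 blocks of 160 trials (960
trials), the three cue conditions equiprobable (treated as exactly 1/3),
rare targets on exactly 25% of EC and EN trials, a 100 ms cue, a 1 s
inter-stimulus interval, a 100 ms target, and inter-trial intervals
jittered uniformly in 1.3-1.6 s. With exact allocation, 160/3 is not an
integer, so per-block counts are 53/53/54 with the remainder rotated
across blocks; rare-target counts are made exact at the session level
within each of EC and EN (spread over blocks by largest remainder). The
standard response hand switches after half the blocks, and the order is
counterbalanced across (virtual) participants.

Reaction times come from a shifted log-normal family -- the conventional
right-skewed choice for RT data -- parameterized by target means and SDs
per derived condition (go 250±100, no-change 358±76, no-nogo 354±84,
change 403±88 ms) with a common 100 ms shift and a 40 ms between-subject
SD of the location. Error types are Bernoulli processes: premature presses
during the cue-target interval (rates per cue condition: EG 9.8%, EC
0.45%, EN 0.34%), omissions and choice errors per responded condition, and
failed inhibitions on 13% of nogo trials. These rates are generative
parameters, not claims about data; they produce the qualitative behavioral
pattern (go fastest, change slowest, premature errors concentrated in EG).

## The EEG simulator

Each oscillatory source is band-limited Gaussian noise (a hard FFT band
mask), not a sinusoid, so that *band power* -- not a spectral line --
carries the injected effect, as in real EEG. The source is projected onto
the scalp through a Gaussian topography in angular distance on the unit
sphere and multiplied by a piecewise-linear amplitude envelope per derived
trial condition (times relative to cue onset, constant extrapolation
outside the breakpoints). Background activity is 1/f^alpha pink noise,
synthesized spectrally, independent across the 64 scalp channels plus two
near-quiet earlobe reference channels. Phase coupling is injected by
letting a source share the analytic carrier of a seed source rotated by a
per-trial von Mises phase offset; the expected phase-locking value is then
the von Mises mean resultant length I1(kappa)/I0(kappa)
(`inject_coupling_level()`), which gives tests an exact ground-truth PLV.

The montage is an idealized spherical 10-10 layout built by great-circle
interpolation between outer-ring and midline anchors -- the standard
template construction when no digitized positions exist -- shipped as a
JSON asset and reproducible from `standard_montage()`.

What the simulator does *not* emulate: ocular and muscle artifacts beyond
optional square-pulse test artifacts, volume conduction with realistic
head geometry, learning effects across blocks, or any dependence of the
EEG on behavioral responses. Passing tests therefore demonstrate that the
pipeline recovers known band-power and phase-coupling structure under
realistic noise, not that it handles every pathology of empirical
recordings.

## Preprocessing

The fixed order is re-reference (linked earlobes) -> zero-phase filtering
-> epoching with baseline correction -> amplitude rejection. Filters are a
4th-order Butterworth high-pass at 0.5 Hz and a biquad 50 Hz notch
(Q = 30), each applied forward-backward; the compiled implementation uses
odd-reflection padding with steady-state initial conditions, the
best-behaved of the common filtfilt edge conventions. Epochs are half-open
windows [-1, 2) s around the locking event (750 samples at 250 Hz, onset
at index 251), baseline-corrected by the mean of the 100 ms preceding the
event. A trial is rejected iff any channel sample of the post-baseline
voltages exceeds ±80 uV (the threshold compares post-baseline values; the
choice is configurable). A subject is excluded iff strictly more than 30%
of trials are rejected.

## Surface Laplacian (CSD)

Scalp potentials are interpolated with order-4 spherical splines
(Legendre series g and h truncated at 50 terms, computed by the
three-term recurrence) and differentiated analytically on the sphere; the
output is the negative surface Laplacian, so current sources are
positive. The regularization default is lambda = 1e-5; halving it changes
smooth maps by under 2% RMS. The transform is precomputed as a single
electrode-by-electrode matrix, making it exactly linear, reference-free,
and cheap (one matrix multiply per epoch set). Output units are arbitrary
(potential per squared sphere radius); the scale cancels in
percent-change normalization downstream. Correctness is checked against
the analytic surface Laplacian of a degree-3 spherical harmonic
(-l(l+1) times the harmonic).

## Time-frequency analysis

The mother wavelet is the complex Morlet
w(t) = (pi f_b)^(-1/2) exp(2 pi i f_c t) exp(-t^2 / f_b) with f_b = 1 and
f_c = 1.5; the printed form of this equation in the literature this
pipeline follows is typographically ambiguous, and this reading is the
standard one consistent with the cmor1-1.5 parameterization. The daughter
at analysis frequency f is the mother compressed by the scale f_c / f
with 1/sqrt(scale) normalization; energy is the squared magnitude of the
FFT convolution, with samples flagged when less than 95% of the wavelet
energy overlaps the epoch. The default grid is 1-40 Hz in 1 Hz steps.
Power is expressed as percent change from the -250 to -50 ms pre-stimulus
baseline, computed on condition-averaged energy (grand-average
convention; per-trial normalization is available by passing single-trial
energy). The replica pipeline makes one bias/variance choice here worth
spelling out. For cue-locked analyses, each condition is normalized by its
own baseline: the cue conditions have equal trial counts by design, and a
condition's own baseline cancels any condition-linked *multiplicative*
power component shared by baseline and window -- notably the
interference between a phase-coupling seed and its coupled sources, whose
expected constructive/destructive cross-term depends on the coupling
concentration and therefore on condition. For target-locked analyses the
derived conditions have strongly unequal trial counts (rare change/nogo
trials), and a per-condition baseline estimated from very few trials
injects a count-dependent ratio bias into the condition contrasts (the
expectation of P/B grows with the variance of B); there the baseline is
pooled over all trials, which is unbiased because a pre-stimulus baseline
cannot differ between conditions in expectation in that window. Sensorimotor analyses flip left-hand-block trials across the
midline so that `central_right` is always ipsilateral to the standard
hand; prefrontal analyses use unflipped data, since no hand-locked
lateralization is expected frontally.

## Phase-locking value

Instantaneous phase comes from a zero-phase 4th-order Butterworth
band-pass (9-14 Hz) followed by the analytic signal. PLV is the modulus
of the across-trial mean unit phasor of the phase difference, computed
per time sample and averaged over the 0.9-1.1 s pre-target window (the
standard reading when the windowing is ambiguous). Because the estimator
is positively biased at small N, trial counts are equalized across
conditions by seeded subsampling before condition comparisons. PLV is
computed on CSD-transformed signals by default, consistent with the
pipeline order; a raw-potential path is available by skipping the CSD
stage.

## Statistics

Cue-interval contrasts are paired t-tests on mean power in nine 100 ms
bins from 200 to 1100 ms, corrected with Benjamini-Hochberg FDR at
q = 0.05 *within* one contrast-by-cluster family (the family scope is
configurable; within-family correction is the conservative default when
the scope is ambiguous). Target-locked prefrontal beta (200-500 ms) goes
into repeated-measures ANOVAs with factors Condition and Hemisphere;
effects with more than one numerator df receive the Greenhouse-Geisser
epsilon estimated from the covariance of the effect's orthonormal
contrast variables, and the convention is to report uncorrected degrees
of freedom with corrected probabilities. PLV contrasts use Wilcoxon
signed-rank tests per connection (exact by sign enumeration for n <= 15
without ties, normal approximation with continuity correction otherwise;
zero differences dropped) with FDR across connections. All tests are
two-sided. Degenerate inputs (zero-variance differences) yield flagged
missing results, never infinite statistics.

## The replica study and problem sizes

`replica_config()` assembles the full pipeline: 22 virtual subjects, the
default effect configuration, and group statistics. The per-subject
session is scaled to 2 blocks of 12 trials (one block per standard hand,
4 trials per cue condition per block, exactly one rare target among
them), and the replica time-frequency grid is 9-25 Hz in 2 Hz steps;
both choices keep a twenty-seed cohort study at interactive desk scale
while preserving the design structure exactly. The full-length session
and the 1-40 Hz grid remain the module defaults for single-session use.
With fewer trials per subject, single-subject power estimates are noisy
(tens of percent), and the group-level contrasts carry the inference --
which is also how the corresponding human studies are powered.

The default effect configuration injects: contralateral mu/beta ERD in
all cue conditions (deepest in EG); ipsilateral mu rising in EG, flat in
EN, falling in EC, with the matching ipsilateral beta drop only in EC; a
target-locked prefrontal beta burst with amplitude ordering go <
no-change/no-nogo < change/nogo; and seed-to-frontal alpha coupling at
von Mises concentration 8 (expected PLV about 0.94) that drops to 1
(about 0.45) when a change is expected. The null configuration equalizes
every envelope and concentration across conditions, leaving only the
task structure; it is used to verify that the family-wise significance
rate stays near the FDR level.

`replica_pattern_check()` codifies the qualitative success criteria
(ipsilateral mu ordering EC < EN < EG over 0.5-1.1 s with significant
EC-EG bins, the prefrontal beta Condition effect with the injected
ordering, and at least one significantly reduced ipsilateral frontal PLV
connection for EC vs EG), and `replica_family_significance()` counts
families with any significant result for null calibration.

## Numerical choices and degenerate inputs

* FFT lengths are rounded up to 5-smooth integers.
* The wavelet kernel is truncated at ±4 amplitude SDs; an analysis
  frequency whose central 95% energy span exceeds the epoch is refused
  with the lowest usable frequency named.
* Percent-change normalization refuses non-positive baselines (possible
  only for identically zero input).
* The spline system is solved once per montage with an explicit
  condition estimate; duplicate electrode positions are refused.
* The exact allocation path fails loudly (naming the offending count)
  whenever probabilities cannot be realized as integers.
* Seeds: one global seed expands into per-stage, per-subject substreams
  through a fixed integer hash, so any stage or subject can be re-run
  independently and reproducibly; all seeds stay below 2^31.

## Known limitations

The spherical head and Gaussian topographies ignore realistic volume
conduction, so absolute CSD magnitudes are not physiologically
interpretable (only their spatial pattern and relative changes are).
The simulator's stationary band-limited carriers make band power
chi-squared distributed, which is optimistic relative to the heavy tails
of real EEG power. Ocular-artifact removal (ICA) is deliberately out of
scope: the synthetic data carry no ocular components, and the amplitude
rejector covers the artifact classes that are simulated. The behavioral
and EEG generators are independent, so brain-behavior correlations are
null by construction and the power-RT correlation serves as a
specificity check rather than a sensitivity one.
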