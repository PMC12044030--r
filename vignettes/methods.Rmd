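---
title: "Methods: tracking the reselection of visual and motor working-memory content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking the reselection of visual and motor working-memory content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmreselect)
```

## The scientific problem

In retro-cue working-memory experiments, a participant holds two lateralized
tilted bars in memory; a colored cue during the delay indicates which bar
must be reproduced at the end of the trial. Because each bar's tilt direction
is yoked to the hand that will report it, and the cued bar's screen side is
counterbalanced against that hand, two neural signatures can be tracked
independently:

* **visual selection** — attenuation of posterior alpha power (8–12 Hz,
  electrodes PO7/PO8) contralateral to the cued item's location;
* **motor selection** — attenuation of central beta power (13–30 Hz,
  electrodes C3/C4) contralateral to the required response hand.

When an interrupting perceptual task is inserted into the delay (at an early,
medium, or late onset), the question is *what* is reselected afterwards
(motor plans only, or visual location too) and *when* (immediately after the
interrupter response, or just in time for the probe). `wmreselect` implements
the full analysis machinery for this design — behavioral decomposition, gaze
towardness, time–frequency lateralization, cluster-based permutation
inference, and cross-correlation lag analysis — together with a synthetic
cohort generator so that every stage can be validated against known ground
truth without any recorded data.

## Orientation space

Bar tilts are 180°-periodic: all angular arithmetic wraps differences into
(−90°, 90°] and errors into [0°, 90°] (`orientation_diff()`,
`orientation_error()`). Uniform random reports therefore have a mean absolute
error of 45°, which serves as the chance level for the behavioral tests. All
circular machinery (report sampling, mixture fitting) operates on **doubled
angles**, where the orientation circle becomes the full circle and von Mises
distributions apply; a report standard deviation of 10° in orientation space
corresponds to a doubled-angle concentration of roughly κ ≈ 8.2.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults encode the study
conditions the rest of the package is validated under.

**Trial tables** (`make_trial_table()`). The default design uses 24-trial
blocks: one third no-interruption blocks, the rest split evenly between
fixed-onset and variable-onset interruption blocks, with the three
interrupter onsets at 600, 1400 and 2400 ms after the cue. Within every
onset condition the four cells of cued side × response hand are
counterbalanced, and the tilt sign determines the response hand on every row
(anticlockwise ↔ left). Orientation magnitudes avoid the meridians (10–80°
in 1° steps). Interrupter reaction times are truncated-normal with mean
400 ms and sd 50 ms, bounded to the 100–800 ms response window — anchored to
the ~401.5 ms average reported for late-onset interrupters under an 800-ms
deadline.

**Reports** (`sample_reports()`). Reports are drawn from the standard
three-component continuous-report mixture: a von Mises component on the
target (probability `p_target`), a von Mises "swap" component on the
interrupter orientation (`p_nontarget`), and a uniform guessing component
(`p_guess`). The attractive bias toward the interrupter is modelled as a
derivative-of-Gaussian odd function of the signed target–interrupter
difference with peak amplitude `bias_gain` (degrees) at a difference of
`bias_sd` = 20°. Only the measured bias *curve* is known empirically; the
generative form is a modeling choice, and the derivative-of-Gaussian is the
smoothest odd shape with a single interior peak that vanishes at 0° and
±90°, which is what the binned curve looks like.

**Gaze** (`sample_gaze()`). Binocular traces at a configurable raw rate
carry a cue-locked and (on interruption trials) a response-locked Gaussian
deflection signed by the cued side, smooth drift noise, and optional
saturation artifacts standing in for blinks, with ground-truth intervals
returned alongside. Trials are generated at fixation scale (amplitudes well
below the 2.75° rejection criterion).

**EEG epochs** (`sample_epochs()`). Each channel carries 1/f-amplitude
Gaussian background noise plus, per `neural_effect()`, a band-limited
oscillation (random frequency in the band, random phase per trial and
channel) whose amplitude at the channel contralateral to the relevant trial
feature is reduced by `contra_attenuation` inside the effect windows.
Transient windows use a Hann profile; sustained windows ramp up over 100 ms
and hold. Response-locked windows sit at interrupter onset + that trial's
simulated reaction time (+ `motor_delay_ms` for the motor generator). With
attenuation *a* and negligible noise, the planted lateralization index is
analytically −100·(1−r)/(1+r) with r = (1−a)², which the tests verify.

What the generator does **not** emulate: volume conduction and realistic
scalp topography beyond the effect pair, eye-movement artifacts in the EEG,
trial-to-trial latency jitter of the neural response beyond the RT
distribution, and non-stationary background spectra. Passing tests therefore
demonstrate that the analysis machinery is correct and well calibrated, not
that it would be equally sensitive on any given real dataset.

**Paired reselection courses** (`sample_reselection_courses()`). The
cross-correlation stage is additionally validated on directly generated
visual/motor band-course pairs: Gaussian deflections (sd 50 ms) centred
100 ms after the response, with a plantable motor delay and smooth noise at
peak SNR 20. Two geometric constraints matter and are deliberate: the
deflections sit well inside the −400..400 ms window (edge truncation of a
template shifts the correlation peak), and the 50-ms width keeps the
correlation peak sharp enough that the triangular partial-overlap term
introduced by mean-centering cannot displace it. At this SNR the group-mean
peak lag recovers planted delays of ±100 and ±200 ms within one sample.

## Behavioral analysis

`apply_exclusions()` implements the a-priori rules: probe RTs above 5000 ms
or 2.5 SD above the participant mean; interruption trials answered wrongly,
late (> 800 ms), or not at all. Datasets are flagged (not silently dropped)
when more than 15% of trials are removed or when the mean reproduction error
reaches 45° in any condition.

`fit_mixture()` maximizes the three-component likelihood by
expectation–maximization on doubled angles with a shared κ for the two von
Mises components, 10 random restarts plus one moment-informed start, and a
relative log-likelihood tolerance of 1e-8. κ updates invert the Bessel ratio
A₁(κ) with the Best–Fisher approximation refined by root-finding; κ is
capped at 10⁴ and fits at that boundary are flagged. Degenerate input (zero
spread) returns the boundary fit with a warning rather than an error.

`response_bias_curve()` demeans each participant's *signed* errors across
all interruption trials — signed demeaning is the only choice that removes a
constant response bias without touching the bias of interest — and averages
them in a moving window (step 5°, width 45°) over the signed
target–interrupter difference, whose axis wraps with a 180° period. Errors
are demeaned across (not within) onset conditions; the alternative is not
distinguishable from the published description, and across-condition
demeaning uses all trials for the estimate of the constant bias. Empty bins
are reported as `NA`, never 0. The curve is tested against zero with the
same cluster-based permutation machinery used for time courses, with bins as
the ordered axis; participants remain the exchangeable unit, so the overlap
of neighbouring windows affects sensitivity but not validity.

## Gaze analysis

`preprocess_gaze()` runs the chain: blink interpolation (linear, ±100 ms
padding, nearest-value extension at trace boundaries), eye averaging,
downsampling to 250 Hz by decimation after a decimation-length moving
average (anti-aliasing; the reference description does not state a method),
epoching to −200..4200 ms, rejection of trials exceeding ±2.75° on either
axis, 15-sample (60 ms) centred moving-average smoothing with edge
truncation, and per-trial baselining on −200..0 ms. Baselining is applied
after smoothing; the order is ambiguous in the reference description, and
this order guarantees an exactly zero pre-cue mean in the output.
`towardness()` is (mean x on right-cued trials − mean x on left-cued
trials)/2, positive toward the cued item, and is antisymmetric under label
exchange by construction.

## Time–frequency analysis

`morlet_tfr()` uses complex Morlet wavelets with a **fixed 300-ms analysis
window** at every frequency, so the cycle count scales as f × 0.3 (3 cycles
at 10 Hz, 6 at 20 Hz). The Gaussian envelope's standard deviation is
0.3/(2π) s ≈ 47.7 ms — the ±πσ extent of the envelope spans the stated
window — and each kernel is mean-corrected for admissibility and
L2-normalized. Convolution is FFT-based with the kernel centred at lag zero;
power is the squared magnitude. Output samples closer than half the window
to an epoch edge are flagged invalid and excluded from cluster statistics.
Power may be decimated in time (`decim`) for statistics, since it varies on
the envelope timescale.

`lateralization_index()` averages power over trials within the contra and
ipsi splits *before* forming 100·(contra−ipsi)/(contra+ipsi) — the
induced-power convention — and then averages the two electrodes' indices.
Power enters raw (not log-transformed): the normalized difference is already
self-normalizing and bounded in [−100, 100]. Zero-power cells propagate
`NA`, never 0. No baseline correction of power is applied anywhere.
`band_course()` is an unweighted mean over the band's frequencies;
`topography_contrast()` forms the same normalized difference per channel
from right- versus left-labelled trials, averaged in requested time windows.
`epoch_around_event()` re-cuts −400..400 ms epochs at per-trial events
(interrupter onset + RT), dropping and counting trials whose window leaves
the source epoch.

## Cluster-based permutation inference

`cluster_permutation_test()` computes per-point one-sample t statistics,
thresholds at the two-sided critical value for `cluster_alpha` = 0.05
(strict inequality; the sidedness choice is exposed), forms clusters from
contiguous supra-threshold runs of common sign (1-D) or 4-connected
components (2-D time × frequency), and uses the cluster **mass** (sum of t)
as the statistic. The null is built from random participant sign flips
(1024 by default), recording the maximum absolute mass per permutation
across both signs; p = (1 + #{null ≥ observed})/(1 + n_perm). When 2ⁿ sign
patterns number no more than `n_perm`, the test switches to exhaustive
enumeration and p-values are exact proportions (the identity pattern
included, so p ≥ 2⁻ⁿ). Mass comparisons use a 1e-8 relative tolerance so
the identity permutation always counts at least once despite float
round-off between code paths. Both one-sided variants are available, and
the reported clusters can be restricted to either sign while the null
maximum always spans both. The permutation inner loop is compiled (Rcpp),
which is what makes the 200-dataset calibration runs take seconds. The
family-wise false-positive rate on temporally correlated null data
(AR(1), φ = 0.7, 20 participants × 100 points) is verified to lie in
[0.02, 0.09] over 200 simulated datasets.

A cluster's **onset** is defined as its first time index. The
onset-ordering summary (`compare_onset_conditions()`) takes, per onset
condition, the first significant cluster starting after that condition's
interrupter onset; it claims an ordering only when every condition has such
a cluster and the starts are strictly increasing.

`esd_reject()` implements Rosner's generalized extreme studentized deviate
procedure for per-trial variance scores; the outlier count is the largest
step whose statistic exceeds its critical value, so inner non-significant
steps cannot mask extreme later ones. The implementation reproduces the
canonical 54-point literature example (3 outliers) and its published R
statistics.

## Cross-correlation lag analysis

`normalized_xcorr()` evaluates z[k] = Σᵢ x[i]·y[i−k] over the full lag
range −(n−1)..(n−1), including partial overlap, and divides by the global
energy √(Σx²·Σy²), so coefficients lie in [−1, 1] and are invariant to
amplitude scaling of either input. With y a delayed copy of x (delay d), the
peak falls at k = −d; this sign convention is documented and pinned by a
brute-force double-loop oracle in the tests. Signals are mean-centred over
the analysis window by default (a shared offset otherwise dominates the
peak); centering is a flag, as is per-lag normalization and a minimum
overlap fraction (default 0.5) that flags edge lags as unreliable without
removing them. `peak_lag()` breaks exact ties toward the smallest |lag| and
then the negative lag; `zero_lag_test()` is the group one-sample t of
per-participant peak lags against zero, with Cohen's d on the same scores.

## The pipeline and its desk-scale problem sizes

`run_reselection_pipeline()` chains simulation → behavior → gaze → spectral
→ cluster statistics → cross-correlation from a single `run_config()`, whose
seed determines every random draw; rerunning a config reproduces every
table. Fixed- and variable-predictability trials are pooled by default (a
paired contrast is available through `paired_cluster_test()`). Figures
(`autoplot()` methods) are advisory; all numeric conclusions come from the
tidy tables and cluster reports the pipeline emits.

The package's validation runs use a cohort of 20 participants × 96 trials
(24 per onset condition + 24 no-interruption), 4 channels, 250 Hz, TFR at
the band frequencies with 4× time decimation for statistics, and 1024
permutations — sizes chosen so the full recovery suite completes in a few
minutes on a laptop while the planted effects (alpha/beta attenuation 0.35
and 0.3 at background noise sd 1) emerge reliably at the group level.
Under these conditions the pipeline recovers the full qualitative pattern:
two alpha clusters per onset condition, reselection onsets strictly ordered
early < medium < late, response-locked alpha and beta clusters beginning
within ~100 ms of the interrupter response, and a synchronous (statistically
zero) visual–motor lag.

## Known limitations

* The generator's oscillatory effects are stationary sinusoids under an
  amplitude envelope; real band power fluctuates and its attenuation is
  partial and variable across participants.
* The mixture model shares one κ across target and swap components and fits
  a single nontarget; swap modeling with multiple nontargets and Bayesian
  model comparison are out of scope.
* The bias-curve bins overlap (45° windows at 5° steps), so neighbouring
  bins are strongly dependent; the cluster test remains valid (participants
  are the exchangeable unit) but cluster extents along the bin axis should
  not be over-interpreted.
* In the pooled response-locked analysis, cue-locked effects from
  early-onset trials can extend into the pre-response window and merge with
  the response-locked cluster, moving the nominal cluster start earlier than
  the response; the per-onset analyses disambiguate.
* 2-D cluster connectivity is fixed to the 4-neighbourhood; TFCE and
  cluster-extent statistics are not provided.
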