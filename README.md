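# wmreselect

Analysis machinery for retro-cue working-memory experiments with an embedded
interrupting task, for researchers studying how internal visual
representations and their associated action plans are re-attended after
external interference.

In the underlying paradigm, participants memorize two lateralized tilted
bars; a retro-cue selects the one to reproduce, and on most trials a
perceptual discrimination task interrupts the memory delay at one of three
onsets (600, 1400, or 2400 ms after the cue). Because the cued item's screen
side and the response hand implied by its tilt are manipulated orthogonally,
two lateralized EEG signatures can be tracked independently and expressed as
the normalized index

```
LI = 100 * (contra - ipsi) / (contra + ipsi)
```

on band power: posterior alpha (8–12 Hz, PO7/PO8) relative to the cued
item's location indexes *visual* selection, and central beta (13–30 Hz,
C3/C4) relative to the required response hand indexes *motor* selection.
The package implements, as tested and reusable components:

* a **synthetic cohort generator** — balanced trial tables, circular-mixture
  reports with an attractive bias, fixational gaze with blink artifacts, and
  epoched multichannel EEG with planted, band-limited lateralized effects —
  so every stage runs against known ground truth;
* **behavior** — trial exclusions, 45°-chance-level and condition tests with
  Cohen's d, EM fitting of the target/swap/guess von Mises mixture on
  doubled angles, and the moving-window (step 5°, width 45°) response-bias
  curve;
* **gaze** — blink interpolation, downsampling, fixation filtering,
  smoothing, baselining, and the towardness metric;
* **spectral** — Morlet time–frequency power with a fixed 300-ms window
  (cycles = f × 0.3), lateralization indices, band courses, topography
  contrasts, and event-locked re-epoching around the interrupter response;
* **stats** — cluster-based sign-flip permutation tests (1-D and 2-D, mass
  statistic, 1024 permutations, cluster alpha 0.05, exact enumeration on
  small cohorts) and generalized ESD trial rejection;
* **crosscorr** — full-lag normalized cross-correlation
  `z[k] = Σ x[i]·y[i−k]` scaled to [−1, 1], per-participant peak lags, and
  the group zero-lag test;
* a **pipeline** (`run_reselection_pipeline()`) chaining all stages from a
  single seeded, YAML-serializable config.

## Worked example

Simulate a 10-participant cohort, decompose the reports, and test the
alpha-band lateralization course against zero:

```r
library(wmreselect)

cfg <- task_config(n_participants = 10, n_trials_per_participant = 96,
                   seed = 1)
trials <- make_trial_table(cfg) |>
  sample_reports(p_target = 0.95, p_nontarget = 0.02, p_guess = 0.03,
                 kappa = 8.2, bias_gain = 2)

chance_and_condition_tests(trials)
#> # A tibble: 3 × 8
#>   test              estimate       t    df  p_value cohens_d     n zero_variance
#>   <chr>                <dbl>   <dbl> <dbl>    <dbl>    <dbl> <int> <lgl>
#> 1 interruption vs …    9.66  -75.8       9 6.12e-14  -24.0      10 FALSE
#> 2 no-interruption …    9.22  -47.8       9 3.87e-12  -15.1      10 FALSE
#> 3 interruption vs …    0.442   0.435     9 6.74e- 1    0.137    10 FALSE
```

Mean reproduction errors (9–10°) sit far below the 45° chance level in both
block types, and the interruption cost (0.44°) is not resolvable at this
cohort size. The mixture decomposition recovers the generator's components:

```r
fits <- fit_mixtures(trials)
dplyr::summarise(fits, dplyr::across(c(p_target, p_nontarget, p_guess,
                                       sd_deg), mean))
#> # A tibble: 1 × 4
#>   p_target p_nontarget p_guess sd_deg
#>      <dbl>       <dbl>   <dbl>  <dbl>
#> 1    0.948      0.0259  0.0258   9.61
```

Plant a transient alpha attenuation (cue-locked and response-locked),
decompose, lateralize, and run the cluster test:

```r
eff <- neural_effect("alpha", c("PO7", "PO8"), contra_attenuation = 0.35,
                     windows = data.frame(start_ms = c(200, 0),
                                          end_ms = c(800, 400),
                                          profile = "transient",
                                          lock = c("cue", "response")))
epochs <- sample_epochs(trials, cfg, list(eff), noise_sd = 1, seed = 2)

alpha <- morlet_tfr(epochs, freqs = 8:12, channels = c("PO7", "PO8"),
                    decim = 4) |>
  lateralization_index(trials, c("PO7", "PO8"), "item_side") |>
  band_course("alpha")

mat <- course_matrix(dplyr::filter(alpha, valid), value = "index")
cluster_permutation_test(mat, n_perm = 1024, time = attr(mat, "axis"),
                         seed = 3)
#> <cluster_result> exhaustive sign-flip test, 1024 permutations, |t| > 2.262 (df = 9)
#> # A tibble: 5 × 9
#>   cluster  sign start   end n_points    mass       p start_ms end_ms
#>     <int> <int> <dbl> <int>    <int>   <dbl>   <dbl>    <dbl>  <dbl>
#> 1       1    -1    21    50       30 -387.   0.00195      280    744
#> 2       2    -1    71    87       17  -77.8  0.0215      1080   1336
#> 3       3    -1   179   195       17  -56.7  0.0293      2808   3064
#> 4       4    -1   202   205        4  -10.7  0.686       3176   3224
#> 5       5    -1   246   247        2   -4.97 0.916       3880   3896
```

The significant negative clusters are the planted cue-locked selection
(280–744 ms) and the interrupter-response-locked reselection visible here
after the early (1080–1336 ms) and late (2808–3064 ms) onsets; negative
values mean contralateral attenuation. `autoplot()` methods exist for band
courses, towardness, bias curves, and cross-correlograms, and `tidy()` /
`glance()` for fitted objects. `run_reselection_pipeline(run_config(...))`
chains everything — behavior, gaze, per-onset and response-locked spectral
analyses, the onset-ordering summary, and the visual–motor
cross-correlation — and writes tidy CSV/JSON outputs when given an output
directory.

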