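# gammasync

Gamma-band time-frequency, phase-synchrony and decoding analysis of
perceptual-state EEG.

## The problem

When a degraded two-tone image is suddenly (or gradually) resolved into a
coherent object, EEG over occipito-parietal cortex shows increases in
gamma-band activity (here low gamma 30–45 Hz and high gamma 60–75 Hz) and
in inter-electrode phase synchrony around the moment the percept emerges.
Analyzing this requires a chain of estimators, each easy to get subtly
wrong: time-resolved spectral power and phase on a 1 Hz grid, baseline
z-normalization, all-pairs phase-locking, a connectivity measure immune to
volume conduction, multiple-comparison-corrected contrasts, and a
cross-validated decoder of perceptual state with permutation significance.
`gammasync` packages that chain for EEG researchers and methodologists,
together with a synthetic EEG generator that emulates the two paradigms
(rapid serial presentation with rare targets; 12 s rotating stimuli with
variable recognition moments) so that every stage can be validated against
known ground truth.

## What it computes

* **Time-frequency**: smoothed pseudo Wigner–Ville power of the analytic
  signal, W(t, f) = Σ_τ h(τ) r_g(t, τ) e^(−i4πfτ/sr), on a 15–90 Hz × 1 Hz
  grid, with phase from an auxiliary Gaussian-windowed complex
  decomposition; baseline z-normalization per channel and frequency
  (subtract baseline mean, divide by baseline SD), and averages over the
  four bands 15–30, 30–45, 45–60, 60–75 Hz.
* **Synchrony**: inter-trial phase-locking value
  PLV(f, t) = |mean_trials e^(i(φᵢ − φⱼ))| over all electrode pairs, and
  the imaginary part of coherency, ImCoh = Im(S_ij / √(S_ii S_jj)), whose
  insensitivity to instantaneous mixing makes it a volume-conduction-safe
  connectivity measure (with a trial-shuffle null screen built in).
* **Statistics**: per-timepoint Wilcoxon maps and band-wise paired t
  contrasts with step-down Holm correction and contiguous
  significant-window extraction; behavioural summaries, including the
  conversion of detection time to stimulus rotation angle
  (angle = min(t, 9 s) × 20°/s; 4.30 s → 86°).
* **Decoding**: linear SVM (libsvm) on channel- and band-averaged
  normalized power from occipito-parietal electrodes, 30 repetitions of
  stratified 3-fold cross-validation with per-repetition regularization
  selection; accuracy, sensitivity, specificity, balanced accuracy
  (= (sensitivity + specificity)/2), and leave-one-out label-permutation
  p-values.
* **Simulation**: 1/f^α background, von Mises phase-coupled narrow-band
  bursts (expected pair PLV = I₁(κ)/I₀(κ)), zero-lag mixing, Poisson
  blinks, and the full trial structure of both paradigms, all under
  mandatory seeds.

Recordings travel as EDF (interchange) or a lossless single-file array
container; events and behaviour as CSV; results as tibbles with
`tidy()` / `glance()` / `autoplot()` methods. `run_pipeline()` chains
simulate → preprocess → tfr → sync → stats → classify from one R or YAML
configuration and writes a hash-stamped manifest; a thin CLI wrapper lives
at `inst/scripts/gammasync-pipeline.R`.

## Worked example

Simulate a small rotating-stimulus session, summarize behaviour, and run
the full pipeline on it:

```r
library(gammasync)

cfg <- synth_config("rotation", n_channels = 8, sr = 400, n_trials = 24,
                    perceived_prob = 0.5, exact_counts = TRUE, seed = 42)
ds  <- generate_rotation_dataset(cfg)
behaviour_summary(ds$behaviour)
#> # A tibble: 1 × 5
#>   n_trials hit_rate n_perceived detection_mean detection_sd
#>      <int>    <dbl>       <int>          <dbl>        <dbl>
#> 1       24       50          12           6.15         2.73

time_to_angle(behaviour_summary(ds$behaviour)$detection_mean)
#> [1] 123.0344

run <- default_pipeline_config(tempfile("gsrun"), seed = 42)
run$simulate <- list(n_channels = 8, sr = 400, n_trials = 24,
                     perceived_prob = 0.5, exact_counts = TRUE)
run$tfr      <- list(stride = 16)
run$classify <- list(reps = 10, stride = 25)
man <- run_pipeline(run)

str(man$stages$classify)
#> List of 3
#>  $ balanced_mean: num 100
#>  $ n_excluded   : int 2
#>  $ n_trials     : int 22

read.csv(file.path(run$out_dir, "contrast_windows.csv"))
#>    band t_start t_end n_points
#> 1 60-75   -0.54 -0.50        2
#> 2 60-75   -0.34 -0.34        1
#> 3 60-75   -0.10 -0.02        3
```

Reading the numbers: 12 of 24 trials reach a percept; their mean detection
time of 6.15 s corresponds to 123° of rotation from the inverted position
(a time of 4.30 s would give 86°). The decoder separates perceived from
unperceived trials from 60–75 Hz normalized power in the final 3 s of the
movie with 100% mean balanced accuracy over 10 cross-validation
repetitions — 2 perceived trials whose response fell inside that window
were excluded first. The response-locked rank-sum map finds
Holm-corrected significant windows only in the 60–75 Hz band in the second
before the report, where the generator actually placed the perception
effect.

`autoplot()` works on the TFR, contrast, classifier-report and
connectivity objects; `export_tfr_matrix()` / `export_topography()` write
figure-ready tabular text.

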