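---
title: "Methods: time-frequency, synchrony and decoding of perceptual-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-frequency, synchrony and decoding of perceptual-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gammasync` implements an EEG analysis chain for studying gamma-band
signatures of emergent visual perception: trials in which a degraded
(two-tone) stimulus is, or is not, resolved into a coherent percept, either
in a rapid serial presentation of short-lived targets or in slowly rotating
stimuli where recognition arrives at a variable moment. This vignette is
the package's own account of the models, the tunable parameters, and the
numerical choices, so that every default can be judged rather than trusted.

## The signal model and the synthetic generator

No public recording accompanies this design, so the package ships a
generator whose output has exactly the statistical structure the analysis
assumes, with known ground truth for every effect:

* **Background**: independent per-channel noise with power spectral density
  proportional to $1/f^\alpha$ (default $\alpha = 1.2$, RMS 10 µV), made by
  spectral shaping of white Gaussian noise. Typical resting EEG shows
  $\alpha \approx 1\text{--}1.5$; channel correlations are introduced only
  through explicit mixing, keeping the noise model and volume conduction
  separable.
* **Oscillatory bursts**: narrow-band components
  $A\,w(t)\cos(2\pi f t + \phi_{\text{trial}} + \text{lag}_{\text{ch}} +
  \varepsilon_{\text{ch}})$ with a raised-cosine (Hann) envelope $w$; a
  `sustain_s` option splits the Hann into ramp–plateau–ramp for sustained
  state activity. The per-trial reference phase $\phi_{\text{trial}}$ is
  uniform; the first listed channel carries it exactly and every other
  channel adds independent von Mises$(0, \kappa)$ jitter
  $\varepsilon_{\text{ch}}$. Pairs involving the reference channel then
  have expected inter-trial phase-locking exactly
  $I_1(\kappa)/I_0(\kappa)$ — the calibration the synchrony tests rely on.
  (Giving *every* channel independent jitter would square that ratio,
  which is why the reference-channel construction is used.)
* **Volume conduction**: an instantaneous (zero-lag) square mixing matrix.
  Zero-lag mixing produces real-valued coherency, which is precisely why
  the imaginary part of coherency is computed alongside PLV.
* **Ocular artifacts**: Poisson blinks (default 0.01 Hz — participants
  watching short movies suppress blinking), ~300 ms half-sine deflections
  of 150 µV on the EOG channels, scaled on EEG channels by a configurable
  frontal decay profile. Blink times are returned as ground truth.
* **Paradigms**. Rapid serial presentation: 4.5 s trials of thirty 150 ms
  frames, exactly one target per trial at a frame onset drawn uniformly in
  1.5–3.0 s (a 1/30 target rate), an evoked gamma burst on target frames.
  Rotation: 12 s movies separated by 3 s, the stimulus rotating 180° over
  the first 9 s (20°/s); each trial is perceived with probability 2/3;
  perceived trials draw a detection latency from a truncated normal
  (mean 4.30 s, SD 2.95 s, truncated to [1, 11] s) and receive a
  60–75 Hz component (centre 68 Hz) on occipito-parietal channels that
  ramps up 0.8 s before the report and is *sustained until movie offset*.
  The sustained shape is a deliberate modelling decision: perception-state
  gamma is treated as state activity rather than a transient, so that
  response-locked windows see it rising before the report *and* the final
  3 s of the movie remains informative for decoding whatever the response
  latency. Both claims are then tested against the same generator.
* **Burst amplitude**: the rotation default (1.3 µV against 10 µV RMS
  noise) was calibrated once so that, after decomposition and baseline
  normalization against the unperceived state, the perceived-trial
  60–75 Hz band average in the final 3 s sits at ≈ +3 baseline SD. That is
  the effect size all decoding results in the test suite refer to.

What the generator does **not** emulate: biophysical forward models
(dipoles, leadfields), saccadic spike potentials, electrode drift and
impedance changes, line noise, or non-stationary background power. Passing
tests therefore demonstrate correctness of the estimators under the stated
statistical structure, not robustness to every artifact of real lab data.

## Preprocessing

Average reference uses good EEG channels only (EOG and bad channels are
neither included in the mean nor re-referenced). Filtering is a
Hamming-window FIR band-pass (defaults 1–100 Hz) with transition width 25%
of the low cutoff, applied by FFT convolution with the linear-phase delay
removed — an exactly zero-phase filter. Epochs are cut around lock events
(response, or the movie midpoint at 6 s for unperceived rotation trials;
target onsets for the rapid-presentation task), with edge-truncated epochs
dropped rather than zero-padded so that baselines are never contaminated
by padding. Amplitude screening removes trials exceeding ±75 µV on EEG /
±100 µV on EOG (the short-lived-stimulus convention) or ±100 µV on all
channels (the rotation convention); both thresholds are arguments. Ocular
correction is least-squares EOG regression — deterministic and testable,
in place of manual ICA component selection, whose subjective step cannot
be reproduced. Trial selection keeps responses in [1, 11] s and, for the
rapid task, correct categorizations. Each step appends to a provenance
attribute, and the prescribed order (re-reference → filter → epoch →
reject → correct → select) is what `run_pipeline()` executes.

## Time-frequency estimation

Power on the 15–90 Hz × 1 Hz grid comes from a smoothed pseudo
Wigner–Ville distribution of the analytic signal:

$$W(t, f) = \sum_\tau h(\tau)\; r_g(t,\tau)\; e^{-i 4 \pi f \tau / sr},
\qquad r_g(t,\tau) = \sum_s g(s)\, x(t+s+\tau)\, x^*(t+s-\tau)$$

with `h` a Hamming lag window of `round(sr/4)` samples (≈ 4 Hz frequency
smoothing) and `g` a Hamming time window of 60 ms. Numerical notes:

* The lag product doubles frequencies, so the grid must stay below
  `sr/4`; functions refuse grids above that. The desk-scale default of
  500 Hz sampling leaves 90 Hz < 125 Hz with margin.
* The 60 ms time window was chosen (over a shorter 25 ms candidate) so
  that the difference-frequency oscillation of cross-terms between
  gamma components ≥ 30 Hz apart falls outside the window's main lobe;
  measured residual at the midpoint bin of a two-tone test is ~0.2% of
  ridge energy, versus ~28% at 25 ms. Burst onsets are still localized
  well within ±100 ms.
* Quadratic distributions go negative off-ridge; negative values are
  clipped to zero and the clipped fraction is logged on the object
  (~30% of bins for pure-noise input is normal — those bins oscillate
  around zero).
* The Wigner–Ville estimate is real and carries no phase, so phase comes
  from an auxiliary complex decomposition: convolution with
  Gaussian-windowed complex exponentials of 4-cycle support per
  frequency, unit gain at the centre frequency. Its angle feeds PLV and
  coherency; its squared magnitude is *not* used for power.

Baseline z-normalization subtracts the baseline mean and divides by the
baseline SD of the *across-trial average* power, per channel and frequency
— so the normalized across-trial average has exactly mean 0, SD 1 in the
baseline. Two baseline conventions are built in: a pre-stimulus window
(rapid task), and a reference-condition baseline where the unperceived
trials' statistics normalize everything (rotation task) — the latter is
also what the decoder uses, mirroring normalization "to the no-perception
state". Whether to subtract the ERP before decomposition ("induced-only")
is a flag, default off, since the evidence for either reading is
ambiguous; both modes are tested.

## Synchrony

PLV is the magnitude of the across-trial mean unit phasor of the phase
difference, per channel pair, frequency and time. Its null level under
independent phases is $\sqrt{\pi/4N}$, which the tests verify at several
trial counts. Coherency is estimated across trials at each time-frequency
bin (not by Welch averaging over time), so ImCoh inherits the TFR's time
resolution; bins with zero power are propagated as missing and excluded
from summaries with counts logged. The volume-conduction screen compares
band-averaged |ImCoh| against the 95th percentile of a trial-shuffle null;
zero-lag mixed sources must stay below it (checked at the 93% level to
allow for estimator noise), while a quarter-cycle lag flips the verdict.
Per-channel summaries average |ImCoh| over a declared window and band and
export full symmetric matrices for topographic (head-in-head style)
plotting.

## Statistics

Per-timepoint contrasts use Wilcoxon tests (signed-rank when paired,
rank-sum otherwise; exact p for n ≤ 25 without ties, continuity-corrected
normal approximation otherwise, with a hand-computed z statistic), with
step-down Holm correction within band and contiguous significant windows
extracted in seconds. Fully tied cells (no evidence) score z = 0, p = 1
rather than aborting a whole map. Band-level contrasts average a declared
window — "the second before the report" is read literally as [−1, 0] s —
and run paired t-tests per band, Holm-corrected over the four-band family;
the t statistic carries the sign of (first argument − second), so passing
the no-perception condition first yields negative t when perception power
is higher. The four 15 Hz bands are half-open [lo, hi), so each 1 Hz bin
belongs to exactly one band. The family for Holm correction is
configurable; the four-band family is the default and the per-timepoint
maps correct over time points within band.

The family-wise-error calibration test simulates the four-band null with a
shared across-band variance component (r ≈ 0.5) because band averages of
one recording share background power — independent bands would be a less
faithful null and the conclusion does not depend on it.

## Decoding

Features are normalized power averaged over the occipito-parietal roster
(C1/Z/2, CP1/3/Z/2/4, P1/Z/4, PO9/7/5/3/Z/4/6/8/10, O1/Z/2, intersected
with the montage) and over the band's frequency bins, retaining the time
points of the final 3 s of the movie (a `collapse_time` switch produces
one scalar per band instead; retaining time is the default because
temporal patterns carry information). Perceived trials whose response
falls inside the feature window are excluded to keep motor activity out.
The classifier is a linear maximum-margin SVM (libsvm via e1071).
Evaluation: 30 repetitions of stratified 3-fold cross-validation with
random fold assignment; within each repetition the regularization constant
is selected from a log grid 10⁻³…10³ by pooled balanced accuracy, and the
pooled confusion matrix yields accuracy, sensitivity (perceived recall),
specificity and balanced accuracy, reported as mean ± SD over repetitions.
Feature standardization is fitted on training folds only (libsvm's
internal scaling), verified by a leakage canary. Class imbalance is
handled by stratification alone, no reweighting.

Significance uses label permutation with leave-one-out scoring for both
the observed and permuted statistics. Two p-values are reported: the
plug-in `(1 + #{perm ≥ obs}) / (1 + N)`, and a randomized tie-broken
version. Leave-one-out accuracy is coarse (n + 1 possible values), so
permuted scores tie with the observed one often and the plug-in estimator
is conservative (super-uniform) — valid but not uniform; the randomized
version is exactly uniform under the null, and it is the one whose
calibration the test suite verifies by Kolmogorov–Smirnov across 200 null
simulations.

Subjects enter decoding only with ≥ 10 unperceived trials, keeping
held-out folds honest under imbalance.

## Pipeline, problem sizes and determinism

`run_pipeline()` chains simulate → preprocess → tfr → sync → stats →
classify from one configuration (R list or YAML), writes each stage's
outputs (lossless single-file array containers plus CSV/TSV tables), and
records a manifest with the configuration snapshot, per-stage counts and
MD5 hashes of every output; identical configurations reproduce identical
hashes. Seeds are mandatory — there is no implicit global randomness; all
generator and cross-validation seeds derive from the configuration.

Default problem sizes are desk scale by design: 16 + 2 channels at 500 Hz,
90 rotation trials, TFR stride 10–20 (power varies on the 60 ms smoothing
scale, so a 25–50 Hz feature rate loses nothing), 30 CV repetitions. The
suite's heavier checks (the end-to-end decoding run, the PLV/Bessel
calibration, the permutation-uniformity simulation) each complete in a few
minutes on one core. Lab-scale settings (2000 Hz, 64/128 channels) are
configuration changes, not code changes; every analysis is sampling-rate
agnostic below the `sr/4` grid limit.

## Known limitations

* EDF export quantizes to 16 bits per channel range and pads to whole
  1-second records; the native container is the lossless path.
* The 128-channel montage is a best-effort interpolated standard layout —
  no channel list is published for such caps — and is labelled accordingly.
* ImCoh is blind to genuinely zero-lag neural coupling by construction;
  it trades that sensitivity for immunity to volume conduction.
* The regression-based ocular correction removes only the EOG-linear
  component of artifacts; saccadic spike potentials with poor EOG
  projection survive it.
* Decoding results on the generator quantify estimator and harness
  correctness at a stated effect size; they are not evidence about any
  particular real dataset.
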