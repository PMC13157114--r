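---
title: "Methods: signal models, scoring rules, and inference in stressvep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal models, scoring rules, and inference in stressvep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressvep)
```

`stressvep` implements the complete measurement chain of an acute-stress
psychophysiology experiment in which socially anxious participants, after a
psychosocial stressor or a placebo control, complete (a) an attentional
threat-bias task with two emotional faces flickering at 12 and 15 Hz in the
left and right hemifields, and (b) a passive face-viewing task, while EEG,
electrodermal activity, heart rate, saliva samples, and affective ratings
are recorded. Every stage is paired with a synthetic-data generator that
produces inputs with known ground truth, so the full pipeline is testable
without any recordings.

# The measurement models

## Frequency-tagged ssVEP and attentional bias

Each flickering stimulus drives a steady-state visual evoked potential
(ssVEP) at its own flicker frequency, projected predominantly to the
contralateral posterior scalp. Attention to a stimulus scales its tagged
amplitude. Amplitudes are estimated with complex Morlet wavelets
(`morlet_amplitude()`), using `cycles = freq/2` and an amplitude
normalization fixed so that a stationary unit-amplitude sinusoid at an
analysis frequency yields an envelope of 1.0 away from edges; this makes
amplitudes comparable across frequencies despite the frequency-dependent
cycle count. The default analysis set is ten log-spaced frequencies over
1-40 Hz with the two tag frequencies appended explicitly, because the log
grid does not land on them and all downstream scores are defined at the
tags.

Per trial, each stimulus is read out at *its own* tag frequency, averaged
over the occipital/parieto-occipital cluster (O1, O2, Oz, PO7, PO8, P9,
P10) and a time window (100-500, 500-1000, 1000-2000, 2000-3000, and the
global 100-3000 ms). Cell means over trials feed the attentional bias
score

$$\mathrm{ABS} = \frac{A_\text{high} - A_\text{low}}{A_\text{high} + A_\text{low}},$$

which lies in $[-1, 1]$, is antisymmetric under swapping the pair, and is
positive when the higher-arousal face captures more attention. An
alternative reading that sums the envelope over both tags is available
behind `sum_tags = TRUE`, but it is off by default: summed over both tags
the two stimuli are no longer separable, which is the entire point of
frequency tagging.

**Cross-tag leakage.** With `cycles = freq/2` the wavelet at either tag has
a spectral standard deviation of 2 Hz, so the 12 Hz estimate receives the
15 Hz tone with Gaussian gain $e^{-9/8} \approx 0.32$ and vice versa. This
compresses bias scores toward zero (an injected amplitude ratio of 1.5
yields an expected ABS of about 0.155 rather than the leakage-free 0.2).
The package treats this as a property of the prescribed estimator, not an
error: recovery tests assert the leakage-corrected expectations, derived
in the test suite from the Gaussian spectral gain plus averaging of the
two tones' beat phase over the analysis window.

## ERP components

P1 (80-120 ms at O1/O2/PO7/PO8/P9/P10), N170 (130-200 ms at
PO7/PO8/P9/P10), EPN (240-300 ms at P7/P8/PO7/PO8/P9/P10), and LPP
(400-1000 ms at midline Cz/CPz/Pz/POz) are scored as the mean voltage in
the window over the (hemisphere-side) cluster, on unrejected trials of the
cell. Lateral clusters are split by the 10-20 label convention (odd = left,
even = right; z = midline, excluded from splits). Because a strong P1
biases the absolute N170, a peak-to-peak P1-N170 measure is also provided:
on the cell-averaged cluster waveform, the N170 trough (minimum in
130-200 ms) minus the P1 peak (maximum in 80-120 ms). The sign convention
is trough minus peak, so more negative means a larger N170; the measure is
invariant under adding a constant to the waveform. Peaks are found on
cell-averaged waveforms, not per trial, the standard and more robust
choice at usual trial counts.

## Frontal alpha ERD

Alpha power is the squared Morlet envelope averaged over 8-13 Hz (integer
frequencies) and the frontopolar channels Fp1/Fpz/Fp2, using the same
normalized wavelet engine as the ssVEP stage — one spectral engine, one
normalization. Per trial, ERD is the log10 power in the 200-2800 ms
stimulus window minus the log10 power in the -200-0 ms baseline; the
participant value is the trial mean (single-trial/"induced" by default,
with `evoked = TRUE` computing power on the trial average instead).
Negative values are desynchronization. For a pure envelope gain $g$
applied to the alpha oscillation, ERD equals $2\log_{10} g$ exactly, which
is the closed form the tests check at $g \in \{0.25, 0.5, 1, 2\}$.

The 200/2800 ms margins keep one wavelet half-width clear of the epoch
edges for the stimulus window, but the 200 ms baseline has no such margin:
the pipeline therefore epochs 500 ms wider (from -700 ms) for the ERD
stage and the 8 Hz wavelet (half width about 280 ms) then sees no edge in
the baseline window.

## Skin conductance, heart rate, saliva, ratings

Electrodermal traces are band-passed 0.01-5 Hz and scored trough-to-peak:
the valley is the minimum 1000-4000 ms after onset, the peak the maximum
1500-7500 ms *after the valley*, ties resolved to the earliest sample.
A response is valid only if the trace covers 7500 ms post onset
(otherwise `short_trial`), a peak exists after the valley, and the
amplitude is at least 0.02 uS — the boundary is inclusive, since responses
*below* 0.02 uS are excluded. Participants enter condition-level analyses
only with at least five valid responses in every condition. Exclusions
are data (reason codes), never exceptions.

Heart rate is derived from RR intervals: instantaneous HR = 60000/RR at
each beat time, linearly interpolated onto a 10 Hz grid (the input is a
beat series; some uniform grid is needed, and linear interpolation of
instantaneous HR is the simplest defensible choice), averaged in the
0-1000 (deceleration), 1000-3000 (acceleration), 3000-7500 (recovery) and
0-7500 ms windows, minus the -1000-0 ms baseline mean.

Saliva series carry six samples labelled t-30, t-pre, t+00, t+15, t+30,
t+50; numeric times come from the labels with "t-pre" mapped to -5 min
(configurable — it has no number of its own). AUCg is the trapezoidal
integral of all six samples; AUCi integrates samples 2-6 and subtracts the
second sample (the pre-stressor baseline) times the spanned time, making
it invariant to adding a constant. Using the second sample as the AUCi
baseline follows its definition "from the second to the sixth timepoint";
the first-sample alternative sits behind `baseline_sample = 1`.

# Preprocessing

The chain is band-pass (0.01-40 Hz) → 50 Hz notch → optional channel
interpolation → artifact-decomposition hook → epoching (-200..3000 ms) →
average reference → baseline correction (-200..0 ms) → ±150 uV rejection,
and the applied order is recorded on the output. Choices worth stating:

* **Filters.** Zero-phase filtering is implemented as a Butterworth
  *magnitude* response applied in the frequency domain on a periodic even
  extension of the signal, padded to a 2-3-5-smooth FFT length. A
  conventional forward-backward IIR implementation is numerically
  unusable for a 0.01 Hz edge at 512 Hz (the poles sit within 1e-4 of the
  unit circle). The gain contract is what matters and is tested: unity
  (±1%) in the passband, ≥ 20 dB one octave beyond an edge, > 90%
  suppression at the notch frequency.
* **Rejection** reads "exceeding 150 uV" as absolute amplitude on any EEG
  channel (±150 uV), the common convention; it is monotone in the
  threshold. Whether rejection runs before or after re-referencing is not
  dictated by the data; the pipeline re-references first and documents the
  order, and both stages are pure functions so the alternative order is a
  one-line change.
* **Epoching** uses `round(t * fs / 1000)` sample indices with inclusive
  endpoints, so -200..3000 ms at 512 Hz is exactly 1639 samples. Events
  too close to a recording edge are kept but flagged (`reason = "edge"`),
  never silently dropped.
* **Interpolation** replaces a bad channel by the inverse-distance-weighted
  mean of its four nearest neighbours on an idealized unit-sphere 10-20
  layout. Spherical-spline interpolation would need digitized electrode
  positions that do not exist here; neighbour averaging is exact for
  locally identical signals, which is the testable contract.
* **ICA** is a no-op hook (`ica_hook`): component-based artifact removal
  requires human or classifier judgment, and the synthetic recordings
  carry no ocular or muscle artifacts. The hook marks where it belongs in
  a real-data pipeline.

# Inference

`ttest_ind()` is the pooled-variance two-sample t-test with
`df = n1 + n2 - 2` and a central-t confidence interval, computable from
summary statistics alone so printed group tables can be checked directly.

`mixed_rmanova()` fits the split-plot design with one between-subjects
factor and up to two within-subjects factors by explicit sums-of-squares
partitioning: each within family (main effect and its group interaction)
is tested against its own participant-interaction stratum. Its F values
are validated to 1e-9 against an independent projection oracle
(`aov()` error strata) on enumerated fixtures. Greenhouse-Geisser epsilon
is computed per within family from the pooled within-group covariance of
orthonormalized contrast scores, $\varepsilon = \mathrm{tr}(M)^2 / (k\,
\mathrm{tr}(M^2))$; it is exactly 1 for two-level families and is checked
against `car::Anova` on nonspherical fixtures. Reported p values always
use the epsilon-corrected (fractional) degrees of freedom — for
$k \ge 3$ this is the correction "applied when sphericity is violated"
operationalized without a Mauchly pre-test, matching how fractional dfs
are conventionally reported; for $k = 2$ it coincides with the uncorrected
test. Unbalanced data raise an explicit error naming the offending cell;
nothing is imputed. Partial eta squared is
$SS_\text{effect} / (SS_\text{effect} + SS_\text{error})$ with the
effect's own error stratum, and is invariant to affine rescaling of the
response. Post hoc contrasts are paired (within factors) or
pooled-variance independent (between factors) t-tests on cell means,
Bonferroni-adjusted over the family actually computed.

# The synthetic generator

`sim_config()` fixes the study conditions: 40 participants per group,
512 Hz EEG, 12/15 Hz tags counterbalanced over hemifield and frequency
assignment (96 trials per emotion combination, divisible by four so the
counterbalancing is exact), 3000 ms trials with 4500-5500 ms intervals, a
passive-viewing task of 32 trials per expression, and six-sample saliva
series. The generator emulates:

* **ssVEP structure:** each stimulus is a pure sinusoid at its tag,
  projected with weight 1 to contralateral posterior channels, 0.4
  ipsilateral (a single scalar rather than a head model, keeping recovery
  closed-form), and their mean at the posterior midline.
* **Group effects as parameter offsets** (free parameters, not empirical
  claims): a left-hemifield gain `1 + hemifield_bias` on the left stimulus
  in the stress group only; a global ERP attenuation (`erp_group_gain`,
  stress 0.85); and a weaker alpha desynchronization gain in the stress
  group (0.75 vs 0.55).
* **Between-participant heterogeneity:** log-normal participant-by-cell
  gains on the left stimulus (`cell_gain_sd = 1.0`) dominate the spread of
  bias scores; with `hemifield_bias = 0.35` the stress group's global
  cells average about ±0.15 with SD ≈ 0.41, matching the magnitude and
  spread of the printed cell statistics, and the group × hemifield
  interaction is recovered in 85-92% of simulated studies at n = 40 per
  group — the calibrated-power condition the recovery suite checks.
* **ERP templates** are cosine-tapered plateau bumps (flat top, cosine
  ramps), not Gaussians: the plateau spans each component's scoring window
  so that the windowed mean, the windowed peak, and the injected amplitude
  parameter coincide, and the ramps reach zero before the neighbouring
  component's window. A Gaussian wide enough to be flat over its window
  necessarily leaks into the adjacent window, making "recover the injected
  amplitude" ill-defined.
* **Alpha ERD** multiplies a stationary 10 Hz oscillation's envelope by
  the participant's gain from 150 ms after onset (configurable). The
  150 ms onset matters: a step exactly at 0 ms smears backwards through
  the 8 Hz wavelet into the -200..0 ms baseline and biases the ERD closed
  form by more than the test band; desynchronization starting ~150 ms
  post-stimulus is also the physiologically sensible shape.
* **Autonomic and endocrine signals:** bi-exponential SCRs
  (rise 0.75 s, decay 6 s, onset latency 1.8 s, per-condition amplitudes,
  75% response probability), RR series with event-locked deceleration then
  acceleration, declining cortisol and stressor-peaked alpha-amylase
  trajectories, and ratings drawn around the printed per-group,
  per-expression means and SDs on the 0-1 slider scale.
* **1/f background noise** via spectral shaping of white noise
  (exponent 1, SD 2 uV).

The viewing-task inter-trial interval is not dictated by the protocol and
is a parameter; its default (4400-5400 ms) leaves a minority of trials
with onset spacing under 7500 ms, which the SCR scorer excludes as short
trials — mirroring the nonzero short-trial exclusion rate such timing
produces in practice.

Two *study-scale* simulators (`simulate_bias_experiment()`,
`simulate_erp_experiment()`) run the identical generative amplitude model
(shared code path) for 80 participants but skip waveform synthesis, since
the quantity under test — the distribution of cell scores — is determined
at the amplitude level. Waveform-level and amplitude-level paths are
reconciled on small sessions in the test suite.

What the generator does *not* emulate: ocular/muscle artifacts (hence no
ICA), volume-conduction head models, non-stationary alpha dynamics,
overlapping-response deconvolution for SCR (consecutive responses 8 s
apart overlap, which bounds session-level trough-to-peak recovery at about
0.03-0.06 uS — the tests quantify this separately from measurement-noise
recovery), and saliva assay error structure. Passing tests therefore
demonstrate correctness of the scoring chain under the assumed signal
models, not robustness to every artifact of real recordings.

# Problem sizes and reproducibility

Unit and recovery tests run on deliberately small sessions (1-4 trials per
cell, one or two participants per group) where ground truth is exact;
study-scale properties (recovery power, type-I error of the
Greenhouse-Geisser test, permutation level checks) use the full n = 40 per
group at the amplitude level with 100-600 replicates. All randomness flows
from explicit integer seeds; a session's seed is a deterministic function
of the config seed, participant index, and group, so identical calls are
bit-identical. `scripts/acceptance.R` recomputes the package's headline
quantities from scratch for any seed.

# Known limitations

* The split-plot ANOVA supports at most one between- and two
  within-subject factors (the maximal design used here) and requires
  complete data; there is no mixed-model fallback for missing cells.
* Greenhouse-Geisser correction is mildly conservative near sphericity;
  no Huynh-Feldt alternative is provided.
* The ssVEP stage quantifies, but does not undo, cross-tag wavelet
  leakage; a narrower-band estimator would trade temporal resolution
  within the 100-500 ms window.
* EDF/BDF ingestion is out of scope; continuous data enter as in-memory
  matrices or the package's own TSV serialization.
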