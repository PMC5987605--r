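---
title: "Simulating and analyzing the rapid N400 brain vital sign: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing the rapid N400 brain vital sign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem rn400 addresses

The N400 is a negative scalp potential peaking roughly 400 ms after a
semantically incongruent word: hearing *doctor–egg* produces a larger
parietal negativity than *doctor–nurse*. Rapid-assessment ("brain vital
sign") protocols elicit it in about five minutes with a compressed auditory
sequence — 60 blocks, each holding five tones followed by a prime–target
word pair, half the targets congruent and half incongruent (30 trials per
condition). Clinical translation needs a pipeline that takes such a
recording from raw multichannel data to group statistics and an
individual-level decision, and that pipeline must be testable without any
patient data.

`rn400` therefore couples a fully parameterized synthetic M/EEG generator
with the complete sensor-level analysis chain: filtering and downsampling,
recursive-least-squares (RLS) ocular artifact removal, epoching and
conditional averaging, global field power (GFP) with a sign-flip permutation
interval test, Morlet time–frequency maps with a permutation T statistic,
and a radial-kernel SVM that separates congruent from incongruent
trial-averaged waveforms subject by subject. Because every recording is
synthesized from a known ground truth, every stage of the analysis can be
verified against the signal that was actually injected.

## The signal model

Each synthetic subject is a channels × samples recording at 1200 Hz with
EEG (Fz, Cz, Pz), EOG (heog, veog) and 32 MEG-like channels, built as an
exact superposition of four components. Each component draws from its own
sub-seed of the subject seed, so disabling one leaves the others
bit-identical — the superposition and ground-truth bookkeeping are testable
invariants, not aspirations.

**Evoked responses.** Every word target adds a per-condition template at its
onset: both conditions share an auditory N1–P2 complex, and incongruent
targets additionally carry the N400 differential — a Gaussian-windowed
negativity with 420 ms peak latency, 120 ms FWHM, and amplitudes −4.0 µV at
Pz, −3.2 µV at Cz, −2.0 µV at Fz. The incongruent-minus-congruent
difference therefore equals the differential template exactly. Latency and
parietal maximum are literature-anchored; the amplitudes are generator
design values chosen to give group effects of realistic ERP magnitude.
Tones and primes add small generic responses for sequence fidelity; they are
identical across conditions and cancel in every differential measure.

**Induced beta dynamics.** An ongoing beta oscillation (20 Hz, 2 µV
equivalent amplitude) is synthesized as narrowband-filtered noise, so it has
random phase and leaves no trace in trial averages. Inside 335–440 ms after
each *incongruent* target its amplitude is multiplied by 0.5 — an induced
desynchronization visible only in power, the signature the time–frequency
branch must recover. A property test confirms the averages of the two
conditions stay statistically indistinguishable when only this effect is
enabled.

**Ocular artifacts.** Blinks are Poisson events (8/min) on the vertical EOG:
biphasic transients of 150 µV that leak into the EEG with coefficients 0.25
(Fz), 0.12 (Cz), 0.05 (Pz); saccade-like transients on the horizontal EOG
leak at 0.4 × those values. This is exactly the structure the RLS canceller
assumes — reference channels that observe the artifact plus their own noise.

**Background noise.** Independent per channel: spectrally shaped white noise
with power ∝ 1/f (flattened below 0.5 Hz), 10 µV SD on EEG/EOG and 30 fT on
MEG-like channels. MEG-like sensors observe the same evoked-plus-beta
sources through a seeded random nonnegative 32 × 3 mixing matrix at
20 fT/µV; no realistic forward model is attempted — the sensors exist to
exercise GFP and the spectral statistics across a sensor array.

**Cohorts.** A cohort draws per-subject modulations from the baseline:
template amplitudes scaled by a common factor uniform in ±20 %, latencies
shifted uniformly within ±20 ms, with independent event sequences and
sub-seeds per subject. Block timing (tones at 0.6 s spacing, prime at 3.3 s,
target at 4.3 s in 5 s blocks) reproduces the five-minute total; the tone
deviant probability of 0.2 is a placeholder, as no ratio is established for
the paradigm.

## The analysis chain

Preprocessing downsamples to 300 Hz (anti-aliased), notches the 60 Hz line
frequency and its harmonics below Nyquist, low-passes at 100 Hz, and then
cleans each EEG channel by RLS against both EOG channels jointly: 3 FIR
taps per reference (6 weights), forgetting factor λ = 0.9999,
P₀ = δ⁻¹I with δ = 0.01. The cleaned output is the prediction error
e_n = d_n − hᵀr_n of the standard RLS recursion; adaptation runs once over
the continuous recording and is never reset. At λ = 1 the recursion solves
the δ-regularized least-squares problem exactly, which the tests verify
against a direct normal-equations oracle.

All filters are applied forward–backward (zero phase) so latencies survive
filtering; band-passes are realized as 4th-order Butterworth high-pass +
low-pass cascades, which remain numerically stable at a 0.5 Hz edge where a
single order-8 band-pass polynomial is fragile. Inputs are extended by
reflection (up to 3 s) before filtering to suppress edge transients.

Two branches then run from the same cleaned recording:

* **ERP branch (EEG)** — 1–10 Hz, epochs −200…900 ms around word targets,
  −100…0 ms baseline, conditional averages. Group statistics: paired t test
  on per-subject 300–500 ms window means at Cz, and peak characterization of
  the grand-average difference — the global extremum over channels × time
  within 300–500 ms defines at once the scalp maximum, the peak latency and
  the peak amplitude, the classical ERP peak measurement (window-mean
  amplitudes per site are reported alongside).
* **Broadband branch (MEG-like)** — 0.5–45 Hz, same epoching; GFP
  (spatial SD across sensors) per condition and subject; a pointwise paired
  T statistic across subjects with a sign-flip permutation null (1000
  draws) finds the significant interval, keeping only runs of at least
  30 ms to suppress isolated false positives. The Morlet branch convolves
  each trial with unit-energy 6-cycle complex wavelets on a 1–45 Hz grid,
  takes log₁₀|W|² (floored at 10⁻²⁰ to keep silent epochs finite),
  subtracts the per-trial baseline mean per frequency, averages log power
  across channels and then across trials, and compares conditions with the
  same sign-flip permutation engine over 0–800 ms.

A 6-cycle wavelet at 0.5 Hz would need ~12 s of support — an order of
magnitude more than the 1.1 s epoch — so the wavelet grid starts at 1 Hz
even though the broadband filter passes 0.5 Hz; samples within one wavelet
σ_t of the epoch edge are flagged, not dropped. Log power is averaged over
channels after per-channel decomposition and baseline subtraction; the
order is configurable. The beta band is taken as 13–30 Hz throughout.

## Individual-level classification

Rows of the feature matrix are trial-averaged waveforms per subject per
condition — the 331 epoch samples at each of Fz, Cz, Pz concatenated (993
features, 30 rows for 15 subjects). Classification uses a radial-kernel SVM
under ten repeats of stratified tenfold cross-validation, fold assignments
re-randomized per repeat; feature standardization is fitted on each training
fold only. Confusion counts are pooled over all repeats, and accuracy,
sensitivity (incongruent = positive) and specificity come from the pooled
table. Significance is assessed by relabeling: class labels are shuffled
across the whole matrix, the CV rerun, and the p-value is
(1 + #{null ≥ observed}) / (1 + n_perm) over 1000 shuffles — the add-one
estimator never returns zero.

The SVM hyperparameters deserve a note, because nothing in the protocol
fixes them. With 30 rows and 993 columns the problem sits deep in the
n ≪ p regime, where the textbook RBF default (C = 1,
γ = 1/(n_features · Var(X))) underfits badly: on synthetic cohorts it
loses 15+ accuracy points to the same kernel with stronger fitting
capacity. We therefore ran an inner cross-validated grid search
(C ∈ 10⁰…10³ crossed with γ ∈ γ₀·{0.01, 0.03, 0.1, 1}, γ₀ the variance
formula above) and fixed the package defaults at its modal selection:
**C = 100, γ = γ₀/30**. Full nested selection inside every outer fold is
methodologically cleaner but measurably worse here — with 27-row training
folds the inner estimates are noisy enough that selection variability costs
several accuracy points — so the defaults are fixed and documented, and
both parameters remain arguments. The permutation null reruns the CV with
single-repeat tenfold folds by default (the null accuracy distribution is
invariant in expectation to the repeat count); the identical 10 × 10
procedure is available via `repeats`.

## Numerical and procedural choices

* **Seeds.** Every stochastic stage consumes a sub-seed derived
  deterministically from a master seed; reports embed the seeds, and
  rerunning a configuration is bit-identical. Cohort synthesis and analysis
  randomness (folds, permutation draws) can be seeded independently.
* **Sign-flip engine.** Paired tests across subjects build their null by
  randomly negating each subject's whole difference series (fresh draws per
  permutation, not exhaustive enumeration). Since sign flips leave the sum
  of squares invariant, null T values follow from flipped means alone,
  which makes thousand-draw nulls over hundreds of Monte-Carlo cohorts
  cheap. Pointwise p is the plain exceedance fraction; zero-variance points
  with zero mean report T = 0, p = 1 rather than 0/0.
* **Type-I calibration.** The pointwise rejection rate of both permutation
  tests is audited at α = 0.05 on Gaussian null cohorts supplied directly
  at the GFP/TFR-summary level (500 and 200 cohorts respectively, 15
  subjects each). Calibration depends only on the paired input
  distribution, so auditing at this level tests the same property as full
  raw-signal synthesis at a small fraction of the cost; the full signal
  path is exercised separately by the cohort-level tests.
* **Degenerate inputs.** Paired tests with zero-variance differences report
  a degenerate flag instead of an infinite t; empty epochs, windows outside
  bounds, cutoffs at or above Nyquist, upsampling requests, and double
  baseline correction all fail fast with named errors. Epochs that would
  cross recording bounds are dropped and counted, never zero-padded.
* **EDF I/O.** Recordings serialize to 16-bit EDF with one-second records;
  per-channel physical ranges are symmetric and cover the data, bounding
  round-trip error by range/2¹⁶. Channel kind travels in the conventional
  label prefix ("EEG Fz", "EOG veog"); the true sample count rides in the
  reserved header field so a padded final record trims away on read.
  Header timestamps are fixed so identical recordings serialize
  byte-identically.
* **Problem sizes in the tests.** The test suite runs the full default
  15-subject cohort once and shares it; Monte-Carlo properties use 50 seeds
  (averaging laws, induced-effect isolation) and 20 seeds (RLS mixture
  recovery); calibration suites use 500/200 summary-level cohorts with
  1000-draw nulls. These sizes give the audited proportions standard errors
  well inside the asserted bands.

## What the synthetic cohort does and does not show

The generator reproduces the statistical structure the analysis assumes:
phase-locked evoked differences, induced band-limited power changes,
reference-observable ocular artifacts, 1/f background, realistic trial
counts and session length. It deliberately omits much that real data
contains: no true head geometry or forward model (MEG mixing is random and
nonnegative), no heteroscedastic or non-stationary noise, no muscle or
movement artifacts, no lexical content or item-level variability, no
latency jitter across trials within a subject, and between-subject
variability reduced to amplitude/latency jitter. Passing tests therefore
demonstrate that the pipeline recovers known effects under its own model
assumptions — correctness of the machinery, not clinical validity on real
recordings. Effect sizes are design choices; the classification accuracies
the synthetic cohort supports depend on them directly and should be read as
verification targets, not performance claims about patients.

## Known limitations

* The significant-interval rule (pointwise α with a 30 ms minimum run) is a
  run-length heuristic, not a cluster-mass or max-T correction; documented
  alternatives are out of scope.
* The Morlet grid's 1 Hz floor means slow (< 1 Hz) dynamics are only ever
  treated by the broadband filter, never resolved spectrally.
* RLS assumes artifact propagation is linear and quasi-stationary at the
  3-tap scale; slow drifts in mixing are tracked by the forgetting factor
  but rapid nonlinear coupling is not modeled.
* With 30 rows, pooled cross-validated metrics are quantized in steps of
  1/300 and fold-seed sensitivity of a point or two is expected; the
  permutation p-value, not the raw accuracy, carries the inferential
  weight.
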