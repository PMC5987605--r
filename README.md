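# rn400 — rapid-N400 brain vital sign simulation and sensor-level analysis

The N400 is a negative event-related potential (ERP) peaking ~400 ms after a
semantically incongruent word (*doctor–egg* vs *doctor–nurse*), maximal over
parietal scalp. Rapid "brain vital sign" protocols elicit it in about five
minutes with a compressed auditory sequence of 60 blocks — five tones plus a
prime–target word pair per block, 30 congruent and 30 incongruent targets —
so that semantic processing can be monitored at the bedside.

`rn400` implements the full sensor-level analysis chain for this paradigm,
driven by a synthetic M/EEG cohort generator so every stage is verifiable
without recorded data:

* **Synthesis** — event sequences; Gaussian-windowed evoked templates (N400
  differential: 420 ms peak, Pz-maximal); induced beta desynchronization
  (13–30 Hz power drop at 335–440 ms in incongruent trials); Poisson blink
  artifacts leaking into frontal EEG; 1/f background noise; MEG-like sensors
  via random nonnegative source mixing; exact ground-truth bookkeeping.
* **Preprocessing** — zero-phase notch/low-pass/band-pass filtering,
  anti-aliased downsampling (1200 → 300 Hz), epoching (−200…900 ms),
  baseline correction, conditional averaging.
* **Artifact removal** — recursive least squares (RLS) adaptive cancellation
  of ocular activity using both EOG channels jointly (m = 3 taps per
  reference, λ = 0.9999), applied to the continuous recording.
* **Sensor statistics** — global field power GFP(t) = spatial SD across
  sensors; paired sign-flip permutation T tests, pointwise with a 30 ms
  minimum-run rule for the significant interval; window-mean paired t tests
  (300–500 ms).
* **Time–frequency** — 6-cycle complex Morlet wavelets (1–45 Hz),
  log₁₀|W|² power, per-trial baseline subtraction (−100…0 ms), permutation
  T map over 0–800 ms.
* **Classification** — radial-kernel SVM on concatenated Fz/Cz/Pz
  trial-averaged waveforms, 10 × stratified tenfold cross-validation with
  pooled confusion counts, and a 1000-draw label-permutation null.

## Worked example

```r
library(rn400)

# one synthetic subject: 60 blocks, ~5 minutes at 1200 Hz
events <- generate_event_sequence(sequence_config(), seed = 1)
table(events$kind)
#>    tone_dev    tone_std  word_prime word_target
#>          60         240          60          60

rec <- synthesize_subject(subject_params(), events, seed = 2)
rec
#> <continuous_recording> 37 channels x 361200 samples @ 1200 Hz (301.0 s)
#>   channels: eeg=3, eog=2, meg=32
#>   ground truth attached (seed 2 )

# preprocess + ERP branch
cfg <- pipeline_config()
clean <- preprocess_subject(rec, cfg)          # 300 Hz, notched, RLS-cleaned
erp <- eeg_branch_subject(clean, events, cfg)  # 1-10 Hz conditional averages
diff <- evoked_difference(erp$incongruent, erp$congruent)
peak_characterization(diff)
#> $channel    "Pz"
#> $latency_ms 416.6667
#> $amplitude  -3.426155
```

The full study-level run is one call:

```r
report <- run_pipeline(pipeline_config())  # default: 15 subjects, seed 7
report
#> <pipeline_report>
#>   ERP: peak latency 420.0 ms at Pz; window effect -1.37 uV (p = 0.004651)
#>   GFP: significant interval 323.333..510 ms; window test p = 1.032e-10
#>   TFR: significant beta decrease 316.667..500 ms
#>   Classification: accuracy 90.33%, sensitivity 0.933, specificity 0.873 (p = 0.004975)
```

The single-subject peak sits within one 300 Hz sample of the injected
420 ms ground truth; the 15-subject grand average recovers 420 ms exactly,
parietally maximal. The detected GFP interval brackets the injected 300–500
ms effect, and the beta-power decrease overlaps its 335–440 ms ground
truth. Specificity sits a few points under sensitivity because the
incongruent class carries the amplitude-jittered differential and is
therefore the wider class.

`report$features` collects the rapid-N400 feature checklist (peak latency,
scalp maximum, window-mean effect, GFP interval, beta decrease,
classification block); `write_report_json()` serializes it with full seed
provenance. A thin CLI over the same functions lives at
`inst/cli/rn400.R` (`simulate` and `run` verbs).

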