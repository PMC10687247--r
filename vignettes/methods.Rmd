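---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

After a tracheostomy, the tube can obstruct at any time: sputum (a movable
obstacle) calls for suctioning, while crusts or blood clots (fixed obstacles)
may require changing the tube or its inner cannula. Breathing sounds recorded
at the tube opening distinguish these states. This package implements a
three-category acoustic taxonomy and the full analysis pipeline around it:

* **NS** (normal): low acoustic energy, concentrated at roughly
  1500–2000 Hz; nothing notable at high frequency.
* **VS** (vibrant): a movable obstacle chops the airflow, producing amplitude
  bursts repeating on the order of 100 per second over a broadband
  (500–12,000 Hz) excitation — *vertical lines* in a spectrogram.
* **SS** (sharp): a fixed narrowing excites sustained high-frequency
  resonances above 2000 Hz — *horizontal lines* in a spectrogram.

Cycles showing **both** patterns are labelled **VS**: a mixed movable + fixed
obstruction is treated as suctionable first, since suction is faster, safer,
and available to caregivers, and may resolve the fixed component too.

The clinical recordings behind this taxonomy are not publicly deposited, so
the package is built around a synthetic-data generator that emulates the
documented acoustics, and every claim a test makes is relative to that stated
world (see "What a green test establishes", below).

# The synthetic generator

`generator_params()` encodes the stated world:

* Per-class cycle durations (s, mean ± SD): NS 3.801 ± 1.592, VS
  3.033 ± 0.949, SS 3.876 ± 1.246; breathing rate 10.5 breaths/min (the
  cohort's 10–11 range).
* Durations are normal, truncated below at 0.5 s. The location parameter is
  solved (`uniroot` on the truncated-normal mean) so the **realised** mean
  equals the configured mean; naive truncation would bias NS upward by
  ~0.08 s and break parameter-recovery checks for the wrong reason.
* NS: Gaussian noise band-limited to 1500–2000 Hz over a weak low-frequency
  floor (relative RMS 0.4) and a small 2000–4000 Hz tail (0.18).
* VS: broadband 500–12,000 Hz noise multiplied by a raised-cosine modulator
  at 100 Hz with depth 0.9 (in `[1 - depth, 1]`).
* SS: 3–6 stationary sinusoids at harmonically unrelated frequencies in
  roughly 2500–9500 Hz (≥ 300 Hz apart) over a broadband floor (0.3 RMS).
* Every cycle is shaped by a rise–plateau–fall envelope (20/60/20 of the
  cycle, raised-cosine ramps). The source material does not describe the
  intra-cycle envelope; this is the simplest shape with soft onsets.
* Noise: background noise is band-limited below 1000 Hz, event (speech-like)
  noise below 1500 Hz; `add_noise()` realises an exact target SNR over the
  full signal. The default corpus SNR is 10 dB.
* Sample rate 44,100 Hz: the recorder was linear PCM and content reaches
  12 kHz, so Nyquist must exceed 12 kHz; 44.1 kHz is the standard dialect.
  The modulation depth, SS line count and component mix ratios are not
  quantified anywhere in the source material; they are engineering choices,
  chosen once and exposed as parameters.

`generate_recording()` spaces cycles with background-noise gaps so the
overall rate matches `breaths_per_minute`, and `generate_cycle_set()` builds
the default benchmark corpus (100 cycles/class, SNR 10 dB, fixed seed).

**What the generator does *not* emulate:** ward acoustics (reverberation,
non-stationary interference, alarms, speech with structure above 1500 Hz),
patient variability in spectral shape, drifting SS resonances, partial or
overlapping obstruction states, and microphone/placement effects. A green
synthetic benchmark therefore establishes that the pipeline implements its
contracts and separates the *idealised* class signatures — it does not
predict clinical accuracy, and the published classifier accuracies on real
recordings are deliberately not reproduction targets.

# Preprocessing

Noise below 1500 Hz dominates these recordings, so `noise_filter()` is a
linear-phase windowed-sinc (Hamming) high-pass, default 255 taps, −6 dB at
the cutoff, ≥ 40 dB stopband attenuation below 0.75 × cutoff and ≤ 1 dB
passband loss above 1.25 × cutoff at the default 1500 Hz / 44.1 kHz. Group
delay is compensated so output length equals input length.

`segment_cycles()` detects cycles by hysteresis on the short-time energy in
1500–12,000 Hz (50 ms frames, 50 % hop): onset above 3 × the noise floor,
offset below 1.5 ×, events < 0.5 s dropped, gaps < 0.2 s merged. No
segmentation algorithm is prescribed by the source material; this detector is
this package's design. Two numerical choices matter:

* The noise floor is the 10th percentile of frame energies, **but never less
  than −40 dB relative to the loudest frame**. In near-silent gaps the
  in-band energy is pure spectral leakage spanning orders of magnitude, and a
  percentile-only floor lands inside that distribution, making the
  hysteresis thrash.
* A quality gate (on by default) drops cycles whose sub-1500 Hz energy
  exceeds their in-band energy by > 10 dB — the stand-in for the study's
  exclusion of severe-noise and inaudibly faint samples.

# Features

* **Spectrogram**: Hann 25 ms / hop 10 ms magnitude-squared STFT, one-sided,
  scaled so total spectrogram energy equals windowed time-domain energy
  (tested against a direct Parseval oracle); dB view floored at −80 dB.
* **MFCC(20)/MFCC(40)**: 48 triangular mel filters over 0–12,000 Hz (the
  analysed range; 48 filters keep 40 retained DCT coefficients well-posed),
  log, orthonormal DCT-II. Verified to 1e−8 against an independently coded
  brute-force oracle. The exact filter bank of the original study is in
  supplementary material unavailable here; this bank is a documented
  stand-in, recorded in `mel_params`.
* **Per-cycle pooling**: classifiers need fixed-length inputs but cycles
  vary in length; the SVM/kNN vector is the per-coefficient mean and SD
  across frames (2 × n_coeffs values). Frame-level versus cycle-pooled input
  is unstated in the source; pooling is config-exposed and swappable.
* **Modulation peak**: envelope (rectified high-band signal, 1 ms smoothing,
  decimated to ~2 kHz) → Welch modulation spectrum (0.5 s Hann segments,
  50 % overlap; Welch averaging keeps the broadband-noise null's max/median
  ratio small) → dominant peak in 20–300 Hz. Prominence is peak/median
  in-band power; peaks are "absent" when the envelope coefficient of
  variation is < 0.05 (a constant envelope otherwise produces spurious
  ratios) or prominence < 100. The gate was calibrated once on the default
  corpus: coherent VS modulation reaches prominence ~1500–2000 (250–320 for
  mixed VS+SS cycles), while the broadband/tonal null — including the
  low-frequency envelope hump of narrowband NS noise and occasional SS
  tone-beat components — stays below ~50, so 100 sits in the gap with
  margin on both sides.
* **Line persistence**: per frame, peaks above 2000 Hz are local maxima
  standing 10 × above a running-median (±25 bins) spectral background — a
  *local* background, because a global frame median classifies every bin of
  a broad noise band as a "peak". Bins (±1) active in ≥ 80 % of frames are
  stable lines; the statistic is the fraction of frames with ≥ 1 stable
  line active.

# Rule-based classification

`classify_cycle()` fires, in order: VS if the modulation peak lies in
50–150 Hz with prominence ≥ 100; else SS if the fraction of energy above
2000 Hz is ≥ 0.4 **and** line persistence is ≥ 0.6; else NS. The ordering
itself implements the clinical VS-over-SS tie-break, and a decision trace
records both pattern scores and the fired rule. The source signatures are
qualitative (images); these numeric thresholds were fixed once against the
default synthetic corpus and are config-exposed — they are part of the
package's stated world, not per-run tuning.

# Machine-learning classifiers

No SVM/kNN/deep-learning R package is assumed; the three model families are
implemented in-package:

* **SVM**: one-vs-one soft-margin C-SVM (C = 1) solved by simplified SMO;
  kernels `poly3` (`(γ⟨x,y⟩ + 1)³`) and `rbf` (`exp(−γ‖x−y‖²)`,
  γ = 1/(d·var)). Features standardised on the training split only (the
  source is silent on scaling).
* **kNN**: Euclidean distance on standardised features, k ∈ {3, 5, 7}
  (odd); multiclass ties broken by summed neighbour distance. Tested against
  an exhaustive-scan oracle.
* **CNN**: a small stand-in for the full-scale image classifiers — 4 blocks
  of (3×3 conv → ReLU → 2×2 max-pool) with 8/16/32/32 channels and a
  softmax head, on dB-grayscale spectrogram images (128×128 by default,
  time-normalised per cycle). Batch size 32 is retained from the full-scale
  setting; the step budget defaults to 2000 (scaled down from 200,000) and
  tests run 100 steps at 32×32 — enough to verify the training loop (loss
  decreases, deterministic under seed), not to benchmark accuracy.
  Convolution/pooling kernels are RcppArmadillo.

# Evaluation

* `split_train_test()`: stratified 80/20 with per-class
  round-half-up — note the published split (3159/791 of 3950) differs by
  one from `round(3950 × 0.8) = 3160`; this package follows its own stated
  convention and documents the discrepancy rather than replicating an
  unexplained off-by-one.
* `binary_metrics()`: positive class defaults to **abnormal** (VS ∪ SS),
  inferred from the clinical question (detecting airway problems) — the
  source never states the convention; a flag flips it. Zero-denominator
  ratios are reported as `NA`, never 0. AUC is the tie-corrected rank
  statistic; `roc_curve()` groups tied scores so its trapezoid area equals
  the rank AUC exactly.
* `three_class_metrics()`: total accuracy plus *accuracy in abnormal
  sounds* = correct / truly-abnormal. The narrower reading (conditioning on
  predicted-abnormal too) was rejected because it silently drops
  abnormal-missed-as-normal errors; with the chosen denominator a VS cycle
  predicted NS counts against the classifier.
* Printed-table reproduction uses round-half-away-from-zero at the printed
  precision.

# Known limitations

* Synthetic validation only: no claim transfers to real ward recordings.
* The segmentation detector assumes noise is predominantly below 1500 Hz;
  broadband interference inside 1500–12,000 Hz will degrade both the noise
  floor estimate and the quality gate.
* The SMO solver is adequate for corpus-scale problems (hundreds of cycles)
  but is not an optimised SVM implementation.
* The CNN is intentionally small; it demonstrates the spectrogram-image
  route, not state-of-the-art accuracy.
* Splitting is per cycle, not per patient; with real data a grouped split
  would be required to avoid patient leakage.
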