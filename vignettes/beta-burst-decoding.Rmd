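---
title: "Beta-burst kernel convolution for motor-imagery decoding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-burst kernel convolution for motor-imagery decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sensorimotor beta (15–30 Hz) activity is not a sustained oscillation but a
train of transient, high-amplitude *bursts* lasting roughly 100–300 ms.
During movement and motor imagery the burst rate over the contralateral
motor cortex drops (the classic event-related desynchronization, seen at
the level of individual events), and — crucially — bursts are not all the
same: their waveform *shapes* are heterogeneous, and only some shapes carry
the task-related rate modulation. `burstconv` implements a decoding
pipeline that exploits this: it detects bursts, learns which waveform
shapes are most lateralized between task and baseline, turns those shapes
into convolution kernels, and decodes left- vs right-hand motor imagery
from CSP features of the kernel-convolved signals.

## Pipeline overview

1. **Preprocessing** (`filter_epochs`, `remove_line_noise`,
   `reject_trials`): zero-phase windowed-FIR low-pass (default cutoff
   120 Hz, transition bandwidth 25% of the cutoff; forward–backward
   application with mirror-reflection padding of three filter orders), a
   spectral-interpolation notch for narrow-band interference, and
   peak-to-peak trial rejection (threshold `Q3 + 3·IQR` of per-trial
   maxima by default).
2. **Time-frequency decomposition** (`superlet_tf`): superlets — at each
   frequency, the geometric mean of complex Morlet amplitudes with cycle
   counts `k·c`, `k = 1..o(f)`, where the order `o(f)` grows linearly from
   `o_min = 1` at 1 Hz to `o_max = 40` at 43 Hz (`c = 4`, 0.5 Hz grid).
   Superlets retain single-wavelet time resolution while sharpening
   frequency resolution, which is what makes transient bursts separable
   from the 1/f background.
3. **Burst detection** (`detect_bursts`, `detect_all`): iteratively take
   the largest TF amplitude, measure its time/frequency FWHM on the
   current residual, subtract a 2D Gaussian with matching amplitude and
   per-side widths, clip at zero, and repeat until no peak exceeds the
   noise floor (twice the standard deviation of the initial TF amplitudes,
   fixed across iterations). Peaks in the beta band whose trough-centered
   260 ms waveform can be extracted are emitted as bursts.
4. **Kernel selection** (`select_kernels`): robust-scale the waveform
   matrix per time sample, extract principal axes, and score every burst.
   The lateralized modulation index of axis `m` is
   `I_m = |(u_ipsi^C3 − u_contra^C4) − (u_ipsi^C4 − u_contra^C3)|` with
   `u = |mean task-period score − mean baseline score|` per (motor
   channel, laterality) cell. The three axes (among components 2–9) with
   the largest `I_m` are kept; per axis, the score range is split into
   seven equal-width groups and the two extreme groups are averaged (raw,
   unscaled waveforms) into one kernel each — six kernels in total.
5. **Features and decoding** (`convolve_kernels`, `fit_csp`,
   `crossval_decode`): each kernel produces one temporally filtered copy
   of the epochs (same-length centered convolution); CSP (4 components)
   and log average power per copy give 24 features (band-filtered
   baselines give 4, 12, 20 or 32); repeated (10×) stratified 5-fold
   cross-validation with pooled-covariance LDA yields time-resolved AUC
   curves over incremental (100 ms steps) or sliding (1 s, 50 ms steps)
   windows.
6. **Evaluation** (`compute_itr`, `cluster_permutation_test`): the
   information transfer rate `ITR = (1 − H(p))/T` (binary entropy `H`,
   window time cost `T`), and threshold-stepped cluster-based permutation
   tests (sign flips of paired subject differences, max-statistic
   correction) for comparing decoding curves.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| low-pass cutoff | 120 (95 if Nyquist forbids) | Hz | keep broadband shape, kill EMG/HF noise |
| superlet `o_min, o_max, c` | 1, 40, 4 | – | standard burst-resolution setting |
| TF grid | 1–43 Hz, 0.5 Hz | Hz | covers mu + beta with margin |
| burst band | 15–30 | Hz | beta proper |
| waveform window | 0.260 | s | canonical burst support (lagged-coherence based) |
| trough search | ±0.030 | s | trough must be near the TF peak |
| noise floor | 2 × SD(TF) | – | fixed pre-subtraction floor guarantees termination |
| trial sample fraction | 0.10 | – | cost control on large pooled datasets |
| candidate axes | 2–9 | – | axis 1 encodes temporal skew, excluded |
| score groups | 7, keep 2 extremes | – | "similarly shaped" burst groups |
| CSP components | 4 | – | 2 per class, interleaved by eigenvalue |
| CV | 10 × 5-fold, stratified | – | stable AUC estimates |
| permutations | 2^13 | – | p-value resolution ~1e-4 |

## The synthetic generator

`simulate_epochs()` is a first-class module, not a test stub. Each trial
and channel is:

* **1/f background**: Gaussian noise with PSD ∝ `f^-noise_exponent`
  (default exponent 1, overall SD 6 µV) — this aperiodic structure is
  load-bearing: the 2·SD noise floor of the burst detector is only
  meaningful when low frequencies dominate the TF amplitude distribution,
  exactly as in real EEG. On spectrally flat noise the floor degenerates
  and the detector over-triggers; tests therefore always use the colored
  background.
* **mu rhythm**: a 10 Hz sinusoid (4 µV, random phase per trial/channel).
* **optional line tone** for exercising the notch.
* **bursts**: trough-centered cosines under asymmetric Gaussian envelopes
  (`burst_family`: center frequency, cycles, skew, amplitude
  distribution), placed by per-(channel, class, period, family) Poisson
  rates with a 130 ms minimum separation (placement is redrawn rather
  than thinned, so realized counts stay Poisson-like). Peaks keep 0.35 s
  from the epoch edges so every injected event lies inside the TF valid
  region at beta frequencies.

Default rates follow the ERD pattern (baseline 0.6/s per motor channel,
task 0.25/s contralateral, 0.55/s ipsilateral — plausible magnitudes, not
reference values). Two rate tables are provided because they model two
different physiologies:

* `default_rate_table()` — hemisphere-symmetric ERD. Note that the
  modulation index contrasts *absolute* baseline-to-task score shifts
  between the two (class, hemisphere) pairings, so any mirror-symmetric
  modulation — classic bilateral ERD, or two families suppressed with
  equal strength on opposite hemispheres — cancels in expectation. This
  table is appropriate for decoding tests but blind to the index.
* `lateralized_rate_table()` — the two families are contralaterally
  suppressed with *unequal* strengths (family 1 strongly on the left
  motor channel, family 2 weakly on the right). This class-by-hemisphere
  interaction of shift magnitudes is exactly what the index detects, and
  is the study condition for kernel recovery.

What the generator does **not** emulate: volume conduction / realistic
forward models, ocular or muscular artifacts, non-stationary background
power, inter-subject variability of burst shape. Passing tests therefore
show that the pipeline recovers the statistical structure it assumes, not
that it is robust to every pathology of real recordings.

## Numerical and design choices

* **Wavelet convention**: complex Morlet with Gaussian SD
  `n_cycles / (2π f)`, ±3 SD support, unit-energy normalization, zero
  padding. The geometric mean offsets amplitudes by machine epsilon so a
  zero envelope cannot poison a whole row. The superlet inner loop is
  compiled (Rcpp/Armadillo, FFT-based batched convolution); the plain-R
  `morlet_response` is kept as an independent reference, and the two are
  held to within 1e-6 of each other at order 1 by the test suite.
* **TF valid region**: per frequency, half a standard deviation of the
  longest wavelet at that frequency. Peaks inside the edge zone are
  subtracted but not emitted.
* **Gaussian subtraction**: per-side sigmas (`width / sqrt(2 ln 2)` per
  side) rather than one symmetric sigma, so skewed blobs do not leave
  shoulder residuals that re-trigger detection; the residual is clipped at
  zero to preserve nonnegativity, and the FWHM is measured on the current
  residual. The fixed (initial) noise floor guarantees termination.
* **Failed waveform extraction** (no trough within ±30 ms, or window
  clipping the epoch edge) still subtracts the blob, so later peaks are
  not blocked; the event is simply not emitted.
* **Kernels average raw waveforms**, not robust-scaled ones: the kernels
  convolve raw microvolt signals, so physical units must be preserved.
  Group edges use the empirical score range of the sampled set (outlier
  sensitivity noted).
* **CSP**: per-trial covariances are trace-normalized before class
  averaging (amplitude-outlier guard); rank deficiency is handled by an
  `1e-10 · trace` ridge with a warning. Components are interleaved
  (λ_max, λ_min, λ_2nd-max, λ_2nd-min).
* **Log power features**: the log of average power (not raw power) feeds
  LDA, improving its Gaussian assumption; zero-variance projections floor
  at `log(1e-20)` with a warning.
* **LDA**: pooled-covariance weight vector with an `1e-8 · trace` ridge
  fallback; AUC is computed by the rank formula (pROC is the cross-check
  in tests).
* **ITR**: `p(t)` defaults to the window's mean AUC used as the accuracy
  probability — the metric is defined for accuracies, scores are AUCs,
  and this package keeps that conflation explicit (any probability-like
  series can be supplied instead). Incremental windows measure `T` from
  their segment start, so the metric's ceiling is `1/0.1 = 10` bits/s;
  sliding windows measure `T` from the beginning of the baseline period,
  which deliberately does not reproduce a 20 bits/s ceiling (that bound
  would require `T` to be the 50 ms step, inconsistent with elapsed
  recording time).
* **Cluster inference**: one-sided paired t statistics; the enhancement
  integrates summed exceedance of contiguous supra-threshold runs over a
  ladder of thresholds (start 0, step 0.2, up to the observed maximum);
  sign-flip permutations (exhaustive when `2^n ≤ n_perm`) with the
  max-statistic correction, `p = (1 + #{perm ≥ obs}) / (n_perm + 1)` for
  random draws. Zero-variance nonzero-mean differences map to an infinite
  t (perfectly consistent shift) rather than zero.
* **Cross-validation regimes**: burst detection is label-free, so bursts
  are detected once; the label-dependent stages differ by pipeline.
  `pipeline_kernels` uses a fixed kernel set — the calibration framing in
  which kernels come from a separate recording — while CSP and LDA are
  always refit inside each fold. `pipeline_kernels_cv` additionally
  refits kernel selection per fold from the precomputed bursts; it is
  provided for strict-separation audits but is not the default because
  the calibration framing matches how such a BCI is deployed and the
  strict mode multiplies the convolution cost by the fold count.
* **Window conventions**: 0-based sample indexing with half-open
  `[start, end)` windows — a window of `w` seconds always holds
  `round(w·fs)` samples, and incremental windows never double-count
  boundary samples. Baseline and trial incremental windows are built as
  separate families.
* **Native container**: gzip-compressed little-endian float64 array plus
  a JSON sidecar — lossless round-trips, and the metadata stays diffable.
  EDF export quantizes to 16 bits against per-channel physical ranges
  that are first rounded to their 8-character ASCII header form, so the
  round-trip error is bounded by half a quantization step
  (`edf_quantization_step()`).

## Validation scales

The simulation-based checks in the test suite run at desk scale on one
CPU: detector recovery on 20 trials (~110 injected events, fixed 10 µV
amplitudes ≈ 4× the TF noise floor); kernel recovery over 20 seeds at 120
trials with fixed 12 µV amplitudes under the hemisphere-asymmetric rate
table; decoding on 200-trial evaluation sets with a high task-period rate
contrast (0.7/s ipsilateral vs 0.05/s contralateral, 15 µV bursts) and a
20-trial-per-class calibration recording for kernel selection; and
permutation-test calibration with 200 null simulations at 512
permutations. These sizes give stable pass/fail behavior while keeping
the whole suite within tens of minutes; they are choices of the package's
own validation design, and larger replications only sharpen the same
statistics.

## Known limitations

* The spectral-interpolation notch is a deliberately simple stand-in for
  DSS-based line-noise removal: same contract (suppress a narrow band,
  leave the rest), much smaller surface; it does not exploit spatial
  structure.
* The peak-to-peak IQR rejection rule replaces cross-validated rejection
  threshold searches; it only promises "noisy trials removed".
* `I_m` uses only the two motor channels and pools bursts per cell (no
  per-trial level); under perfectly symmetric bilateral modulation it is
  blind by construction.
* The estimator of `I_m` is noisy at small burst counts; at desk scale
  (~400 sampled bursts) axis selection is reliable only when the true
  modulation is strong. Dataset-scale pooling (the intended use) improves
  this linearly in subject count.
* Detected burst times are TF-peak times; for strongly skewed envelopes
  the TF peak can sit a few tens of milliseconds from the waveform
  trough, and trough identification can lock onto a neighboring
  oscillation cycle (one period ≈ 40–53 ms in beta).
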