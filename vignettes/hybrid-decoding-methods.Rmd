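---
title: "Methods: simulating and decoding an eyes-closed frontal hybrid EEG-fNIRS BCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding an eyes-closed frontal hybrid EEG-fNIRS BCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hybridbci)
```

## The decoding problem

A communication channel for users who cannot move — and often cannot keep
their eyes open or fixate — must be driven by brain signals alone, from
sensors that can be mounted quickly on hair-free skin. The setting this
package implements uses ten frontal EEG electrodes (AFp1/2, AFF1h/2h/5h/6h,
F3/4, F7/8) together with nine prefrontal near-infrared channels, recorded
while the user either performs continuous mental arithmetic (MA) or relaxes
(BL) for 10 s with eyes closed. The decoder answers, per trial, which of the
two states produced the signals.

Two physiological effects carry the information:

* **Electrical.** With eyes closed the alpha rhythm (8–13 Hz) is strong over
  the whole scalp; engaging in mental arithmetic attenuates it. Because the
  attenuation is spatially graded, the class difference appears both in
  band power and in the *shape* of the channel covariance — which is what
  spatial filtering exploits.
* **Hemodynamic.** The prefrontal oxygenation response (HbO up, HbR down)
  develops over seconds and peaks after task end; mental arithmetic evokes
  a larger response than relaxation. The most discriminative window is
  10–15 s after task onset, i.e. the tail of the response to a 10 s task.

## Pipeline

Event onsets mark the start of the task period; all windows are half-open
`[start, end)` in seconds relative to that onset, with sample `k` at time
`k / rate` (0-based).

1. **EEG**: decimate 1000 → 200 Hz (8th-order Butterworth anti-alias
   low-pass at 80 Hz, i.e. 80% of the new Nyquist, then keep every 5th
   sample); band-pass 0.5–50 Hz with a 3rd-order Butterworth applied
   forward–backward (offline zero-phase filtering; the effective order
   doubles); remove ocular artifacts (below); epoch 0–10 s.
2. **NIRS**: convert dual-wavelength intensities by the modified
   Beer–Lambert law, `ΔOD(λ) = −log10(I/I0)` and
   `(ΔHbO, ΔHbR)ᵀ = (ε d DPF)⁻¹ ΔOD`; band-pass 0.01–0.2 Hz (6th-order
   zero-phase Butterworth); epoch 10–15 s.
3. **Features**: per training fold, select the participant-specific EEG
   passband, fit CSP, take log variances of the six selected components;
   per NIRS channel take the window mean and least-squares slope (9 × 2 =
   18 features per chromophore).
4. **Classify**: one shrinkage-LDA per modality (EEG, HbR, HbO); stack a
   shrinkage-LDA meta-classifier on the three continuous scores for the
   fusions HbR+HbO (the "NIRS" decoder), EEG+HbR, EEG+HbO and EEG+HbR+HbO
   (the "HYB" decoder).
5. **Evaluate**: 10 × 5-fold stratified cross-validation; accuracies in
   percent pooled per fold then averaged over the 50 folds; information
   transfer rate at m = 6 trials/min (10 s trials), N = 2.

### Numerical choices

* **Low-frequency band-pass stability.** A single 6th-order Butterworth
  band-pass at 0.01–0.2 Hz on a 12.5 Hz stream is a 12th-degree transfer
  function with poles crowded near `z = 1`; in double precision it
  diverges. All band-passes are therefore realized as a high-pass/low-pass
  cascade of the specified order, each applied zero-phase. A 0.05 Hz probe
  sine passes the hemodynamic filter within 1.2%.
* **Epoch lengths.** 5 s at 12.5 Hz is 62.5 samples, so the half-open
  sample count depends on onset phase; trials are truncated to the common
  minimum so epoch arrays stay rectangular.
* **MBLL constants.** Defaults: extinction coefficients for 760/850 nm in
  1/(mM·mm), DPF 5.98/5.07, source–detector distance 30 mm, reference
  intensity I0 = per-channel session mean (a baseline window is
  configurable). The 0.01 Hz high-pass is the drift handling; no extra
  per-epoch baseline subtraction is applied.
* **CSP.** Per-trial covariances are trace-normalized and class-averaged;
  the generalized eigenproblem `Σ₁w = λ(Σ₁+Σ₂)w` is solved by whitening
  `Σ₁+Σ₂` and rotating (equivalent, numerically stable; a scaled-identity
  ridge of 1e-8·tr(C)/d guards rank deficiency). Components are scored by
  the ratio of class medians of projected trial variances — robust to
  outlier trials where mean/eigenvalue scores are not — and three per side
  are kept (fewer, symmetrically, below six channels). Log variances are
  normalized by the total selected-component variance by default; the
  normalization is switchable since conventions differ.
* **Band selection.** Welch spectra (1 s Hann windows, 50% overlap,
  zero-padded to a 0.5 Hz grid) of the 0–10 s epochs are scored per bin by
  signed r² of log band power, averaged over channels. The band seeds at
  the extremal-score bin and grows while the better adjacent bin retains at
  least 5% of the running score sum (and the seed's sign). If no bin
  reaches |sgn r²| = 0.01 the full search range 4–35 Hz is returned — a
  zero-effect fallback rather than a degenerate one-bin band.
* **Ocular artifact removal.** The named method is blind source
  separation: a SOBI-style joint diagonalization (Jacobi rotations over
  time-lagged covariance matrices, lags 5–500 ms) of the EEG and EOG
  channels jointly; components correlating above 0.7 in absolute value
  with any EOG channel are zeroed before back-projection. It is
  deterministic and seed-free. A regression-on-EOG fallback is provided.
* **Shrinkage LDA.** Pooled class-centered covariance shrunk toward
  `ν I`, `ν = tr(Σ̂)/d`, with the analytic Ledoit–Wolf intensity
  `γ = min(1, β²/δ²)`; the fit is well-posed even with fewer trials than
  dimensions. The bias places the boundary at the class-mean midpoint
  (equal priors — the design is label-balanced).
* **Stacking hygiene.** Meta-classifiers must never see resubstitution
  scores. Within each outer training fold an inner stratified 8-fold split
  produces out-of-fold base scores for meta training; the base classifiers
  are then refit on the full training fold for test scoring. Eight inner
  folds (rather than the more common four) keep the inner training sets
  close in size to the outer fold, so the score distributions the meta
  learns from match those it is applied to; in side-by-side runs this made
  the fusion gain distinctly more consistent.
* **Exact Wilcoxon.** The exact two-sided signed-rank p-value is computed
  by convolving the null distribution of the positive-rank sum over all
  2ⁿ sign assignments (ranks doubled to integers), which remains exact
  under tied ranks; standard exact routines refuse ties. Normal
  approximation with continuity and tie correction is used above n = 25.
  Friedman and Benjamini–Hochberg go through the standard library
  routines.

## The synthetic generator

Real recordings are not distributed with the package; the generator
produces sessions with the paradigm's structure (per session: 15 s
pre-rest, 20 trials of 2 s instruction + 10 s task + 15–17 s uniform rest,
15 s post-rest; labels drawn balanced without replacement; default 3
sessions = 60 trials so 5-fold CV keeps ≥ 12 test trials per fold) and the
statistical structure the analysis assumes:

* **EEG** (22 scalp channels + 4 EOG): per-channel 1/f Gaussian background
  (6 µV); an eyes-closed alpha rhythm as narrowband noise at 10 ± 1 Hz
  (8 µV, half shared across channels, half channel-specific) whose
  amplitude drops during MA task windows by `alpha_attenuation_ma` times a
  per-channel weight drawn once from U(0.3, 1) — task-related
  desynchronization is spatially graded, and a perfectly uniform power
  change would be invisible to trace-normalized spatial filters; blink and
  saccade sources (< 4 Hz pulse trains and smoothed telegraph signals,
  60 µV at the eyes) mixed into the scalp channels with gains decaying
  from prefrontal (0.4) to occipital (0.02).
* **NIRS** (9 channels × 2 wavelengths): the task boxcar scaled by the
  class amplitude (HbO 1.0 µM for MA, 0.5 µM for BL; HbR = −1/3 of HbO)
  with mean-one lognormal trial-to-trial jitter (CV 0.4), convolved with a
  double-gamma response (peak 6 s, undershoot 16 s, ratio 1/6 — the
  boxcar⊗HRF peak then falls 10–15 s after onset); plus spatially coherent
  cardiac/respiratory/Mayer oscillations (1.0/0.3/0.1 Hz, 0.35 µM), a slow
  drift random walk (0.3 µM) and white noise (0.08 µM); all mapped to
  strictly positive intensities by the Beer–Lambert forward model with
  per-channel baseline intensities.

The default effect sizes were chosen once so that the default 60-trial
dataset decodes at unimodal accuracies near the published group means of
this paradigm (EEG ≈ 77%, NIRS ≈ 75%), and are not adjusted thereafter.
Setting `alpha_attenuation_ma = 0` and `hrf_amp_ma = hrf_amp_bl` removes
all class information, and the pipeline decodes such data at chance.

What the generator does **not** emulate: volume conduction through a head
model (channel correlations are source-mixing only), eyelid/pupil dynamics,
photon transport (the forward model is the same linear law the inverse
uses), motion artifacts, session-to-session nonstationarity, and
participant heterogeneity beyond per-dataset random gains. Passing tests
therefore demonstrate internal correctness and sensible statistical
behavior of the pipeline — not clinical performance on real recordings.

## Problem sizes used by the test suite

The suite validates properties at deliberately modest sizes: module tests
run on one 12-trial session at a 200 Hz EEG rate; the chance-level control
uses the full 60-trial default at 1000 Hz with 10 × 5-fold CV; the
fusion-gain property uses 20 generator seeds at 60 trials with EEG
generated directly at 200 Hz (skipping the decimation stage) and
`alpha_attenuation_ma = 0.3`, calibrated once so both unimodal decoders
are moderate and balanced (~80%) — the regime in which fusing independent
information should, and does, help.

## Known limitations

* The heuristic band-growth rule reproduces the cited selection method's
  published defaults, but the original's exact stopping tolerances are not
  public; the 5% growth fraction and the 4–35 Hz fallback are package
  constants.
* "NIRS accuracy" is defined as the HbR+HbO fusion and "HYB" as
  EEG+HbR+HbO throughout; studies sometimes report the best combination
  per participant instead.
* Whether reference intensities should be per-session or per-trial is a
  judgment call; the default is per-session (the high-pass removes the
  difference in practice), with a configurable baseline window.
* The SNIRF importer shells out to Python's h5py (bundled bridge script);
  EDF and BrainVision are parsed natively.
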