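---
title: "Anticipatory decoding of continuous steering actions: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anticipatory decoding of continuous steering actions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steertrf)
```

## The scientific problem

When a person drives, the decision to turn the wheel is prepared by the
brain well before the hands move. `steertrf` asks whether that preparation
is visible in scalp EEG: can multichannel EEG predict a *continuous*
steering trace, and how far ahead of the action does the predictive signal
reach? Two linear models frame the question:

* **Forward (encoding) model.** For each EEG channel, lagged linear ridge
  regression (LLR) estimates weights $w(\tau)$ in
  $\mathrm{eeg}(t) = \sum_{\tau \in [\tau_1, \tau_2]} w(\tau)\, s(t - \tau)$,
  where $s$ is the steering angle. The weight vector over lags is the
  temporal response function (TRF). Under this convention a weight at a
  *negative* lag describes EEG activity that precedes the steering action.
  The default window is $[-1.5, 0.5]$ s: up to 1.5 s of anticipation and
  0.5 s of lag.
* **Backward (decoding) model.** Steering is reconstructed from all EEG
  channels jointly, restricted to a fixed-size window placed progressively
  earlier: with anticipation $a$ the decoder sees only EEG in
  $[t - (a + 1.5), t - a]$. Decoding quality is Pearson's $r$ between the
  reconstructed and actual steering on held-out folds. Sweeping
  $a = 0, 0.3, \ldots, 3, 6, 12$ s traces how predictive information decays
  with anticipation.

A third ingredient deals with the obvious confound: during real driving the
EEG also picks up muscle activity, head/body motion and eye movements, all
of which correlate with steering at (or near) zero lag. Measured nuisance
recordings (EMG, accelerometers, EOG) are therefore used in a canonical
correlation analysis (CCA): EEG is rotated into components ordered by their
correlation with the nuisance block, the leading components (above the 90th
percentile of the correlation distribution) are zeroed, and the data are
rotated back. Padding the nuisance block with white-noise columns up to the
EEG channel count makes the rotation square, hence exactly reversible when
nothing is removed — removal is then the *only* way the EEG can change.
Because CCA targets instantaneous correlations only (no lagged copies of the
nuisance streams enter the analysis), anticipated or delayed cortical
activity is spared by design, while zero-lag artifact projections are
captured. The procedure is conservative: cortical signal that happens to be
instantaneously correlated with the nuisances is removed along with them.

## What the synthetic generator emulates

No public recordings accompany this analysis framework, so the package
ships a generator whose sessions have recoverable ground truth:

* **Steering** is low-pass filtered Gaussian noise (order-2 zero-phase
  Butterworth), demeaned, unit variance. Only its smoothness and
  autocorrelation matter downstream; there is no vehicle or track model.
  The default cutoff is 0.5 Hz — slow, lap-like wheel work; the cutoff is a
  free parameter because the spectrum of real steering depends on the
  course driven.
* **EEG** per channel is the sum of (a) the steering trace convolved with
  an anticipatory lag kernel (one Gaussian bump per channel, centers spread
  over $[-1.0, -0.3]$ s, width 0.15 s, alternating sign, L1-normalised so a
  unit-variance steering trace yields roughly unit-scale cortical signal),
  (b) $1/f$ background noise of unit standard deviation, and (c) zero-lag
  projections of the nuisance streams through mixing vectors drawn once
  from the ground-truth seed — a stationary artifact subspace for CCA to
  find.
* **Nuisances**: accelerometers (12 channels) follow smoothed
  $|\mathrm{d}s/\mathrm{d}t|$ (motion intensity, instantaneous with the
  action); EMG (4 channels) is broadband noise amplitude-modulated by the
  same motion intensity; EOG (3 channels) is smoothed steering *advanced*
  by 0.4 s, because gaze typically leads the wheel by a few hundred
  milliseconds. Default artifact gains are 0.5 (EMG), 1.0 (accelerometers)
  and 0.5 (EOG), making artifacts comparable in scale to the cortical
  signal — the pessimistic regime the denoiser exists for.
* A control mode (`nuisance_informative = FALSE`) derives the nuisance
  streams from an *independent* surrogate steering trace with the same
  spectrum. The streams keep their structure but carry no information about
  the actual steering — the condition needed to isolate the EEG's own
  contribution in combined decoding.

The default montage is 24 channels: the smallest realistic montage that
still exceeds the 23 real nuisance columns (4 EMG + 4 EMG envelopes + 12
accelerometer + 3 EOG), so the noise matrix can always be padded to a
square, reversible CCA mapping.

What the generator deliberately does *not* emulate: non-stationarity
(drowsiness, electrode drift), volume-conduction-realistic topographies,
event-locked oscillatory dynamics (mu/beta desynchronisation), and
nonlinear muscle-to-EEG coupling. Passing tests on this ground truth
therefore demonstrate that the estimators recover what they claim under the
stated signal model — not that real recordings satisfy that model.

## Signal conditioning

EEG (and EOG) are band-pass filtered 0.1–24 Hz with an order-4 Butterworth
applied forward and backward ("4 + 4"), then decimated to 100 Hz. The
filters are realised as cascaded second-order sections because an order-4
transfer function with a 0.1 Hz edge at 500 Hz sampling is numerically
fragile in expanded `(b, a)` form; odd-symmetric reflection padding (six
time constants of the slowest edge) suppresses the forward–backward edge
transients. Channels are re-referenced to the montage average, and channels
whose variance exceeds three times the mean channel variance are rejected
(after referencing, in that order). EMG is kept in two forms: filtered like
the EEG, and as a linear envelope (20–249 Hz band-pass, clipped below
Nyquist, then a centered 250 ms sliding RMS with truncated edge windows; at
scaled-down sampling rates below 50 Hz the envelope's high-pass edge adapts
to fs/4). Accelerometers are z-scored with the sample (n − 1) convention.
Steering is decimated to the analysis rate but otherwise untouched.

## Numerical and design choices

* **Lag convention.** One canonical convention,
  $y(t) = \sum_\tau w(\tau) x(t-\tau)$, is used everywhere. The decoder's
  user-facing anticipation window $[-(a+1.5), -a]$ maps onto engine lags
  $[a, a+1.5]$ by a single documented sign flip in `fit_decoder()`.
* **Edges.** Lagged designs are zero-padded; the generator flags the first
  and last kernel-length samples for optional trimming.
* **Ridge grid.** Thirteen log-spaced values, $10^{-3}$–$10^{9}$, one per
  decade. The identity penalty is the default; a first-difference roughness
  penalty is available because ridge shrinkage effectively smooths TRF
  weights in time, and an explicit smoother is sometimes preferable.
* **Cross-validation.** Folds are contiguous time blocks, never random
  samples: steering is strongly serially correlated and random folds would
  leak train information into the test set. Regularisation is chosen by
  nested cross-validation (per outer fold, on the training folds only) by
  default; a `"global"` mode selects one lambda across folds, matching the
  simpler protocol of common TRF toolboxes. Two folds are permitted (the
  minimum that defines held-out data) though nested selection needs three.
  Design columns are standardized before solving; weights are returned on
  the original scale.
* **Degenerate inputs.** A singular system at $\lambda = 0$ falls back to
  the minimum-norm pseudo-inverse with a warning; zero-variance predictions
  score $r = 0$ rather than `NA`; constant columns are rejected by name in
  z-scoring.
* **CCA.** Both blocks are whitened by SVD with a relative singular-value
  cutoff of $10^{-10}$; the decomposition of the whitened cross-product
  gives the transforms. Signs are fixed by making the largest-magnitude
  element of each EEG-side column positive. Column means are removed before
  the rotation and restored after back-projection. An average-referenced
  EEG is exactly rank-deficient by one; the centered data then lie wholly
  in the retained subspace and the pseudo-inverse back-projection remains
  an exact identity on the data. A mapping with fewer components than the
  EEG rank (an unpadded nuisance block) is refused because it would
  compress the data.
* **Percentiles.** One definition everywhere (CCA component selection and
  null baselines): linear interpolation between order statistics
  (`quantile type 7`). Component removal uses a strict "greater than" at
  the 90th percentile; with all correlations equal nothing is removed. The
  90th percentile is acknowledged as an arbitrary but conservative choice
  and is a parameter. The null baseline defaults to the 95th percentile
  with the 99th available.
* **Null distribution.** Fold identities are shuffled by a uniform random
  permutation (the identity permutation is allowed; with ten folds its
  probability is negligible), steering fold $i$ is paired with EEG fold
  $j$, and the full cross-validated decoding is re-run; 100 iterations by
  default. Permutation p-values use the add-one estimator so $p = 0$ never
  occurs.
* **Group statistics.** TRF group significance uses Wilcoxon signed-rank
  tests against zero with FDR correction across latencies within each
  channel (exact distribution below 10 subjects, normal approximation with
  continuity correction otherwise). Repeated-measures ANOVA is computed
  through a multivariate linear model with a within-subject design;
  Mauchly's test gates the Greenhouse–Geisser correction (applied when
  $p_{\mathrm{Mauchly}} < 0.05$, only meaningful from three levels), and
  partial eta squared is $SS_{\mathrm{effect}} / (SS_{\mathrm{effect}} +
  SS_{\mathrm{error}})$.

## Experiments the tests run, and their problem sizes

The test-suite experiments run at reduced problem sizes — shorter sessions
(1–7 min), lower sampling rates (20–50 Hz), 4–24 channels, a coarse
five-point ridge grid, 20–30 null iterations — while keeping the generator's
condition values (noise level, gains, kernel geometry) at their defaults.
Two experiment-specific input choices deserve their rationale:

* **Kernel identifiability.** Recovering a lag kernel from a regression on
  steering requires the steering trace to excite the kernel's full
  bandwidth (a Gaussian bump of width 0.15 s has meaningful spectral
  content up to roughly 1–2 Hz). Encoder-recovery experiments therefore
  drive the generator with a 2 Hz steering cutoff. With the default 0.5 Hz
  trace the kernel is only identifiable up to its projection onto the
  excited band — a system-identification fact, not an estimator failure.
* **Serial correlation and the anticipation decay.** Long-anticipation
  decoding rides on the steering signal's own serial correlation: a decoder
  seeing EEG from 3 s ago can still predict current steering only if
  steering 2–4 s ago predicts steering now. The decay experiments use a
  0.2 Hz cutoff, giving an autocorrelation time of several seconds, so the
  decoding declines gradually from far above the null baseline at $a = 0$
  to within it at $a = 12$ s, instead of collapsing to chance as soon as
  the anticipation exceeds the kernel support.

## Known limitations

Linear models only: no state-space or nonlinear decoders, no online/causal
mode. The CCA denoiser removes any EEG component instantaneously correlated
with the nuisances, including genuinely cortical ones. The generator's
artifact model is linear and stationary. ICA-based ocular component
identification is out of scope (bipolar EOG channels are used instead), as
are source localisation and scalp-topography rendering beyond CSV export of
weights.
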