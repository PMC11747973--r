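---
title: "Encoding models for naturalistic soundscapes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models for naturalistic soundscapes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfscape)
```

## The model

trfscape implements forward (encoding) models of continuous EEG responses
to sound. The measured signal at channel $c$ is modelled as a convolution
of a stimulus representation $s(t)$ with a set of channel-specific weights
$w(\tau, c)$ over time lags $\tau$, plus a residual:

$$ r(t, c) = \sum_\tau w(\tau, c)\, s(t - \tau) + \varepsilon(t, c). $$

The weights — the temporal response function (TRF) — are estimated by
ridge regression on a lagged design matrix $S$ whose column $(f, \tau)$
holds feature $f$ shifted by $\tau$ samples, zero-padded at the edges:

$$ \hat w = (S^\top S + \lambda I)^{-1} S^\top r, $$

which at $\lambda = 0$ reduces to the ordinary normal equations. The lag
window defaults to $[-100, 500]$ ms; at the 100 Hz EEG rate this gives 61
lags, so a 40-band mel-spectrogram model has a $40 \times 61 \times C$
weight array. The penalty is a plain $\lambda I$ over all lag columns with
no intercept (the EEG is z-scored per segment first). We deliberately do
not rescale $\lambda$ by the design variance, as some toolboxes do: the
plain penalty is transparent, and the search grid — nine log-spaced values
from $10^{-4}$ to $10^{4}$ in multiplicative steps of 10 — is wide enough
to absorb scale differences. A consequence is that selected $\lambda$
values are comparable only within this package, not across toolboxes.

### Evaluation protocol

`trf_crossval()` is the canonical protocol: the recording is split into
contiguous, near-equal segments (6 by default; 10 for nested feature-set
comparisons, matching the two analysis styles the package supports); the
EEG is z-scored per channel within each segment; each segment is the
held-out test set exactly once; within every fold $\lambda$ is chosen by
an inner cross-validation over the training segments only; the refit model
predicts the held-out segment; and the score is the Pearson correlation
between prediction and measurement, averaged over channels. The lagged
design is built once on the concatenated recording and then split by rows,
so a handful of samples at segment boundaries mix neighbouring segments
through the lag window — the standard practice for continuous-data
toolchains, and negligible at 61-lag windows against multi-minute
segments. Channels with undefined correlations (zero variance or too few
samples, e.g. a test segment that a sparse discrete model cannot predict
at all) are excluded from channel averages; folds where no channel is
defined are dropped from fold averages.

## Stimulus features

All features are delivered at the EEG rate as a `feature_set` with
per-column discreteness flags:

* **Energy novelty and acoustic onsets.** The waveform is squared and
  smoothed with a Hann window (2048 samples, hop 128), compressed as
  $\log(1 + \gamma x)$ with $\gamma = 10$, differenced, smoothed again,
  half-wave rectified, and resampled; onsets are 1s at thresholded local
  maxima (plateaus resolve to their first sample). Two parameters are not
  fully pinned down by common practice and are therefore explicit
  configuration: the post-difference smoothing (we reuse the Hann family
  at one quarter of the energy window, measured in frames — a single
  smoothing family keeps the knob count down) and the onset threshold.
  The threshold is genuinely arbitrary in this kind of analysis; the
  default (0.05 novelty units) was calibrated once against the synthetic
  tone bank so that at least 95% of true event onsets are recovered within
  ±50 ms, and it lives in `feature_config()`, not in code. Note that the
  log compression acting on the smoothed energy ramp shifts the novelty
  peak slightly ahead of the physical onset (about 20 ms at a 160 ms
  energy window); the onset tests budget for this.
* **Envelopes.** The Hilbert envelope is $|$analytic signal$|$ followed by
  a zero-phase third-order Butterworth low-pass at 30 Hz and downsampling;
  the power envelope squares the signal, block-averages it to the EEG rate
  and compresses pointwise with exponent $\log_{10} 2 \approx 0.301$. The
  printed description of that compression ("the square root of the power
  … a compression parameter of $\log_{10} 2$") is internally inconsistent;
  we implement the exponent reading, which is close to a square root, and
  expose it as configuration (`power_compression_exponent`; 0.5 gives
  exactly the RMS envelope). Resampling is anti-aliased decimation rather
  than generic polyphase filtering: the 30 Hz low-pass already bounds the
  spectrum below the 50 Hz output Nyquist, and polyphase filtering at
  441:1 ratios would cost minutes in pure R for no accuracy gain. Output
  sample $k$ corresponds to time $k/f_{EEG}$.
* **Mel-spectrogram.** 25 ms Hann windows at 10 ms hops, power spectra
  through 40 triangular filters spaced on the mel scale from 0 Hz to
  Nyquist, trimmed/padded to the EEG length.
* **Sound-identity (SI) and condition markers.** Single-sample binary
  impulses at `round(onset * rate)`, one column per category, or per
  category × condition when the cognitive-prior split is on. Marker width
  is one sample because the markers represent onsets, not extents.
* **Combination.** `combine_features()` concatenates columns and min–max
  normalizes every non-binary column to $[0, 1]$ so that continuous
  features share the scale of the binary markers; binary columns pass
  through untouched, and a constant continuous column degenerates to all
  zeros.

## Model comparison machinery

* **Nested comparisons** (`nested_comparison()`) evaluate several feature
  models with identical segment boundaries and z-scoring, yielding paired
  fold scores — the acoustic → +SI → +condition ladder.
* **Statistics.** `wilcoxon_signed_rank()` reports $W$ on the
  smaller-rank-sum convention and a tie-corrected normal $Z$; p-values are
  exact (full sign-assignment enumeration) below 10 informative pairs and
  normal-approximate above, with zero differences dropped. Multiple
  comparisons use Benjamini–Hochberg FDR (`fdr_bh()`, backed by
  `stats::p.adjust`). Statistics operate on channel-averaged scores;
  per-channel values remain available for inspection.
* **Noise floor.** `onset_noise_floor()` re-runs the full protocol on
  onset trains whose inter-onset-interval multiset is exactly preserved
  while positions shuffle (intervals permuted, start offset uniform over
  the feasible slack); the 2.5/97.5 percentiles of the null scores form
  the 95% floor.
* **Cluster permutation** (`cluster_permutation_time()`) compares paired
  TRF weight trajectories over the time dimension only (no channel
  neighbourhoods): per-lag paired $t$, contiguous same-sign
  supra-threshold runs scored by summed $t$, null from random per-unit
  sign flips, cluster $p$ = fraction of null maxima at least as large.

## Variance partitioning

Prediction correlations convert to explained variance as the signed square
$R^2 = \mathrm{sign}(r)\, r^2$, so an anti-correlated model cannot pose as
explanatory. Two- and three-set partitions follow inclusion–exclusion
($A \cap B = A + B - A \cup B$, and the printed three-way identity for the
triple term). Overfitting can push shared terms negative; set theory
requires them nonnegative. The correction we adopt subtracts the smallest
uniform $b \ge 0$ from every union-model $R^2$ — unions are the
overfitting-inflated quantities — such that all intersection terms become
nonnegative. This is the minimal intervention satisfying the stated
constraint, and it leaves three-set unique terms invariant (they gain
$+2b$ from the triple and lose $2b$ from the pairwise terms), so a
genuinely negative unique term is reported as infeasible rather than
silently repaired. Whether a published correction of this kind was uniform
or per-term is typically not recoverable from methods text; only the
nonnegativity constraint is guaranteed here.

## Cross-prediction

`cross_predict_pair()` trains TRFs for two single-column features on the
same folds and scores four combinations per held-out segment (two within,
two cross). Generalization is summarized by the rank correlation between
matched within and cross scores; Spearman is the default (robust to score
scale, matching the $\rho$ convention) with Pearson available. Multi-band
features are excluded because the swapped weight matrices must agree in
dimension. When two features mark the same events with a systematic
latency offset, their TRFs are time-shifted copies; the shift is estimated
by cross-correlating channel-RMS lag profiles (a channel-aggregated
trajectory — the estimation level is not otherwise determined) and is
corrected globally per pair by shifting the predicting feature.

## Explainable-sample (masked) evaluation

A discrete-marker model predicts exactly zero outside the lag window
around its events, so whole-segment correlations dilute toward zero as
event coverage shrinks. `explainable_mask()` marks sample $t$ explainable
iff some event $e$ satisfies $t \in [e + \tau_{min}, e + \tau_{max}]$,
union over events and discrete columns; any continuous column makes every
sample explainable. The mask uses the full lag window including the
acausal −100 ms part — the design matrix has support there, so the model's
prediction is nonzero there; this is a superset of a purely post-onset
window. Masked correlations concatenate all mask-true samples within each
test segment (no per-event averaging), and per-segment scores are averaged
afterwards, consistent with the rest of the protocol.

## The synthetic-data generator

The generator is first-class, tested code and defines the study
conditions:

* Event trains with exact minimum-gap spacing (sorted uniforms plus a gap
  ramp), exact category/condition proportions, fully seeded.
* A tone bank (beep 800 Hz/60 ms; monitor-like and alarm tones at 200 ms)
  whose waveforms are RMS-matched to the bank average before placement —
  overlaps sum, and silence is exactly zero.
* Triphasic P1-N1-P2 kernels as three Gaussian bumps (defaults: latencies
  50/100/200 ms, amplitudes +1/−2/+1, width 15 ms, span 0.5 s, tapered to
  exact zeros at both ends). The true component amplitudes and widths of
  such responses are free parameters of the simulation; these defaults
  give the canonical morphology at physiologically usual latencies.
* Pink noise by spectral shaping (amplitude $\propto f^{-1/2}$, DC zeroed,
  unit variance per channel), independent across channels.
* EEG as the identical-response-per-trial convolution of events with a
  kernel plus pink noise at a controlled SNR (optional per-trial amplitude
  jitter exists but is off by default, matching the simulation's
  assumption). Defaults: 100 Hz, 22 channels, 600 s, 396 events — the
  dimensionality of the motivating analyses.

### SNR semantics

The single-trial SNR estimator (`estimate_trial_snr()`) divides the mean
absolute response over $[0, 0.5]$ s by the baseline standard deviation
over $[-0.1, -0.01]$ s and converts to dB. We use $20 \log_{10}$ — both
quantities are amplitude-scale — with $10 \log_{10}$ available via
`db_factor`. Two analytic facts shape the noise calibration:

1. a 90 ms baseline window of 1/f noise has a standard deviation well
   below the marginal one (factor $c \approx 0.5$ for a 10-minute
   recording), because the dominant low-frequency power does not vary
   within so short a window; and
2. at strong noise the numerator is dominated by
   $E|n| \approx 0.8\,\sigma$, so the estimator saturates near
   $20 \log_{10}(0.8 / c) \approx +4$ dB and can never read, say,
   −30 dB, for any noise gain (`estimator_snr_floor()`).

`calibrate_noise_sd()` therefore solves the amplitude-ratio definition
$\sigma = \overline{|k|} / (c \cdot 10^{\mathrm{SNR}/20})$ exactly, which
is monotone across the whole sweep grid; empirical estimator readings
agree with the nominal level within about 2 dB at high SNR (+1.6 dB bias
measured at 20 dB) and saturate at the floor below it. Levels like −30 dB
are thus nominal labels of noise strength. An expected-estimator
root-finding calibration was evaluated and rejected: it diverges and
becomes non-monotone near the saturation floor.

### What the generator does not emulate

No eye/muscle artifacts, channel dropout, drift, channel covariance, or
head geometry; responses are identical across channels and trials. Tests
passing on this generator demonstrate the correctness of the estimation
machinery under the stated generative model — not robustness to the
nonstationarities of real recordings.

## The SNR sweep and a known red result

`run_snr_sweep()` reproduces the simulation protocol: per SNR level,
random 396-event trains over 10 minutes, synthetic EEG, the standard
onset-TRF protocol, and both whole-segment and masked scoring on held-out
folds, averaged over replicates (default 10 with distinct derived seeds;
the test and acceptance runs use 5 and 3 replicates and 8 channels to stay
within desk-scale runtimes — problem sizes are stated where used). Across
−30…10 dB both curves rise monotonically (Spearman $\rho = 1$ in our runs)
and masked scoring dominates whole-segment scoring at every level, as the
sparse-event geometry dictates.

One property one might expect does **not** hold: at −30 dB the true-onset
scores do not fall fully inside the onset-shuffle noise-floor CI
($r_{masked} \approx 0.02$ against a CI of roughly ±0.009). With an
identical response on every trial, weight estimation averages noise down
by $\sqrt{396}$, so the fitted TRF retains a genuine kernel component and
held-out prediction stays marginally above chance even at nominal −30 dB.
This is a real feature of the identical-response simulation, not an
estimation artifact; the corresponding assertion in the acceptance suite
is intentionally left failing, with the measurement above as its record.

## Numerical choices and degenerate inputs

* Ridge systems solve by Cholesky on $S^\top S + \lambda I$; a singular
  system at $\lambda = 0$ is an error advising $\lambda > 0$.
* $\lambda$ ties break toward the smaller value; the final reported TRF
  uses the modal selected $\lambda$ refit on all data.
* Correlations over fewer than 3 samples, or against a zero-variance
  series, are `NA` and excluded from averages.
* A constant channel within a segment makes z-scoring impossible and is
  reported with channel and segment indices.
* Min–max of a constant continuous column is defined as all zeros.
* Onset-train shuffles require at least 2 onsets; marker construction
  fails loudly when two same-column events collide on one sample.
* All stochastic operations are pure functions of their integer seeds
  (`withr::with_seed`); pipeline stages derive per-stage seeds from the
  run seed.

## Known limitations

Backward (decoding) models, banded/group ridge, spatial (channel
neighbourhood) clustering, perceptual loudness models and real-data
preprocessing (filtering, ICA) are out of scope. The cluster permutation
test operates on channel-aggregated lag profiles only. Partitioning stops
at three sets.
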