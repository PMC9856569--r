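---
title: "Estimating consciousness levels from chronic ECoG with soft-clustered signal features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating consciousness levels from chronic ECoG with soft-clustered signal features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients in a completely locked-in state (CLIS) have no behavioural channel
left: no eye movement, no muscle twitch, nothing an examiner could score.
Before attempting any brain-computer communication with such a patient one
needs an estimate of whether the patient is conscious *at all* at a given
moment. `ecogstate` implements a fully unsupervised pipeline that turns a
long multichannel electrocorticography (ECoG) recording into a continuous
per-window "consciousness level" in $[0,1]$, built from seven signal
features whose directions of change with arousal are well documented, fused
by two soft-clustering algorithms.

The method makes one working hypothesis and otherwise no clinical
assumptions: *higher values of the selected features accompany higher
levels of consciousness*. Everything downstream — the choice of the
"conscious" cluster, the interpretation of the membership trace — follows
from that hypothesis, so the output should be read as a relative,
within-recording arousal index, not as a calibrated clinical scale.

## The pipeline

1. **Preprocessing.** The signal is band-pass filtered 0.5–45 Hz with a
   third-order Butterworth filter. Filtering is applied forward–backward
   (zero-phase): phase distortion would directly bias the imaginary
   coherency feature, at the cost that the effective amplitude response is
   the squared magnitude of the designed filter. Channels whose peak
   absolute amplitude anywhere in the recording exceeds a threshold
   (default 200 amplitude units, as read from the file header) are
   rejected; the criterion is the per-channel maximum over all files, so
   the channel set is consistent across the whole recording. The threshold
   is configurable because amplitude scales vary wildly between recording
   systems. No artefact removal beyond channel rejection is performed.

2. **Windowing.** Features are computed in 3-s windows sliding by 1 s.
   Windows never span two source files; each one-hour file of duration
   $D$ seconds contributes exactly $\lfloor (D - 3)/1 \rfloor + 1$ windows.
   A 24-file day of one-hour files therefore yields $24 \times 3598 =
   86{,}352$ feature rows.

3. **Seven features per window**, averaged across retained channels
   (connectivity features: mean of the strictly-lower triangle of the
   pairwise matrix):

   * **Relative band power** $P_\theta$ (0–4 Hz) and $P_\beta$ (12–30 Hz):
     band power over total power in 0–45 Hz, from a Welch PSD (Hamming
     sub-windows of 1/8 of the segment, 50% overlap). The theta band is
     deliberately kept at the literal 0–4 Hz convention of the source
     analysis; bands are configuration values.
   * **SEF95**: the lowest frequency containing 95% of total power,
     divided by 45 Hz. Computed on the discrete Welch grid without
     interpolation, ties resolving to the lower frequency — grid-exact and
     reproducible.
   * **ERR**, the Poincaré-plot ellipsoid radius ratio
     $SD1/SD2$ with $SD1^2 = \tfrac12\mathrm{Var}(x_k - x_{k+\tau})$ and
     $SD2^2 = 2\mathrm{Var}(x_k) - SD1^2$: $\approx 1$ for irregular
     signals, $\to 0$ for smooth/linear ones. The delay $\tau$ is 1/4 of
     the dominant cycle period, estimated once from the first file
     (first retained channel, first 120 s) and held fixed so windows are
     comparable; per-window re-estimation is available by configuration.
     When no spectral peak stands above four times the median in-range
     density the configured default period (0.25 s) is used with a
     warning. In rare finite-sample cases $SD2^2$ can go negative for
     strongly anti-correlated lags; the value is flagged and the window
     imputed rather than aborting a day-long run.
   * **LZC**, Lempel–Ziv complexity: the window is binarized at its median
     (the dominant parameter-free convention) and parsed with the LZ76
     exhaustive-history scheme (compiled code); the reported value is the
     normalised form $c(n)\log_2(n)/n$, which removes the dependence of
     the raw phrase count on window length.
   * **iCOH$_\theta$**: mean over theta-band bins of
     $|\Im(S_{xy}/\sqrt{S_{xx}S_{yy}})|$ from Welch auto-/cross-spectra.
     Using only the imaginary part makes the measure blind to zero-lag
     (volume-conducted) coupling.
   * **wSMI**: signals are resampled to 200 Hz (polyphase, anti-aliased —
     the 2/5 factor rules out plain decimation), mapped to ordinal
     patterns of $k = 3$ samples spaced $\tau = 8$ samples (so the pattern
     spans 80 ms, on the theta time scale), and the weighted symbolic
     mutual information is computed with natural logarithms and the
     $1/\log k!$ prefactor. The weight rule discards identical and
     rank-reversed symbol pairs — the standard choice for suppressing
     common-source coupling. Joint probabilities are raw co-occurrence
     frequencies; empty cells contribute zero.

4. **Normalisation and clustering.** Each feature column is min-max
   normalised over the whole recording (offline analysis; a streaming mode
   is out of scope). Missing windows are imputed by carrying the previous
   value forward. Two soft 2-cluster partitions are fitted:

   * **Fuzzy c-means** with fuzzifier $m = 2$, at most 1000 iterations,
     objective tolerance $10^{-5}$, seeded random membership
     initialisation (the seed is a configuration field and logged);
   * **Gaussian mixture** (full per-component covariances) by EM with the
     same iteration/tolerance settings, initialised from a seeded k-means
     partition.

   In each partition the **conscious cluster** is the one whose centroid
   has the larger mean over the seven normalised coordinates
   (operationalising the working hypothesis); an exact tie falls back to
   the larger $P_\beta$ coordinate, and a tie on both is treated as a
   degenerate clustering error. The **consciousness trace** is the
   membership degree to that cluster, and the final estimate is the
   element-wise mean of the FCM and GMM traces (average ensemble).
   A no-refit mode evaluates the FCM membership formula and GMM
   posteriors against user-supplied fixed parameters, for applying
   centres calibrated on a reference dataset to a new recording.

## The synthetic generator

Chronic clinical ECoG is not shareable, so the package ships a seeded
generator whose output exercises every pipeline stage. Each channel is
pink (1/f) background noise plus state-dependent components on a planted
schedule:

* **conscious** epochs add band-limited stochastic theta (2–4 Hz) and beta
  (15–25 Hz) oscillations shared across channels with a distinct lag per
  channel, plus private broadband noise. The lags make the shared rhythms
  visible to iCOH (which ignores zero-lag coupling) and keep ordinal
  patterns between channels related but not identical, which is what wSMI
  rewards; the broadband component raises LZC and ERR.
* **unconscious** epochs add a dominant *zero-lag* coherent sedation-like
  alpha rhythm (9–13 Hz) and a modest zero-lag slow wave (0.5–1.5 Hz),
  with little broadband noise. The zero lag makes the coupling invisible
  to iCOH and down-weighted by wSMI; the spectral concentration outside
  both scored bands keeps relative theta and beta power low and pulls the
  spectral edge down; the regularity lowers LZC and ERR.

A design note on the unconscious regime: classic slow-wave-dominated
unconsciousness would *raise* relative theta power (the theta band here
starts at 0 Hz), which would contradict the generator's documented
contract that conscious windows dominate on all seven features. The
alpha-dominated profile — a recognised electrographic pattern of deep
sedation — keeps the contract satisfiable, with the slow wave retained at
modest amplitude. Default gains (theta 2.0, beta 1.2, broadband 1.0
vs. alpha 2.5, slow 0.3, noise 0.15, on a common variance scale before the
overall 10-unit amplitude scale) are the package's "strong contrast"
conditions: chosen from the variance bookkeeping above so that each
feature separates in expectation, and fixed once. Optional "noisy"
channels are scaled by a multiplier that pushes them above the rejection
threshold.

What the generator does *not* emulate: biophysical dipole geometry,
electrode montage effects, drifting artefacts, sleep architecture, or any
behavioural paradigm. Passing the end-to-end test therefore shows that the
pipeline recovers a planted contrast of the documented kind — not that it
would classify real clinical states correctly.

## Numerical choices and problem sizes

* Welch sub-windows of 1/8 of a 1500-sample segment give a 2.67 Hz grid —
  coarse in the theta band, but identical to the source analysis
  convention; band sums include both edge bins.
* The FCM/GMM seeds, the generator seed, and the schedule fully determine
  a run; reruns are bit-identical, which the test suite asserts.
* Tests and the acceptance script run the full pipeline on a desk-scale
  fixture of two 10-minute 8-channel files with an alternating 5-minute
  schedule (1196 windows); the 24-hour, 64-channel geometry is exercised
  through the closed-form window arithmetic and a short 64-channel
  rejection fixture. These sizes are the package's validation choices;
  full-scale generation is available through the same configuration
  objects.
* Degenerate inputs are errors, not silent values: zero total power for
  relative power or the spectral edge, constant signals for ERR, all
  channels rejected, misaligned ensemble inputs, a constant feature column
  under min-max normalisation.

## Known limitations

* The consciousness level is relative to the recording's own feature
  range; min-max normalisation makes values incomparable across
  recordings without the pre-defined-parameter mode.
* With 2.67 Hz spectral resolution the theta band holds only two Welch
  bins; iCOH$_\theta$ is correspondingly coarse.
* The ensemble weighs FCM and GMM equally regardless of how informative
  each partition is; no thresholding of "conscious vs. unconscious" is
  attempted.
* The EDF codec covers continuous, uniform-rate EDF; EDF+ annotations and
  per-signal rates are not supported.
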