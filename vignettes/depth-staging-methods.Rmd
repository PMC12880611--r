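---
title: "Methods: unsupervised anesthetic-depth staging with DepthFCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised anesthetic-depth staging with DepthFCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DepthFCM)
```

## The problem

During general anesthesia the frontal EEG undergoes a reproducible spectral
shift: beta activity fades as consciousness is lost, alpha spindles emerge
over a growing delta background during adequate hypnosis, and delta comes to
dominate as anesthesia deepens. Proprietary depth indices (BIS, PSi) compress
this physiology into a single number whose failure modes are opaque.
DepthFCM instead stages hypnotic depth *unsupervised*: it clusters normalized
band-power features with Fuzzy C-Means (FCM) into three physiologically
interpretable states — `slight`, `proper` and `deep` — and reports, for every
30-second epoch, graded membership in each state rather than a crisp call.
The fuzzy memberships are the point: anesthetic depth is a continuum, and an
epoch midway between states should say so.

## Processing chain

1. **Ingestion** (`readEEG`): EDF or self-describing CSV; multi-channel
   frontal montages are reduced to one trace by the plain arithmetic mean
   (`toMono`). Averaging precedes filtering; with a linear filter the two
   orders are equivalent up to numerical noise, and averaging first does the
   cheap dimension reduction early.
2. **Artifact handling** (`autoArtifactMask`, `applyMask`): every sample
   whose absolute amplitude exceeds 300 µV (default) is flagged, padded by
   0.5 s and merged into rejection intervals. The default policy drops any
   analysis window overlapping a rejected interval — epoch-level exclusion,
   the conservative choice for spectral features — rather than interpolating.
3. **Filtering** (`bandpassFilter`): Butterworth bandpass 0.5–30 Hz, design
   order 4, applied forward–backward (`filtfilt`). Offline analysis has no
   causality constraint, so zero-phase filtering is the default: it preserves
   the timing of spectral transitions at the cost of squaring the magnitude
   response (a causal single pass is available via `zeroPhase = FALSE`).
4. **Windowing** (`makeEpochs`): 30-s windows advancing by 28 s, i.e. 2 s of
   overlap between consecutive windows. The step is a first-class parameter:
   a 2-s *step* (dense sliding) is an equally defensible reading of a
   "2-second sliding overlap", and `step_s = 2` reproduces it.
5. **Spectral estimation** (`welchPSD`): Welch averaged periodograms with 4-s
   Hann-tapered, constant-detrended segments at 50% overlap. 4 s gives
   0.25 Hz resolution — comfortably resolving the 0.5 Hz delta edge — while
   averaging ~14 segments per window keeps the estimator variance low.
   Density scaling is enforced: the PSD integrates to the signal variance
   (checked by a Parseval test).
6. **Features** (`extractFeatures`): band powers by trapezoidal integration
   of the PSD over delta (0.5–4 Hz), high-theta (6–8 Hz), alpha (8–12 Hz)
   and beta (13–30 Hz), each divided by the four-band sum. The 4–6 and
   12–13 Hz ranges are a deliberate *spectral buffer*: their power counts
   toward nothing, which removes the transitional zones that vary little
   across depth states. Closed-interval trapezoids tile exactly (the
   integral over [6,8] plus [8,12] equals that over [6,12]), so adjacent
   bands sharing the 8 Hz edge never double-count power. Every feature
   vector lies on the 4-simplex: components in [0,1] summing to 1, invariant
   to any rescaling of the PSD. Epochs with zero four-band power are
   degenerate and dropped with a logged count.

## The clustering model

FCM minimizes
$$J_m = \sum_{i=1}^{c}\sum_{k=1}^{n} u_{ik}^m \, \lVert x_k - v_i\rVert^2,
\qquad \sum_i u_{ik} = 1,$$
alternating the membership update
$u_{ik} = \big[\sum_j (d_{ik}/d_{jk})^{2/(m-1)}\big]^{-1}$ and the centroid
update $v_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m$. Defaults follow the
staging methodology: $c = 3$ clusters, fuzziness $m = 2$, Euclidean distance
in the normalized-ratio space, convergence when the membership matrix changes
by at most 0.005 (max absolute element; membership change is the standard
monitored quantity for FCM and is what the tests assert), random
initialization by drawing centroids as data rows, and 10 seeded restarts with
the lowest $J_m$ winning — restarts tame initialization sensitivity at
negligible cost. A point coinciding with a centroid receives membership
exactly 1 there (the standard degenerate-distance completion). $m \to 1^+$
recovers hard k-means; the suite checks this limit at $m = 1.05$.

The **global model** is fitted once on the pooled epochs of all recordings,
every epoch with equal weight, and is then *frozen*: per-subject staging
(`applyModel`) only evaluates memberships against the fixed centroids. This
separates the population-level definition of the three states from
subject-level trajectories through them.

**Feature space.** The default clustering space is the full 4-D ratio vector
(all four bands are informative); a 2-D projection — delta ratio against
alpha + high-theta ratio, with beta implied as the complement — is supported
both for visualization and as an alternative clustering space
(`feature_space = "paper2d"`).

**Labeling** (`assignDepthLabels`) is post hoc and physiological: the
centroid with the largest delta ratio is `deep` (delta dominance marks
cortical suppression); of the remaining two, the larger beta ratio is
`slight` (beta-rich light hypnosis); the third is `proper`. Ties within 1e-9
on a deciding coordinate abort labeling rather than guess. Hard labels for
display take the argmax membership, with exact ties broken toward `proper`,
then `deep` — preferring the clinically conservative middle state.

**Smoothing** (`smoothLabels`) is available (moving-average of membership
rows, renormalized, labels recomputed) but off by default: frame-by-frame
output maximizes temporal sensitivity, and smoothing has not been validated
against clinical endpoints here.

## The synthetic generator

`generateEEG` exists so every stage is testable without clinical recordings.
Each regime is a sum of four band-limited Gaussian oscillators (white noise
filtered into the delta, high-theta, alpha and beta bands — *processes*, not
sinusoids, so power spreads realistically across band edges and exercises
the buffer logic) over a 1/f pink-noise floor whose power is 10% of the
oscillator total, guaranteeing nonzero buffer-band power. Regime weights are
fixed module constants:

| regime | delta | high-theta | alpha | beta | RMS (µV) |
|--------|------:|-----------:|------:|-----:|---------:|
| light  | 0.15  | 0.10       | 0.20  | 0.55 | 20 |
| proper | 0.40  | 0.15       | 0.35  | 0.10 | 30 |
| deep   | 0.72  | 0.10       | 0.13  | 0.05 | 40 |

These were chosen analytically (`expectedRegimeFeature` adds each band's
share of the 1/f power to the oscillator weight and renormalizes) so the
expected delta ratios — about 0.18, 0.41 and 0.71 — are pairwise separated
by at least 0.2, and amplitudes grow with depth as they do physiologically.
Scenario scripts concatenate regime segments with linear cross-fades and can
inject high-amplitude Hann transients as artifacts; the generator is
deterministic given its seed and emits a per-sample ground-truth regime
track. A surrogate depth-index trace (`makePsiSurrogate`: plateau values 85
/ 50 / 25 with configurable lag and noise, clipped to [0,100]) supports the
report's index panel and alignment tests only — it never enters any
computation.

**What the generator does not emulate:** burst suppression, electromyographic
and cautery artifacts with realistic spectra, pharmacokinetic drug-effect
dynamics, non-stationarity within a state, or inter-subject spectral
variability. Passing the recovery tests therefore shows the pipeline is
internally correct and sensitive to the intended spectral physiology — not
that it is clinically validated.

## Numerical choices and degenerate inputs

- Filter design order 4 per edge (an 8th-order bandpass transfer function,
  the SciPy convention); verified numerically stable at 178 Hz under
  forward–backward application.
- Welch grids include both the 0 and Nyquist endpoints; band edges off the
  grid are handled by linear interpolation at the exact edge.
- All-zero epochs produce an identically-zero PSD, are flagged degenerate at
  feature extraction, and never reach the clusterer.
- Recordings shorter than one window yield zero epochs with a warning, not
  an error; a fully masked cohort aborts the fit with per-recording epoch
  accounting.
- FCM restarts that fail to reach tolerance within `max_iter` flag the model
  (`converged = FALSE`) with a warning instead of failing.
- Memberships are clamped to [0,1] against last-ulp floating-point
  overshoot; rows are verified to sum to 1 within 1e-9.

## Problem sizes in the validation suite

The test suite fits cohorts of three synthetic recordings of 30 minutes at
178 Hz (about 64 epochs each at the default step) across 10 seeds for the
regime-recovery check, and uses 100 Hz recordings of a few minutes
elsewhere; these sizes exercise every code path at full parameter fidelity
while keeping a complete run to a couple of minutes. The oracle-equivalence
check compares converged fits against `e1071::cmeans` (an independently
implemented FCM) on 20 random instances after greedy centroid matching,
at 1e-4.

## Known limitations

- Amplitude-threshold masking catches high-amplitude transients only; EMG
  contamination at EEG-like amplitudes passes through.
- The three-state model is fixed by design (`c = 3`); no cluster-count
  selection is attempted, and the fuzzy partition coefficient is exposed as
  a diagnostic only.
- Labeling assumes the three clusters actually differ in delta and beta
  character; on data without that structure it deliberately errors.
- EDF support covers continuous 16-bit recordings; EDF+ annotations and
  discontinuous files are out of scope.
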