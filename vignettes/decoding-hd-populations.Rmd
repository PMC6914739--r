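---
title: "Decoding head direction from small cell populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding head direction from small cell populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`decodeHD` compares statistical model-based decoders of head direction (HD)
on small simultaneously recorded HD-cell ensembles. This vignette is the
package's own account of the models it implements, the choices made where
the design was genuinely open, and what the synthetic benchmark does and
does not establish.

## The data model

A session consists of a tracked heading series $\phi(t)$ sampled at video
frame rate (30–60 Hz) and per-cell spike timestamp lists. Frames in which
tracking is lost carry a missing marker and are excluded from occupancy,
tuning curves and training. For decoding, time is divided into half-open
bins of width $\Delta$ (default **0.2 s**) producing a $T \times C$ count
matrix $Y$ and a per-bin heading (circular mean of member frames); bins
with more than half their frames lost are masked invalid. The 0.2 s default
matches the angular-velocity analysis bin; real recordings rarely pin a
canonical decoding bin, so it is a configuration parameter, as is whether
decoding uses all cells or only classified HD cells (default: HD cells).

Tuning curves use sixty 6° bins: rate = spikes / dwell time, with
unoccupied bins flagged undefined rather than imputed as zero. Heading
enters all decoders through its directional cosines
$X_t = [\cos\phi_t, \sin\phi_t]$, centralized by the training-set mean;
predictions return through the two-argument arctangent after adding that
mean back. Train/test splits are contiguous (UT: first 3/4 train; LT: last
3/4 train) because both the data and the state-space models are time
series; a held-out middle block would sever the training sequence.

## The synthetic generator

The generator defines the benchmark conditions:

* **Trajectory.** Angular velocity follows a discretized
  Ornstein–Uhlenbeck process with stationary SD `ang_vel_sd_degps`
  (default **80 °/s**) and time constant `ang_vel_tau_s` (default **1 s**);
  heading is its wrapped integral. An OU process rather than i.i.d. steps
  gives the velocity realistic autocorrelation at the 0.2-s analysis
  scale. The defaults produce a mean absolute angular velocity of roughly
  60 °/s in 0.2-s bins — bracketing values reported for foraging rodents,
  and above the ~40 °/s typical of goal-directed tasks — and cover all
  sixty 6° heading bins within a 10-minute session (asserted in the test
  suite).
* **Tuning.** Cells are von Mises-exponential:
  $r(\theta) = b + (p - b)e^{\kappa(\cos(\theta - \theta_0) - 1)}$. This
  shape is non-negative, peaks exactly at the preferred direction, and with
  $b = 0$ has log-rate exactly linear in $[\cos, \sin]$ — the Poisson GLM's
  observation model — which makes GLM parameter recovery a clean test. The
  true tuning shape of cortical HD cells is not settled; this choice is the
  package's, made for well-posedness of both the cosine fit and the
  log-linear model. Default peak rates are drawn from 10–40 spikes/s
  (within the 2–120 spikes/s range HD cells span), concentrations from
  $\kappa \in [2, 6]$, baseline 0.5 spikes/s.
* **Spikes.** Per video frame, a Poisson count with mean
  rate × frame interval, jittered uniformly within the frame. At ≤60 Hz
  frames and ≤120 spikes/s the within-frame rate variation is negligible,
  so this is an accurate inhomogeneous-Poisson realization without the
  machinery of time rescaling.
* **Populations.** Preferred directions are spread uniformly (with
  jitter) or confined to a sub-arc — the manipulation that exposes the
  vector methods' coverage failure. Flat ($\kappa = 0$) distractor cells
  test the classifier's false-positive rate.

What the generator does **not** emulate: conjunctive coding (egocentric
bearing, speed), anticipatory time shifts, non-Poisson firing
(bursting, refractoriness), electrode drift, and multimodal or asymmetric
tuning. Passing the synthetic benchmark therefore shows the pipeline's
internal consistency and each method's behaviour under its own assumptions;
it does not by itself establish rankings on real recordings.

## Classification

A cell is an HD cell when its mean vector length (rate-weighted circular
resultant over the 60-bin curve) **and** its four-quarter stability score
(mean of the six pairwise Pearson correlations between quarter-session
curves) both exceed the 95th percentile of a 400-iteration shuffle null.
Each iteration shifts the whole spike train circularly by a uniform offset
and recomputes both statistics jointly from the same shift — the reading we
take of a procedure that shifts "the neural data" once per iteration.
Choices worth recording:

* The minimum shift defaults to **20 s**; unconstrained shifts can be
  arbitrarily small and leak genuine tuning into the null.
* Null distributions are pooled across the cells of a dataset by default
  (one cutoff pair per dataset), matching per-region pooled cutoffs used
  with real recordings; per-cell cutoffs are available.
* Quarter-pair correlations use only bins occupied in both quarters, and a
  degenerate (zero-variance) pair is undefined rather than 1.0 — a flat
  cell must not inherit a perfect stability score.
* The sparse-firing variant (for parietal-style data) requires ≥250
  spikes, a Rayleigh test at $p \le 0.05$ with the standard grouped-data
  correction $(\delta/2)/\sin(\delta/2)$ applied to the 6°-binned
  resultant (the exact correction used with real data is not published;
  this is the textbook one), and a peak-bin shift < 7 bins between
  sessions or split halves.

Calibration is checked, not assumed: on 200 flat Poisson cells the
mean-vector-length cutoff passes 3–7% — the test's nominal type-I error.

## Decoders: numerical choices

* **KF.** Closed-form Gaussian MLE: $A$ and $H$ by least squares on the
  centralized series (no intercepts), $W, Q$ as residual covariances with
  MLE ($1/n$) normalization. The recursion starts at $x_0 = 0$ (the
  centralized mean) with $P_0 = W$ — unstated in most references; chosen
  so the filter's first prediction is the stationary-mean prior.
  A near-singular state moment matrix (heading covering too little of the
  circle) is an error advising more coverage, not a silent pseudo-inverse.
* **GLM.** Per-cell Poisson log-linear fits by IRLS run to convergence
  (relative deviance change < 1e-8, ≤100 iterations; non-convergence and
  zero-spike cells are errors naming the cell). The point-process filter
  uses the information-form update with rates evaluated at the predicted
  state, log-rates clipped at ±30 and the covariance symmetrized each step.
* **VR.** Cosine fit $b_0 + b_c\cos\theta + b_s\sin\theta$ over occupied
  tuning bins; the preferred-direction vector is the unit vector at phase
  $\mathrm{atan2}(b_s, b_c)$. Exactly flat cells are an error. Weights at
  prediction are instantaneous bin rates (unsmoothed).
* **OLE.** $L̂_c = \mathrm{mean}_t\, r_c(t) X_t$ (the occupancy-weighted
  tuning-curve center of mass) and $Q̂_{ij} = \mathrm{mean}_t\, r_i r_j$ —
  the uncentered second moment the least-squares derivation requires, with
  a Pearson-correlation variant available for sensitivity analysis. $Q̂$
  is ridge-regularized by $10^{-6}\,\mathrm{tr}(Q̂)/C$. The defining sum
  is read as $D̂_c = \sum_i (Q̂^{-1})_{ci} L̂_i$, i.e. $D = Q̂^{-1}L̂$, the
  standard optimal-linear-estimator solution.
* **WF/WC.** Zero lags by default (same-bin rates only); lag augmentation
  is available. Rank deficiency falls back to a small ridge with a
  warning. The cascade's polynomial order is selected over 1–5 by minimum
  validation MAE on the last quarter of the training span, then both
  stages are refitted on all training data; with five candidates an
  exhaustive search makes a surrogate-based optimizer pointless.
* **Degenerate readout.** A zero population vector (no cell fires) holds
  the last defined prediction, flagged; the first-bin fallback is the
  equal-weight population vector direction.

A geometric note on coverage: predictions of the population-vector family
are non-negative combinations of per-cell vectors, hence confined to those
vectors' conic hull. For VR the vectors are the preferred directions, so a
half-circle population yields predictions confined to that half-circle.
For the OLE the relevant cone belongs to the *optimal* vectors $D̂$, which
the inverse second-moment matrix generically pushes beyond the
preferred-direction arc (a deconvolution effect); OLE predictions are
therefore confined to the $D̂$ cone, not the preferred-direction arc. The
acceptance suite asserts exactly these two containments, and that both
methods' error rises sharply under half coverage.

Similarly, the scaled-STD tuning proxy (population SD of the
peak-normalized 60-bin curve) is **not** globally monotone in the von Mises
concentration: it rises from 0 (flat) to a maximum near $\kappa \approx 2$
and then declines as the normalized peak concentrates into fewer bins
(its one-hot limit is $\sqrt{59}/60 \approx 0.128$). Tests assert
monotonicity in the low-concentration regime and that any tuned cell
scores above a flat one.

## Statistics

The sequential factor-removal procedure runs a one-way repeated-measures
ANOVA (datasets as subjects; the standard within-subject decomposition, no
sphericity correction), removes the group whose mean is furthest from the
grand mean while the result is significant at $\alpha = 0.05$, and stops at
the first non-significant step. Unbalanced tables drop incomplete subjects
listwise, with the count reported. Factor regressions report Pearson r,
two-sided p and the least-squares slope per method; cell-level factors use
one designated cell per dataset (maximum spike count for response rate,
seeded random choice for tuning strength) to avoid resampling the same
decoding score.

## Problem sizes

The test suite's benchmark sizes are chosen to make each claim's
statistics decisive at desk scale: 10-minute sessions at 30 Hz (18,000
frames, 3,000 0.2-s bins) for end-to-end decoding; 20,000 bins for
maximum-likelihood recovery; toy instances of $T \le 50$, $C = 2$ for the
brute-force grid-filter oracles (65²–101² grid cells); 200 cells × 400
shuffles for classifier calibration; and 3–9-cell ensembles with three
replicates per size for the factor sweep.

## Limitations

The adapters for machine-learning decoders are deliberately thin: the
feedforward adapter has a single hidden layer with weight decay (not a
3-layer dropout network), and recurrent decoders are absent pending an R
backend — they raise a capability error rather than a degraded
approximation. No 2-D position decoding, no anticipatory-time-shift
compensation, and no mixed-effects extensions of the factor analyses are
provided.
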