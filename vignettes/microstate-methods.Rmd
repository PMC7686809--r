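---
title: "Microstate segmentation and moderated regression: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate segmentation and moderated regression: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstates)
```

## The scientific problem

Resting-state EEG alternates between brief (~50–100 ms) periods during which
the scalp topography stays quasi-stable — microstates. Classically four
classes (MS1–MS4, also called A–D) recur and are interpreted as signatures of
large-scale networks (auditory/semantic, visual, salience/cingulo-opercular,
frontoparietal attention). Their temporal parameters — mean **duration**,
**occurrence** rate, time-coverage **contribution**, and directed
**transition probabilities** — summarize network dynamics in 24 numbers per
subject. This package implements the full chain from raw multichannel EEG to
those 24 parameters, and a second stage that relates them to a behavioral
trait (a creativity total) with a second trait (self-esteem) as moderator,
including the inference machinery that moderation analyses need: incremental
\(\Delta R^2\) F tests, simple slopes, Johnson–Neyman regions, and
Benjamini–Hochberg FDR over the 24-test family.

Because raw data for the motivating study design are not publicly deposited,
the package also ships a synthetic-data module that generates
microstate-structured EEG and behavioral cohorts with *known* ground truth.
Every stage is verified against that ground truth rather than against
irreproducible numbers.

## Segmentation model

For a scalp map \(v(t)\) over \(N\) channels the global field power is the
spatial standard deviation
\(\mathrm{GFP}(t) = \sqrt{\tfrac1N \sum_i (v_i(t) - \bar v(t))^2}\).
Topographic signal-to-noise is maximal at GFP peaks, so only peak maps enter
clustering. Spatial similarity between maps is polarity-invariant absolute
spatial correlation \(|C|\); the equivalent dissimilarity is
\(\mathrm{GMD} = \sqrt{2(1-C)}\).

Clustering is classic atomize–agglomerate hierarchical clustering (AAHC):
every peak map starts as its own cluster; the cluster contributing least
explained variance (\(\sum_{m \in c} (\mathrm{GFP}_m \, |C_m|)^2\)) is
dissolved and its members reassigned to the surviving cluster of highest
\(|C|\). A cluster's template is the dominant eigenvector of the
outer-product sum of its member maps — the polarity-invariant mean — with the
sign fixed so the largest-magnitude channel is positive. All ties resolve to
the lowest index, which makes the procedure deterministic given the input
order.

The number of templates is chosen by the classical cross-validation
criterion
\[
\mathrm{CV}(K) = \hat\sigma^2 \left(\frac{N-1}{N-1-K}\right)^2 ,
\qquad
\hat\sigma^2 = \frac{\sum_m \left(\|u_m\|^2 - (T_{k(m)}^\top u_m)^2\right)}
                    {M\,(N-1)},
\]
with \(u_m\) the mean-removed peak maps and \(T_{k(m)}\) each map's
best-matching template. Lower is better; the penalty makes CV rise once
extra templates stop reducing residual variance.

Fit quality is the global explained variance
\(\mathrm{GEV} = \sum_t (\mathrm{GFP}(t)\, C_{t})^2 / \sum_t
\mathrm{GFP}(t)^2\).

After group templates are fixed (two-level subject-then-group clustering by
default; single-level pooling via `level = "pooled"`), **every** sample of
every kept epoch is labeled with its best template by \(|C|\) (backfitting).
No temporal smoothing and no minimum-duration rule are applied — the
backfit label sequence is exactly what the statistics see. Runs truncated at
epoch edges are counted; this preserves the identity
\(c_k = o_k d_k / 1000\) exactly and avoids discarding data in 2-s epochs.
Transition probabilities condition on leaving a state (rows are normalized
over observed departures); the raw count matrix is also returned.

## Preprocessing defaults

* 4th-order Butterworth band-pass, 2–20 Hz, applied forward–backward
  (zero phase) after removing each channel's mean. Microstate boundaries are
  defined by topography timing, so zero phase matters.
* Common-average reference; GFP is reference-shift invariant, labeling is
  not, so re-referencing precedes everything topographic.
* Consecutive non-overlapping 2000-ms epochs from sample 1; any epoch with a
  sample exceeding ±80 µV is rejected automatically. The rejection is
  per-epoch absolute amplitude (not peak-to-peak) — a deliberate,
  reproducible stand-in for manual artifact screening. Independent component
  analysis is intentionally absent: it is not reproducible from a method
  description, and the simulated data carry no structured artifacts.

No EDF/BrainVision/FIF readers are bundled: the package operates on its own
in-memory `eeg_recording` objects plus plain-text CSV/JSON persistence, and
expects upstream conversion for vendor formats.

## The synthetic-data generator

`simulate_subject_eeg()` draws a semi-Markov state sequence: dwell times are
gamma distributed (shape 2 by default, so durations are unimodal with a mode
above zero, unlike a geometric law) with per-state means of 80 ms, and the
next state follows a configurable transition-weight row (zero diagonal).
Within a run the signal is
\(\mathrm{env}(t)\,\sin(2\pi f_\alpha t + \varphi_{\mathrm{run}})\times
T_{\mathrm{state}}\) with \(f_\alpha = 10\) Hz: the topography is stable
while its signed amplitude oscillates, so GFP peaks occur at ~20 per second
and map polarity alternates every half-cycle — the clustering *must*
disregard polarity to recover anything. We use the signed rather than a
rectified oscillation deliberately: a rectified envelope concentrates its
spectrum at twice the alpha frequency and above (20, 40, 60 Hz), i.e. at and
beyond the 2–20 Hz band edge, and the band-pass then smears topographies
across run boundaries badly enough to corrupt template recovery. The signed
tone keeps the simulated signal inside the analysis band, which is also what
makes it a fair test of the segmentation stage rather than of filter
artifacts. Spatially white Gaussian noise is added to a target
signal-to-noise ratio (RMS ratio, default 3) and the signal RMS is scaled to
10 µV.

Templates are smooth zero-mean unit-norm maps built from Gaussian bumps on a
deterministic sunflower-spiral layout of the unit disc; the default four
mimic the canonical microstate orientations (two mirrored diagonals, a
midline-symmetric anterior–posterior gradient, a fronto-central focal map)
and satisfy pairwise \(|C| \le 0.7\). There is no forward-modelled volume
conduction and no dipole geometry — recovery results show the algorithms
work, not that real scalp fields look like this.

`simulate_cohort()` perturbs the dwell means and transition weights per
subject with log-normal multipliers (sd 0.2), yielding a continuous spread
of *true* microstate parameters computed in closed form from each subject's
configuration: the embedded-chain stationary distribution \(\pi\) gives
occurrence \(\pi_k / \sum_j \pi_j m_j\) and contribution
\(\pi_k m_k / \sum_j \pi_j m_j\) (with \(m_j\) the mean dwell), durations are
the dwell means, and transitions the row-normalized weights. The behavioral
score is
\(\mathrm{WCTS} = b_0 + b_1 X_c + b_2 W_c + b_3 X_c W_c + b_{\mathrm{sex}}
\mathrm{sex} + b_{\mathrm{age}} \mathrm{age}_c + \varepsilon\),
with \(X_c\) the mean-centered true parameter and \(W_c\) the mean-centered
self-esteem total. Coefficients apply to *centered* variables — that is how
the moderation model is fit, and it makes the crossover point of a
disordinal interaction (\(w = -b_1/b_3\)) interpretable in sd units of the
moderator. Cohort defaults describe an undergraduate sample: 72% male, age
18.3 ± 0.84 years, self-esteem total 28.37 ± 2.81 on the 10–40 scale (the
mean and sd are back-derived from published region-of-significance anchors:
boundaries at raw scores 27 and 30 reported as mean − 0.486 sd and
mean + 0.580 sd solve to sd = 3/1.066 ≈ 2.81, mean ≈ 28.37). Scale totals
are truncated to their legal ranges (creativity 50–150, self-esteem 10–40)
by resampling the residual, never by clipping, so no point mass accumulates
at the bounds. The creativity residual sd defaults to 10 scale points — the
distribution of such totals is not published, so this is a free,
documented choice. Subscale scores split the total in proportion to item
counts (12/13/13/12 of 50) with mild jitter.

What the generator does *not* emulate: ocular/muscle artifacts, volume
conduction, electrode noise correlations, non-stationary alpha power, or any
dependence of EEG dynamics on the behavioral covariates beyond the planted
effect. Passing tests therefore demonstrate algorithmic correctness and
statistical calibration, not field realism.

## Moderation layer

Behavioral screening drops subjects whose creativity or self-esteem total
deviates more than 3 sd from the full-sample mean (single pass). The
moderated model is explicit OLS — `Y ~ Xc + Wc + Xc:Wc + sex + age` with
predictor and moderator mean-centered before the product — and the
interaction is tested by
\(F = \Delta R^2 (n-6) / (1 - R^2_{\mathrm{full}})\) on \((1, n-6)\) df.
Standardized \(\beta\) comes from refitting with z-scored outcome, predictor
and moderator (covariates raw); conventions for \(\beta\) differ across
software, so the package documents this one and reports raw coefficients
alongside. Simple slopes at moderator values \(w\) use
\(b_1 + b_3 w\) with \(\mathrm{SE}^2 = s_{11} + 2 w s_{13} + w^2 s_{33}\);
Johnson–Neyman boundaries solve \((b_1+b_3w)^2 = t^2_{\mathrm{crit}}
\mathrm{SE}^2(w)\) analytically, are reported only within the observed
moderator range (with \(\le/\ge\) boundary inclusion for the sample
percentages), and degenerate cases (vanishing quadratic coefficient, no real
roots) fall back to the linear solution or to an everywhere/nowhere verdict
from the slope test at the range midpoint. FDR control is Benjamini–Hochberg
over the 24-test family — exactly the family of the standard reporting
table; with that family size the published corrected values (e.g. an
uncorrected 0.002 becoming 0.024) are reproduced to the printed precision.
Sex is coded 0/1 (the coding only shifts the intercept).

## Numerical and design choices

* **Ties** everywhere go to the lowest index (labels, cluster dissolution,
  reassignment, CV ties to the smaller k): determinism over elegance.
* **Template sign**: largest-|value| channel positive. Signs are otherwise
  meaningless under polarity invariance.
* **Peak cap**: clustering cost is quadratic in the number of peak maps, so
  a per-subject cap (default 5000, seeded uniform subsample) bounds it; a
  6-min recording at ~20 GFP peaks/s plus noise-driven peaks yields well
  above that.
* **Canonical ordering**: a k = 4 group set is named MS1–MS4 by solving the
  4×4 assignment problem on \(|C|\) against built-in archetypes exactly
  (dynamic programming over column subsets), not greedily.
* **Flat maps** (GFP = 0) are labeled state 1 with correlation 0 rather than
  erroring mid-pipeline; similarity between flat maps is an error because it
  is genuinely undefined.
* **Two-level clustering** (subject templates, then AAHC over the pooled
  subject templates) is the default, mirroring the usual group-study
  practice and producing a per-subject GEV spread; single-level pooling is
  one flag away.
* **Caching**: `run_pipeline()` hashes the configuration; re-runs into the
  same output directory reuse the per-subject statistics when the hash
  matches, and results are bit-identical either way.

## Problem sizes used in the shipped verification

The test-suite and acceptance-script simulations are sized to be decisive
yet quick: template-recovery checks use one full 6-minute subject at SNR 3
(≈5000 peak maps) plus a 60-s noiseless subject; model-selection frequency
uses twenty 60-s subjects; null calibration of the interaction test uses
5000 cohorts of n = 335 (the design's degrees of freedom, (1, 329)); oracle
comparisons (normal equations, grid-search Johnson–Neyman, brute-force BH)
use 100-replicate batches. The CV model-selection checks run on
average-referenced raw simulations: the synthetic signal is already
band-limited, and the band-pass filter's edge ringing at state switches
creates real mixture topographies that keep lowering residual variance as k
grows — a known sensitivity of the CV criterion worth remembering with real
data too. Template recovery is verified through the full filtered path.

## Known limitations

* The CV criterion's optimum is sensitive to residual structure near the
  band edge (above); corroborating k with GEV saturation is advisable.
* AAHC is deterministic but order-dependent in principle; the shipped
  implementation fixes all tie-breaks, so identical inputs give identical
  outputs.
* The moderation layer is single-level OLS: no bootstrap, no mediation, no
  multilevel structure.
* Transition "probabilities" are conditional on departure; with few runs per
  epoch the per-row counts can be small, and rows with no departures are
  reported as zeros and must not be read as structural zeros.
* Microstate syntax beyond first-order transitions (entropy rates,
  higher-order dependence) is out of scope.
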