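---
title: "Longitudinal EEG trend features for MCI progression prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal EEG trend features for MCI progression prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegtraj)
```

## The problem

Amnestic mild cognitive impairment (aMCI) converts to Alzheimer's disease at
roughly 10–15% per year. Resting-state EEG shows three robust macroscopic
signatures along that trajectory: a shift of spectral mass from fast to slow
rhythms ("slowing"), a loss of signal complexity, and a loss of long-range
phase synchrony, particularly in the alpha band. A single EEG snapshot
captures a patient's position on these axes but not their *velocity*.
`eegtraj` implements a pipeline that quantifies the trajectory itself:
cross-sectional features are extracted from three repeated recordings (months
0, 4 and 8), each feature's short trajectory is summarised by six trend
descriptors, and the resulting feature table is fed to standard classifiers
to predict the one-year outcome (stable, SMCI, vs progressive, PMCI).

Because no public dataset accompanies this design, the package ships a
synthetic cohort generator that reproduces the *statistical structure* the
method assumes. All quantitative claims in the test suite are claims about
that synthetic structure, not about clinical data; see "What the synthetic
cohort does and does not show" below.

## Pipeline stages and their parameters

### Preprocessing

Automated stages, in a fixed order: common-average re-reference → zero-phase
FIR band-pass (0.1–70 Hz) → FIR notch (50 ± 2 Hz) → anti-aliased integer
downsampling to 250 Hz → selection of one contiguous 30 s segment.

All filters are Hamming-windowed sinc designs (`signal::fir1`) applied
forward–backward per channel, so no stage introduces group delay. Filter
order follows the transition-bandwidth rule `n ≈ 3.3 fs / Δf` with the low
transition set to `lo/5`, capped at a third of the series length; on 30–60 s
recordings a 0.1 Hz edge therefore realises a gentler roll-off than the
nominal design, which we accept rather than ringing the filter at lengths
comparable to the data. Human-in-the-loop steps of clinical practice (bad
channel interpolation, examiner epoch screening, ICA artifact removal) are
deliberately **not** implemented; the `"lowest_peak"` segment strategy — the
window whose worst-channel absolute amplitude is smallest — is a documented
automated proxy for manual quiet-segment selection.

### Spectral features (160 per recording)

Welch PSD (2 s Hann segments, 50% overlap → 0.5 Hz resolution at 250 Hz;
both parameters configurable), integrated over the conventional bands delta
0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz by the trapezoidal
rule. Trapezoidal integration is additive across shared band edges, so the
five powers tile the 0.5–45 Hz axis without double counting. From the band
powers, five slowing ratios per channel:

$$R_1 = \frac{\delta}{\alpha},\quad R_2 = \frac{\theta}{\alpha},\quad
R_3 = \frac{\delta}{\alpha+\beta},\quad R_4 = \frac{\theta}{\alpha+\beta},\quad
R_5 = \frac{\delta+\theta}{\alpha+\beta+\gamma}$$

and, per band, the Shannon entropy of the normalised in-band PSD bins
(natural log, so the maximum is $\ln N_\text{bins}$ for a flat in-band
spectrum). Entropy bins are taken on the closed interval `[lo, hi]`: on the
0.5 Hz grid the alpha band has 11 bins and the flat-spectrum maximum is
$\ln 11$. Ratios and entropies are invariant to amplitude scaling of the raw
signal, which is why no absolute-power features are included.

### Nonlinear features (48 per recording)

*Permutation entropy* (PE): entropy of ordinal patterns of embedded windows,
normalised by $\ln(m!)$. Defaults $m = 3$, $\tau = 1$: with 7,500 samples per
segment the $3! = 6$ pattern frequencies are estimated with negligible bias,
and $\tau = 1$ makes PE a local-irregularity measure. Rank ties are broken
by temporal order (a stable ranking), a choice that matters only for
quantised signals.

*Sample entropy* (SE): $-\ln(A/B)$ with template length $m = 2$, Chebyshev
distance, strict tolerance $r = 0.2\,\mathrm{SD}$, self-matches excluded.
Both counts use the same $N - m$ template set so $A/B$ is a conditional
probability. Pair counting is $O(N^2)$ and runs in compiled code
(~0.15 s per 30 s channel); an optional `se_window_s` averages SE over
non-overlapping sub-windows for very long recordings (off by default). If
$A = 0$ or $B = 0$ the value is reported as an explicit undefined-entropy
error, never silently as `NaN` or `Inf`.

*M-DCPSR*: the series is delay-embedded in three dimensions and the median
Euclidean distance of embedded points from their centroid is returned — a
robust scale/spread summary of the reconstructed attractor. The delay comes
from the first zero crossing of the normalised autocorrelation. The printed
crossing rule selects the **larger**-|R| side of the crossing (for a 10 Hz
rhythm at 250 Hz this yields τ = 7 rather than 6); we implement that rule
verbatim as the default and expose `delay_rule = "nearest_zero"` as the
conventional alternative, because silently "correcting" a published rule
would make results irreproducible against it. The delay is estimated per
channel per recording; if no crossing occurs within `N/2` lags (e.g. strong
drift) the delay falls back to `fs/10` samples with a warning.

### Connectivity features (120 per recording)

Alpha-band phase lag index (PLI) for all 120 channel pairs:
$\mathrm{PLI} = |\langle \operatorname{sign} \sin(\phi_x - \phi_y)\rangle|$,
with phases from the Hilbert analytic signal of the 8–13 Hz zero-phase
filtered channels and one second trimmed at each end against edge
transients. PLI is 0 for absent coupling *and* for coupling at 0 or π
(volume-conduction-like), 1 for perfect locking at any other lag, and is
amplitude-invariant. A published variant that folds the absolute phase
difference into $[0, 2\pi)$ before taking the sign is available as
`variant = "as_printed"`, but it saturates near 1 for any input — including
independent signals — so the standard estimator, which reproduces both
stated boundary cases, is the default.

### Longitudinal descriptors (6 × 328 = 1,968 per subject)

For each feature's three-point trajectory $X(t)$ at months $\{0, 4, 8\}$:
mean (MF), sample SD (SDF), range (RF = max − min), trapezoidal area under
the trajectory (AF), and the mean (MVF) and sample SD (SDVF) of the two
consecutive-interval slopes $(X(t+1) - X(t))/4$ in units per month. Two
printed-source ambiguities are resolved as follows: the range formula is
typographically garbled at its source and is implemented as max − min, the
standard dispersion reading; and "mean of three slope values" conflicts with
the two consecutive intervals that three time points admit — the default is
formula-faithful (two slopes), with `include_span_slope = TRUE` adding the
month-0→8 slope as a third value. AF over three points is the sum of two
trapezoids; with a strictly positive feature it is positive. Subjects missing
any of timepoints 1–3 are dropped (complete-case analysis, no imputation);
timepoint 4 defines the outcome label only and never enters the predictors.

### Selection, classification, evaluation

Inside every CV training fold, and only there: features are standardised by
the training mean/SD, the two-group ANOVA F statistic (equal to the squared
pooled t) is computed per feature on training rows, and the top 100 by
descending F (ties broken by canonical column order) are retained. Eight
classifiers are evaluated under stratified 5-fold CV repeated 10 times
(fold partitions re-drawn with seed `base + repeat`), i.e. 50 test folds;
reported mean ± SD aggregate over the 50 folds, with undefined fold metrics
(empty denominators) excluded and counted. The "default settings" of a
commercial toolbox cannot be pinned down exactly, so each classifier is
fixed to an explicit configuration: linear SVM (C = 1), fully grown
CART/Gini tree, Gaussian naive Bayes, pooled-covariance LDA, discrete
AdaBoost with 100 exhaustive-search decision stumps, 1-NN (Euclidean, with a
nearest-positive/nearest-negative distance-ratio score so AUC is
non-degenerate), random forest (100 trees, √P candidate splits), and
unpenalised logistic regression. AUC uses the rank-sum formula with average
ranks for ties, which equals exhaustive positive–negative pair counting.
Group comparisons at single timepoints use the two-sided Mann–Whitney U test
per feature, uncorrected at α = 0.05 by default (Benjamini–Hochberg
available via `adjust = "BH"`).

## The synthetic cohort

Each channel is a sum of: per-band zero-phase-filtered Gaussian noise with
group-by-timepoint amplitude multipliers and mild anterior–posterior
topographic gradients (alpha strongest occipitally); a shared alpha-band
source injected into every channel with a fixed per-channel phase offset
($2\pi c/17$, constant across the band via the analytic signal), weighted by
the coupling coefficient $\kappa \in [0,1]$ in a variance-preserving mix with
channel-private alpha noise; a deterministic quasi-periodic component (two
incommensurate tones in the slow range, and another pair in the fast range)
replacing a $\rho$-fraction of the stochastic variance; and a $1/f$ noise
floor that carries the same $\sqrt{1-\rho}$ weight as the other stochastic
terms, since it is the dominant driver of sample-to-sample irregularity.
Raising $\kappa$ raises alpha-band PLI (≈0.06 at $\kappa = 0$, ≈0.98 at
$\kappa = 1$ on 30 s epochs); raising $\rho$ lowers PE and SE; band
multipliers move the ratios and PSDE; total variance changes move M-DCPSR.
Complexity is thus manipulated *mechanistically* (a mixing weight toward a
deterministic component), never by targeting an entropy value, so the
entropy features remain emergent checks of the generator rather than fitted
quantities.

The default schedule encodes the study conditions: 38 stable and 27
progressive subjects, four equidistant visits, groups statistically
identical at timepoints 1–2 and diverging at 3–4. No effect sizes are
published for the underlying clinical trends, so the default magnitudes are
the package's own calibration, chosen once as plausible for a high-risk
referral cohort and not tuned afterwards: at timepoints 3/4 the progressive
group's delta/theta amplitudes rise by 35%/55% and alpha/beta/gamma fall by
25%/35%, $\kappa$ falls 0.55 → 0.25 and $\rho$ rises 0.25 → 0.55, while the
stable group drifts mildly in the same directions (±5–10%). Between-subject
heterogeneity is a per-subject, per-band log-normal amplitude multiplier
(SD 0.1 on the log scale, constant over time). Generation is at 250 Hz by
default (the post-downsampling rate) with a 500 Hz mode to exercise the
downsampler, and every epoch is a deterministic function of the
configuration and seed.

### What passing tests do and do not show

The generator emulates second-order structure (band powers, coupling,
regularity) and their group-by-time evolution. It does **not** simulate
artifacts (blinks, EMG, electrode pops), non-stationarity within a
recording, realistic volume conduction from a head model, medication or
vigilance effects, or label noise in the clinical outcome. Consequently the
near-perfect classifier performance on the default synthetic cohort shows
that the pipeline *recovers programmed trajectory divergence without
leaking test information* (the label-permutation control sits at chance,
and a null schedule classifies at chance through the entire pipeline) — it
is not evidence about accuracy on clinical recordings, where reported
performance of this design must come from the clinic.

## Numerical choices and degenerate inputs

* Errors are typed conditions (`eegtraj_invalid_config`,
  `eegtraj_invalid_input`, `eegtraj_insufficient_data`,
  `eegtraj_degenerate_input`, `eegtraj_undefined_entropy`); degenerate
  statistics are reported as errors or `NA`, never propagated as `NaN`.
* PSD ratio denominators of zero (all-zero alpha band, etc.) raise a
  degenerate-input error.
* `sign(0)` contributes 0 to the PLI mean (standard convention).
* The autocorrelation-delay result is clamped to ≥ 1 sample: the printed
  rule would otherwise return lag 0 (a degenerate embedding) whenever the
  first crossing occurs at lag 1, since $|R(0)| = 1$ dominates.
* Stratified folds are used even though the source is silent on
  stratification: with 27 positives in 65 subjects, unstratified 5-fold CV
  regularly produces folds where SEN/SPE are undefined.
* F-statistic ties (including ±Inf from zero within-group variance) are
  broken by canonical column order, making selection fully deterministic.

## Problem sizes used by the shipped checks

The test suite exercises unit-level properties on seconds-long epochs and
the cohort-level properties on the full 65-subject design with 12 s epochs;
`scripts/acceptance.R` re-runs the pipeline at the full study conditions
(65 subjects × 3 predictor visits × 30 s × 250 Hz, repeated 10 × 5-fold CV).
The programmed group contrasts are properties of the generating
distribution, not of epoch length; epoch length mainly sets the estimation
noise of individual features. These sizes are stated here so that reported
numbers can be reproduced exactly.

## Known limitations

* Only integer decimation factors are supported in `downsample()`.
* The 0.1 Hz band-pass edge on short recordings is realised with a capped
  filter order (see above).
* PE/SE defaults ($m$, $\tau$, $r$) follow common EEG practice; the source
  publication leaves PE's parameters unstated, and results do depend on
  them. They are exposed in `feature_config()`.
* No linear mixed models, weighted PLI, multiscale entropy, hyperparameter
  tuning or nested CV: all are out of scope by design.
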