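---
title: "Measuring work-instruction cognitive load: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring work-instruction cognitive load: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogload)
```

## The problem

Assembly operators receive work instructions in different formats. Intuitive
visual step-by-step pictures are assumed to impose little extraneous
cognitive load; abstract coded instructions (colour/position/contact codes)
must be deciphered and are assumed to load working memory. `cogload`
implements a complete measurement pipeline for a counterbalanced
within-subject study of this contrast: each participant provides a resting
physiological baseline and then completes two timed assembly sessions, one
per instruction format, building two six-piece block patterns at least three
times each. Cognitive load is measured subjectively (NASA-TLX, short DSSQ)
and objectively (heart-rate variability from a PPG channel, skin conductance,
wrist acceleration); operational efficiency is measured by the number of task
repetitions (NTR), the task completion time (TCT) and marker-based assembly
precision.

Because raw recordings from such studies are rarely public, the package
treats the synthetic-study generator as a first-class module: it produces
signals, questionnaire responses and trial records with known ground truth,
which is what every downstream stage is validated against.

## Signal preprocessing

PPG channels carry a DC level and low-frequency trend that defeat naive peak
detection. The pipeline is mean correction (`removeDC`), Savitzky-Golay
detrending (`detrendSavGol`), then local-maximum pulse detection
(`detectPeaks`) and conversion of peak times to inter-beat (RR) intervals in
milliseconds (`peaksToRR`). All signals are cut into contiguous 60-second
windows (`segmentWindows`); a trailing partial window is discarded so every
spectral estimate rests on equal support, and an RR interval belongs to the
window containing its *terminal* peak, so each interval is counted exactly
once.

Numerical choices worth knowing:

* The Savitzky-Golay smoother (whose output is *subtracted*) uses a window of
  about 3 s (`2 * round(1.5 * fs) + 1` samples) and polynomial order 3. We
  measured the band response: this choice removes more than 95% of sub-0.1 Hz
  drift power while perturbing power at a 1.25-Hz pulse by less than 10%. A
  2-s window, though a natural first guess, amplifies the pulse band by over
  30% through sidelobe ripple and was rejected.
* Peak detection uses a minimum inter-peak distance of 0.33 s (caps heart
  rate at 180 bpm) and a topographic-prominence floor of 30% of the signal's
  amplitude IQR. Both are exposed as arguments.
* Windows do not overlap by default; `stride` allows overlapped segmentation
  if a study needs more windows.

## Skin-conductance decomposition

Skin conductance is modelled as `SC = SC_tonic + SC_phasic`, with the phasic
part generated by a sparse, nonnegative sudomotor driver convolved with the
biexponential Bateman kernel `k(t) = exp(-t/tau2) - exp(-t/tau1)`
(`batemanKernel`, defaults `tau = (1, 3.75)` s, unit peak). `cdaDecompose`
performs continuous decomposition analysis in two stages:

1. a coarse tonic estimate — a smooth curve through the 10th percentile of
   consecutive 10-s blocks;
2. ridge-regularized nonnegative deconvolution of `SC - tonic` against the
   kernel, followed by re-estimation of the tonic through inter-impulse
   sections (samples where the provisional phasic is negligible) and a second
   deconvolution. The re-estimate uses linear interpolation between block
   medians: with few quiet blocks a cubic spline can overshoot and absorb
   response amplitude into the tonic.

The deconvolution solves `min ||K x - y||^2 + lambda ||x||^2, x >= 0` with a
Lawson-Hanson active-set iteration on the Toeplitz normal equations; the Gram
matrix is generated from the kernel autocorrelation on demand, and the active
set is capped (the steepest-gradient columns — the actual SCR impulses —
enter first, so the cap only curtails diffuse baseline fitting). The solver
is verified in the test suite against an independent general-purpose NNLS
implementation. Work happens at a decimated 25-Hz rate (configurable) and
components are interpolated back to the acquisition rate; the tonic component
is finally defined as `SC - phasic` so the decomposition reconstructs the
input exactly. `lambda` defaults to `1e-3`.

SCR events (`detectSCRs`) are phasic local maxima whose rise from the
preceding trough reaches `minAmplitude` (default 0.01 uS, the conventional
threshold); rise time runs onset-to-peak and decay time peak-to-next-trough.
Events closer than about 2 s merge into one — the identifiability limit of
the kernel, not of the solver.

## Features

Per 60-s segment the pipeline computes:

* **19 HRV features** — RMSSD, MEAN, MEDIAN, SDRR, SDSD, SDRR_RMSSD, HR,
  PNN25, PNN50, Poincare SD1/SD2, kurtosis and skewness of the RR
  distribution, and band powers VLF (0.003-0.04 Hz), LF (0.04-0.15 Hz),
  HF (0.15-0.4 Hz), TP, with LF/HF and HF/LF ratios. RMSSD uses the standard
  estimator `sqrt(sum(d^2)/(N-1))`; a variant placing `N-1` outside the
  radical exists in some reports and is available behind
  `rmssdVariant = "printed"`, but it is dimensionally inconsistent with
  typical RMSSD magnitudes and is not the default. Spectra come from
  cubic-spline resampling of the tachogram at 4 Hz, mean removal, and a
  Hann-tapered periodogram; on a 60-s window the VLF band lies below the
  resolvable frequency range and is reported only for completeness.
  Kurtosis is non-excess (normal = 3); SDs use the n-1 convention
  throughout.
* **9 GSR features** — trapezoidal areas under the phasic and full SC
  curves, SCR count, mean rise and decay times (0 when no event), Shannon
  entropy of a 16-bin amplitude histogram (bits), SDs of SC and phasic, and
  the total periodogram power of the phasic component.
* **24 accelerometer features** — mean, median, SD, min, max and range for
  X, Y, Z and the per-sample resultant. The range completes the six-per-axis
  count deterministically.

`buildFeatureTable` assembles these into a `SummarizedExperiment`
(features x segments, labels in `colData`); `featureFrame` flattens it for
modelling. Physiology-only tables have 28 feature columns, 52 with
accelerometry.

## Questionnaires and precision

NASA-TLX is scored in raw (RTLX) mode by default — the unweighted mean of
the six subscales — with the pairwise-weighted mode available when weights
were collected; published summary scores are reproducible under either, and
raw mode needs no extra inputs. The performance subscale is *kept in the
workload direction* for scoring; `reversePerformanceForDisplay` flips it for
radar charts only. Short-DSSQ states (engagement, distress, worry) are sums
of eight pre-coded 0-4 items, hence 0-32.

Assembly precision compares the `choose(n, 2)` pairwise Euclidean distances
between piece-marker centers of a constructed pattern with the reference
pattern: the per-trial score is the sample SD of the signed deviations
`observed - reference`, averaged over the trials of a session. The all-pairs
set is parameter-free and the statistic is invariant to any rigid motion or
reflection of the whole assembly — only placement error counts. Signed
deviations (rather than absolute) preserve systematic compression or
expansion of the build. Units follow the coordinates (pixels by default);
camera calibration is out of scope.

## The statistical battery

Paired session contrasts (`pairedCompare`) gate on a Shapiro-Wilk test of
the paired differences at alpha = 0.05: normal-looking differences get the
paired t-test with Cohen's d (`mean(d)/sd(d)`); otherwise the Wilcoxon
signed-rank test with the matched rank-biserial correlation. The Wilcoxon
implementation uses Pratt's treatment of zero differences, mid-ranks for
ties, no continuity correction, and an exact enumeration of all `2^n` sign
assignments for up to 10 nonzero differences (the tie/zero-corrected normal
approximation beyond). The first-listed condition is the minuend, so effect
sizes are negative when the second condition scores higher.

The three-session DSSQ comparisons use a one-way repeated-measures ANOVA
(`rmAnova`). Mauchly's test (Box's two-term chi-square approximation, the
same used by the classical multivariate-linear-model treatment) gates the
Huynh-Feldt correction: when sphericity is rejected at 0.05 both F degrees
of freedom are multiplied by the Huynh-Feldt epsilon (capped into
`[1/(k-1), 1]`, never below Greenhouse-Geisser). Post-hoc analysis runs all
pairwise gated paired tests with Holm adjustment by default (Bonferroni and
none are available); simple paired tests rather than pooled-error contrasts
match the reporting style of paired effect sizes.

## Condition classification

`fitLogistic` fits binary (`glm`) or multinomial (`nnet::multinom`) logistic
models of the session label on z-scored features, with an explicit reference
class (the baseline session in the canonical layout). Fit quality is the
likelihood-ratio chi-square against the intercept-only null on
`(classes - 1) x predictors` degrees of freedom (`lrDf`). Backward
elimination (`backwardEliminate`) starts from all candidates and removes the
least-contributing feature while its removal p-value exceeds 0.10. The
default removal criterion is the drop-one likelihood-ratio test. We chose it
over per-feature Wald tests deliberately: strong condition effects
quasi-separate the classes at realistic segment counts, and under separation
Wald standard errors diverge (the Hauck-Donner effect) so every Wald p-value
approaches 1 and the elimination would discard even perfect predictors.
Separation is additionally detected and flagged on the fit. Metrics
(`evaluateModel`) are accuracy and macro-averaged precision/recall in
percent, reported in-sample by default — mirroring the canonical reporting —
with stratified k-fold (selection refit inside each fold) as the honest
companion; neither is claimed to reproduce any particular study's numbers.

## The synthetic-study generator

`simulateStudy(studyConfig(...))` emulates the full protocol: four
counterbalanced subgroups crossing instruction order with pattern
allocation, a 3-minute baseline, sessions of nominally 5 minutes extended
until each assigned pattern is repeated three times (`TCT =
max(300 s, time of the required repetition)`), per-repetition assembly
trials, and per-session questionnaire responses. One master seed spawns one
deterministic substream per participant, so studies are reproducible and
participants independent.

Generator components and their defaults:

* **PPG** — one asymmetric Gaussian pulse per beat (only peak times matter
  downstream), DC offset 2, a low-frequency trend of three sinusoids below
  0.1 Hz, white noise. RR tachograms combine condition-specific mean/SD with
  0.1-Hz and 0.25-Hz modulation so LF and HF bands are populated.
* **GSR** — tonic level near 2 uS with a slow random walk over 30-s knots,
  SCR events as a Poisson process at a condition-specific rate with
  log-normal amplitudes (median 0.3 uS), convolved with the Bateman kernel.
* **Accelerometer** — 1 g gravity on Z plus one damped-oscillation burst per
  task repetition and sensor noise.
* **Questionnaires** — truncated normals within scale bounds; published
  summary means/SDs are the only distributional information available for
  such studies, so the shipped defaults
  (`defaultConditionEffects()`) use overall cognitive load 39.84 (SD 13.74)
  for the visual condition vs 57.24 (SD 14.71) for code, and the
  corresponding DSSQ state means per time point. TLX subscales scatter with
  SD 10 around a participant-level latent load; DSSQ items allocate the
  latent state score across the eight items.
* **Performance** — repetition durations are log-normal (medians 32 s visual
  vs 84 s code, sigma 0.3), which makes NTR and TCT *emerge* from the
  protocol rule rather than being drawn directly; placement noise is
  isotropic Gaussian per piece (SD 2.0 px visual vs 1.4 px code) on top of a
  random rigid motion of the whole assembly, which the precision metric must
  ignore.

What the generator does *not* emulate: realistic PPG morphology (dicrotic
notch), motion artifacts coupling the movement and physiological channels,
within-participant correlation between questionnaire sessions, or
learning-curve trends across repetitions. Passing recovery tests therefore
demonstrates that the pipeline measures what the model injects — not that
real recordings are this clean.

## Problem sizes used in validation

The shipped tests validate: driver recovery on 60-s skin-conductance
fixtures at 25 Hz (position within one working-rate sample, impulse mass
within 10%, reconstruction exact to machine precision); sign recovery of all
injected condition effects on twenty independent 30-participant
questionnaire/performance studies; type-I calibration of the gated paired
test over 10,000 null replicates (half normal, half heavy-tailed); RM-ANOVA
power above 80% for a d = 0.8 shift at n = 30 over 200 replicates; and the
full physiological feature path on studies of 2-8 participants at 25-50 Hz
with 2-3-minute sessions, where class separation is already essentially
complete. These sizes were chosen as the smallest that make the properties
sharp; every stage scales linearly in recording length.

## Known limitations

* The CDA tonic estimator is intentionally simple (percentile grid +
  inter-impulse re-estimate). On recordings with dense overlapping SCRs the
  tonic can absorb phasic mass; the residual diagnostic on the
  `SCDecomposition` object is the guard.
* VLF power on 60-s windows is not interpretable (reported for table
  compatibility only).
* In-sample classification metrics on segment rows ignore the within-
  participant dependence of segments; the k-fold scheme stratifies by class,
  not by participant.
* The 19 + 9 = 28 physiological feature columns are what the extractors
  define; reports that count 29 presumably include a duplicated or derived
  column whose identity is not recoverable, so both 28- and 52-column tables
  are first-class here and the discrepancy is documented rather than
  resolved. Legacy names `spectralEnergy`/`bandPower` are treated as aliases
  of the phasic band-power feature in the packaged selected-feature table.
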