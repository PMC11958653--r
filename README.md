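# cogload

Does the *format* of an assembly work instruction change what it costs the
operator? `cogload` is an R package for within-subject studies that compare
intuitive **visual** step-by-step instructions against abstract **code-based**
instructions (colour/position/contact codes) in a timed block-assembly task,
measuring cognitive load both subjectively and physiologically and relating
it to operational efficiency. It is written for human-factors and
psychophysiology researchers who need the full measurement chain — from raw
wearable signals to corrected p-values — as tested, scriptable code.

## What it computes

**Physiology.** PPG is mean-corrected, Savitzky–Golay detrended, and pulse
peaks are converted to RR intervals; skin conductance is decomposed as
`SC = SC_tonic + SC_phasic` by continuous decomposition analysis (CDA):
ridge-regularized *nonnegative* deconvolution of the conductance against the
biexponential Bateman kernel `k(t) = e^{-t/τ₂} − e^{-t/τ₁}` (τ = 1, 3.75 s)
recovers a sparse sudomotor driver. Per 60-s window the package extracts
19 HRV features (RMSSD, SDRR, SDSD, pNN25/50, Poincaré SD1/SD2, VLF/LF/HF/TP
band powers, ratios, …), 9 electrodermal features (SCR areas, counts,
rise/decay times, entropy, band power) and 24 accelerometer statistics,
assembled into a labelled `SummarizedExperiment`.

**Behaviour.** NASA-TLX overall cognitive load (raw or pairwise-weighted),
short-DSSQ engagement/distress/worry (0–32), number of task repetitions,
task completion time, and assembly precision — the sample SD of
observed-minus-reference pairwise Euclidean distances between piece-marker
centers, invariant to rigid motion of the whole build (lower = more
precise).

**Statistics.** Shapiro–Wilk-gated paired tests (Student + Cohen's d, or
Wilcoxon signed-rank with Pratt zeros, exact for n ≤ 10, matched
rank-biserial effect size); one-way repeated-measures ANOVA with Mauchly's
sphericity test and the Huynh–Feldt correction; Holm-adjusted post-hoc
pairs; and condition classification by binary/multinomial logistic
regression with backward elimination, likelihood-ratio χ² on
`(classes − 1) × predictors` df, and accuracy / macro precision / recall.

**Synthetic studies.** `simulateStudy()` generates complete counterbalanced
studies (signals, questionnaires, repetition schedules, placement trials)
with known ground truth, which is how every stage is validated.

## Worked example

```r
library(cogload)

cfg     <- studyConfig(nParticipants = 30, includeSignals = FALSE, seed = 7)
study   <- simulateStudy(cfg)
scores  <- questionnaireScores(study)
perf    <- performanceMetrics(study)
battery <- statsBattery(scores, perf)

aggregate(cbind(cl, distress) ~ session, scores, \(x) round(mean(x), 2))
#>   session    cl distress
#> 1    code 62.65    11.73
#> 2  visual 36.50     7.93

aggregate(cbind(ntr, tctMin, precisionSd) ~ session, perf, \(x) round(mean(x), 2))
#>   session  ntr tctMin precisionSd
#> 1    code 6.00   8.42        1.85
#> 2  visual 9.17   5.00        2.55

battery$paired[, c("measure", "shapiroP", "test", "effectSize", "pValue")]
#>                          measure shapiroP                 test effectSize   pValue
#>  cognitive load (visual vs code)   0.2494       student-paired      -1.56 2.10e-09
#>             ntr (visual vs code)   0.0127 wilcoxon-signed-rank       1.00 1.35e-06
#>          tctMin (visual vs code)   0.6087       student-paired      -3.58 2.82e-18
#>     precisionSd (visual vs code)   0.6051       student-paired       2.50 3.43e-14
```

Reading the output: code-based instructions raise mean cognitive load
(62.7 vs 36.5; the negative effect size means the second-listed condition
scored higher) and distress, and triple the completion-time gap
(8.4 vs 5.0 min) while pinning most participants at the minimum six
repetitions — yet assembly *precision* is better under code (SD 1.85 vs
2.55 px), the speed/accuracy trade-off the pipeline is built to expose. The
repeated-measures branch reports, per DSSQ state, the Mauchly p-value,
whether Huynh–Feldt df-correction was applied, the (corrected) ANOVA
p-value, and Holm-adjusted pairwise effects:

```r
battery$anova$distress
#> distress: Mauchly p = 0.109, correction = none, RM-ANOVA p = 0.00613
#>                    pair effectSize pAdjusted
#>       pre vs postVisual      0.576    0.0111
#>         pre vs postCode     -0.115    0.5325
#>  postVisual vs postCode     -0.515    0.0172
```

With `includeSignals = TRUE` the same study carries raw PPG/GSR/accelerometer
channels; `buildFeatureTable()` then produces the segment-level feature
matrix and `classificationBattery()` fits the four condition classifiers
(multinomial with baseline reference, plus the three binary contrasts).

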