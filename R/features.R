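#' Spectral band edges for heart-rate variability
#'
#' Standard short-term HRV bands: very low frequency 0.003-0.04 Hz, low
#' frequency 0.04-0.15 Hz, high frequency 0.15-0.4 Hz.
#'
#' @return Named list with components `vlf`, `lf`, `hf`, each `c(lo, hi)` Hz.
#' @export
hrvBands <- function() {
  list(vlf = c(0.003, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4))
}

## moment-based skewness / kurtosis; kurtosis is non-excess (normal = 3)
momentSkew <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}
momentKurt <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2
}

#' Time-domain HRV features
#'
#' Computes the time-domain and distributional descriptors of an RR series:
#' RMSSD (`sqrt(sum(diff^2) / (N - 1))`), MEAN, MEDIAN, SDRR, SDSD (sample
#' SDs), SDRR_RMSSD, HR (`60000 / MEAN` bpm), PNN25/PNN50 (percentage of
#' successive differences exceeding 25/50 ms), kurtosis (non-excess) and
#' skewness.
#'
#' @param rr an [RRSeries-class] with at least 2 intervals (4 or more
#'   recommended for the moment statistics).
#' @param rmssdVariant `"standard"` puts `N - 1` under the radical;
#'   `"printed"` divides the root of the sum by `N - 1` (a dimensionally
#'   inconsistent variant kept for comparability).
#' @return Named numeric vector of 13 features.
#' @export
hrvTimeFeatures <- function(rr, rmssdVariant = c("standard", "printed")) {
  stopifnot(is(rr, "RRSeries"))
  rmssdVariant <- match.arg(rmssdVariant)
  x <- rr@rr
  n <- length(x)
  if (n < 2L) stop("at least 2 RR intervals are required")
  d <- diff(x)
  rmssd <- switch(rmssdVariant,
    standard = sqrt(sum(d^2) / (n - 1)),
    printed  = sqrt(sum(d^2)) / (n - 1))
  m <- mean(x)
  c(RMSSD = rmssd,
    MEAN = m,
    MEDIAN = stats::median(x),
    SDRR = stats::sd(x),
    SDSD = stats::sd(d),
    SDRR_RMSSD = if (rmssd > 0) stats::sd(x) / rmssd else NA_real_,
    HR = 60000 / m,
    PNN25 = 100 * sum(abs(d) > 25) / (n - 1),
    PNN50 = 100 * sum(abs(d) > 50) / (n - 1),
    KURT_RR = momentKurt(x),
    SKEW_RR = momentSkew(x))
}

#' Poincare-plot descriptors SD1 and SD2
#'
#' Short- and long-term variability from the Poincare plot of successive RR
#' pairs: `SD1 = sqrt(0.5) * SDSD` and `SD2 = sqrt(2 * SDRR^2 - 0.5 * SDSD^2)`
#' (floored at zero).
#'
#' @param rr an [RRSeries-class] with at least 3 intervals.
#' @return Named numeric `c(SD1, SD2)` in ms.
#' @export
hrvPoincare <- function(rr) {
  stopifnot(is(rr, "RRSeries"))
  x <- rr@rr
  if (length(x) < 3L) stop("at least 3 RR intervals are required")
  sdsd <- stats::sd(diff(x))
  sdrr <- stats::sd(x)
  c(SD1 = sqrt(0.5) * sdsd,
    SD2 = sqrt(max(0, 2 * sdrr^2 - 0.5 * sdsd^2)))
}

#' Frequency-domain HRV features
#'
#' Cubic-spline interpolation of the RR tachogram onto a uniform grid
#' (default 4 Hz), mean removal, Hann-tapered periodogram, and band-power
#' integration over the VLF/LF/HF edges. Total power integrates 0.003-0.4 Hz.
#' On 60-s windows the VLF band sits below the resolvable frequency range;
#' it is reported for completeness but should not be interpreted.
#'
#' @param rr an [RRSeries-class] (at least 8 intervals spanning >= 30 s).
#' @param bands band edges as produced by [hrvBands()].
#' @param resampleFs uniform resampling rate, Hz.
#' @return Named numeric `c(VLF, LF, HF, TP, LF_HF, HF_LF)`; powers in ms^2.
#'   When `HF` (or `LF`) is zero the corresponding ratio is `NA` rather than
#'   infinite.
#' @export
hrvSpectral <- function(rr, bands = hrvBands(), resampleFs = 4) {
  stopifnot(is(rr, "RRSeries"))
  x <- rr@rr
  pt <- rr@peakTimes[-1L]
  if (length(x) < 8L) stop("at least 8 RR intervals are required")
  if (diff(range(rr@peakTimes)) < 30) stop("RR span must be at least 30 s")
  grid <- seq(min(pt), max(pt), by = 1 / resampleFs)
  u <- stats::spline(pt, x, xout = grid)$y
  u <- u - mean(u)
  n <- length(u)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))   # Hann
  uw <- u * w
  ## one-sided periodogram scaled so that the band integral has units ms^2
  sp <- Mod(stats::fft(uw))^2 / (sum(w^2) * resampleFs)
  freq <- (seq_len(n) - 1L) * resampleFs / n
  half <- freq <= resampleFs / 2
  sp <- 2 * sp[half]; freq <- freq[half]
  df <- resampleFs / n
  bandPow <- function(b) sum(sp[freq >= b[1] & freq < b[2]]) * df
  vlf <- bandPow(bands$vlf); lf <- bandPow(bands$lf); hf <- bandPow(bands$hf)
  tp <- bandPow(c(bands$vlf[1], bands$hf[2]))
  c(VLF = vlf, LF = lf, HF = hf, TP = tp,
    LF_HF = if (hf > 0) lf / hf else NA_real_,
    HF_LF = if (lf > 0) hf / lf else NA_real_)
}

#' All 19 HRV features for one segment
#'
#' Convenience wrapper assembling the time-domain, Poincare and spectral
#' feature blocks into the canonical 19-element vector (RMSSD, MEAN, MEDIAN,
#' SDRR, SDSD, SDRR_RMSSD, HR, PNN25, PNN50, SD1, SD2, KURT_RR, SKEW_RR,
#' VLF, LF, HF, TP, LF_HF, HF_LF).
#'
#' @inheritParams hrvTimeFeatures
#' @inheritParams hrvSpectral
#' @return Named numeric vector of length 19.
#' @export
hrvFeatures <- function(rr, bands = hrvBands(),
                        rmssdVariant = c("standard", "printed")) {
  tf <- hrvTimeFeatures(rr, rmssdVariant = match.arg(rmssdVariant))
  pc <- hrvPoincare(rr)
  sf <- hrvSpectral(rr, bands)
  out <- c(tf[c("RMSSD", "MEAN", "MEDIAN", "SDRR", "SDSD", "SDRR_RMSSD",
                "HR", "PNN25", "PNN50")],
           pc, tf[c("KURT_RR", "SKEW_RR")], sf)
  stopifnot(length(out) == 19L)
  out
}

#' Shannon entropy of an amplitude histogram
#'
#' @param x numeric values.
#' @param nBins histogram bin count (default 16).
#' @return Entropy in bits. A constant signal has entropy 0.
#' @export
shannonEntropy <- function(x, nBins = 16) {
  if (diff(range(x)) == 0) return(0)
  h <- tabulate(cut(x, breaks = nBins, labels = FALSE), nbins = nBins)
  p <- h[h > 0] / sum(h)
  -sum(p * log2(p))
}

#' Segment-level skin-conductance features
#'
#' The nine electrodermal descriptors of one 60-s segment: trapezoidal areas
#' under the phasic (SCR) and full SC curves, SCR count, average rise and
#' decay times, Shannon entropy of the SC amplitude histogram, sample SDs of
#' SC and phasic, and the summed periodogram power of the phasic component.
#' When no SCR is detected the rise/decay averages are 0 by convention.
#'
#' @param decomp an [SCDecomposition-class] restricted to the segment.
#' @param events SCR table from [detectSCRs()] for the same segment.
#' @return Named numeric vector of 9 features: `AreaSCR`, `AreaGSR` (uS*s),
#'   `No_Peakes`, `AvgRiseTime`, `AvgDecayTime` (s), `Entropy` (bits),
#'   `STDGSRdata`, `STDSCRdata` (uS), `BandPower` (uS^2).
#' @export
gsrFeatures <- function(decomp, events) {
  stopifnot(is(decomp, "SCDecomposition"))
  if (length(decomp@sc) < 2L) stop("segment is empty")
  dt <- 1 / decomp@fs
  trap <- function(v) sum((v[-1] + v[-length(v)]) / 2) * dt
  ph <- decomp@phasic
  nEv <- nrow(events)
  ## total periodogram power of the phasic component
  phc <- ph - mean(ph)
  bp <- sum(Mod(stats::fft(phc))^2) / length(phc)^2
  c(AreaSCR = trap(ph), AreaGSR = trap(decomp@sc),
    No_Peakes = as.numeric(nEv),
    AvgRiseTime = if (nEv) mean(events$riseTime) else 0,
    AvgDecayTime = if (nEv) mean(events$decayTime) else 0,
    Entropy = shannonEntropy(decomp@sc),
    STDGSRdata = stats::sd(decomp@sc),
    STDSCRdata = stats::sd(ph),
    BandPower = bp)
}

#' Segment-level accelerometer features
#'
#' Six summary statistics (mean, median, sample SD, min, max, range) per
#' axis and for the per-sample resultant `sqrt(x^2 + y^2 + z^2)`: 24 values.
#'
#' @param sig a [TriaxialSignal-class] segment.
#' @return Named numeric vector of 24 features (`meanX` ... `rangeR`).
#' @export
accelFeatures <- function(sig) {
  stopifnot(is(sig, "TriaxialSignal"))
  if (length(sig@x) == 0L) stop("empty accelerometer segment")
  axes <- list(X = sig@x, Y = sig@y, Z = sig@z,
               R = sqrt(sig@x^2 + sig@y^2 + sig@z^2))
  out <- unlist(lapply(names(axes), function(a) {
    v <- axes[[a]]
    stats::setNames(
      c(mean(v), stats::median(v), stats::sd(v), min(v), max(v),
        max(v) - min(v)),
      paste0(c("mean", "median", "std", "min", "max", "range"), a))
  }))
  stopifnot(length(out) == 24L)
  out
}

#' Build the labelled segment-level feature table
#'
#' Runs the full physiological pipeline over every participant x session of a
#' study: PPG mean correction, Savitzky-Golay detrending, peak detection and
#' RR extraction; skin-conductance smoothing and continuous decomposition;
#' 60-s segmentation; per-segment HRV (19), GSR (9) and optionally
#' accelerometer (24) features. Segments without enough beats (or, with a
#' stricter threshold, enough intervals for the spectral features) are
#' dropped; participants contributing no valid segment are excluded with a
#' warning.
#'
#' @param study a study list from [simulateStudy()] or [readStudy()].
#' @param includeAccel include the 24 accelerometer features (default FALSE,
#'   giving a 28-column table; TRUE gives 52).
#' @param windowS segmentation window, seconds.
#' @param scrMinAmplitude SCR detection threshold, uS.
#' @param rmssdVariant see [hrvTimeFeatures()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `features` (features x segments) and colData columns `participant`,
#'   `session` (one of `baseline`, `visual`, `code`), `windowIndex`.
#' @export
buildFeatureTable <- function(study, includeAccel = FALSE, windowS = 60,
                              scrMinAmplitude = 0.01,
                              rmssdVariant = "standard") {
  rows <- list(); meta <- list()
  for (p in names(study$participants)) {
    part <- study$participants[[p]]
    nBefore <- length(rows)
    for (sess in names(part$sessions)) {
      rec <- part$sessions[[sess]]
      if (is.null(rec$ppg) || is.null(rec$gsr)) next
      ppgClean <- detrendSavGol(removeDC(rec$ppg))
      decomp <- cdaDecompose(smoothGaussian(rec$gsr))
      segsP <- segmentWindows(ppgClean, windowS)
      nSeg <- length(segsP)
      if (!nSeg) next
      for (i in seq_len(nSeg)) {
        segP <- segsP[[i]]
        pk <- detectPeaks(segP)
        if (isTRUE(attr(pk, "insufficient")) || length(pk) < 9L) next
        rr <- peaksToRR(pk)
        hv <- tryCatch(hrvFeatures(rr, rmssdVariant = rmssdVariant),
                       error = function(e) NULL)
        if (is.null(hv)) next
        a <- attr(segP, "tStart"); b <- attr(segP, "tEnd")
        idx <- seq.int(round(a * decomp@fs) + 1L, round(b * decomp@fs))
        idx <- idx[idx <= length(decomp@sc)]
        segD <- new("SCDecomposition", sc = decomp@sc[idx],
                    tonic = decomp@tonic[idx], phasic = decomp@phasic[idx],
                    driver = decomp@driver[idx], fs = decomp@fs,
                    tau = decomp@tau, residual = decomp@residual,
                    converged = decomp@converged)
        gv <- gsrFeatures(segD, detectSCRs(segD, scrMinAmplitude))
        feats <- c(hv, gv)
        if (includeAccel) {
          segsA <- segmentWindows(rec$accel, windowS)
          if (length(segsA) < i) next
          feats <- c(feats, accelFeatures(segsA[[i]]))
        }
        rows[[length(rows) + 1L]] <- feats
        meta[[length(meta) + 1L]] <-
          data.frame(participant = p, session = rec$condition, windowIndex = i)
      }
    }
    if (length(rows) == nBefore)
      warning("participant ", p, " contributed no valid segment; excluded")
  }
  if (!length(rows)) stop("no valid segments in study")
  mat <- t(do.call(rbind, rows))
  cd <- do.call(rbind, meta)
  colnames(mat) <- sprintf("seg%04d", seq_len(ncol(mat)))
  rownames(cd) <- colnames(mat)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    colData = S4Vectors::DataFrame(cd))
}

#' Extract the feature table as a data frame
#'
#' Transposes the feature assay into the tidy segments-x-features layout the
#' statistics and classification layers consume, with the segment labels
#' attached.
#'
#' @param ft a `SummarizedExperiment` from [buildFeatureTable()].
#' @return A `data.frame` with one row per segment: `participant`, `session`,
#'   `windowIndex`, then the feature columns.
#' @export
featureFrame <- function(ft) {
  mat <- t(SummarizedExperiment::assay(ft, "features"))
  cd <- as.data.frame(SummarizedExperiment::colData(ft))
  cbind(cd, as.data.frame(mat))
}
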