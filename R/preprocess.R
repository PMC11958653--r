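#' Remove the DC offset from a signal
#'
#' Subtracts the signal mean so the output oscillates around zero, the first
#' step before detrending and pulse-peak detection.
#'
#' @param sig a [RawSignal-class] object.
#' @return A `RawSignal` with zero-mean samples; all metadata preserved.
#' @examples
#' s <- RawSignal(sin(1:100 / 5) + 3.2, fs = 50)
#' abs(mean(samples(removeDC(s)))) < 1e-12
#' @export
removeDC <- function(sig) {
  stopifnot(is(sig, "RawSignal"))
  if (length(sig@samples) == 0L) stop("signal is empty")
  initialize(sig, samples = sig@samples - mean(sig@samples))
}

#' Savitzky-Golay detrending
#'
#' Removes slow trend by subtracting a Savitzky-Golay smooth of the signal
#' (the smoother passes the sub-0.1 Hz trend, so the residual keeps the ~1 Hz
#' pulse content). Window defaults to about three seconds of samples, which
#' keeps sub-0.1 Hz residual power below 5% while perturbing the pulse band
#' by under 10%.
#'
#' @param sig a [RawSignal-class] object.
#' @param windowLength odd filter window length in samples
#'   (default about `3 * fs`, rounded to odd).
#' @param polyOrder polynomial order (default 3), must be `< windowLength`.
#' @return A `RawSignal` containing `signal - smoothed(signal)`.
#' @export
detrendSavGol <- function(sig, windowLength = NULL, polyOrder = 3) {
  stopifnot(is(sig, "RawSignal"))
  n <- length(sig@samples)
  if (is.null(windowLength)) windowLength <- 2 * round(1.5 * sig@fs) + 1
  windowLength <- as.integer(windowLength)
  if (windowLength %% 2L == 0L) stop("windowLength must be odd")
  if (polyOrder >= windowLength) stop("polyOrder must be < windowLength")
  if (windowLength > n) stop("windowLength must be <= signal length")
  trend <- signal::sgolayfilt(sig@samples, p = polyOrder, n = windowLength)
  initialize(sig, samples = sig@samples - trend)
}

## Topographic prominence of local maxima: height above the higher of the two
## minima separating the peak from the nearest higher ground on each side.
peakProminence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[seq_len(p - 1L)]
    hi <- which(left > x[p])
    lmin <- if (length(hi)) min(x[(max(hi) + 1L):(p - 1L)]) else min(c(left, x[p]))
    right <- x[seq.int(p + 1L, length(x))]
    hi <- which(right > x[p])
    rmin <- if (length(hi)) min(x[(p + 1L):(p + min(hi) - 1L)])
            else min(c(right, x[p]))
    x[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect pulse peaks in a cleaned PPG signal
#'
#' Local-maximum search on a mean-corrected, detrended signal with a minimum
#' inter-peak distance (default 0.33 s, i.e. at most 180 bpm) and a
#' topographic-prominence floor expressed as a fraction of the signal's
#' amplitude interquartile range.
#'
#' @param sig a detrended, mean-corrected [RawSignal-class].
#' @param minDistance minimum spacing between accepted peaks, seconds.
#' @param prominenceFrac minimum prominence as a fraction of `IQR(samples)`.
#' @return Numeric vector of strictly increasing peak times (seconds,
#'   including `startTime`). If fewer than two peaks are found the vector is
#'   returned as-is with attribute `insufficient = TRUE` so callers can flag
#'   the segment.
#' @export
detectPeaks <- function(sig, minDistance = 0.33, prominenceFrac = 0.3) {
  stopifnot(is(sig, "RawSignal"))
  x <- sig@samples
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand)) {
    prom <- peakProminence(x, cand)
    keep <- prom >= prominenceFrac * stats::IQR(x)
    cand <- cand[keep]
    prom <- prom[keep]
    ## greedy: keep highest-prominence peaks subject to the distance floor
    minGap <- minDistance * sig@fs
    ord <- order(prom, decreasing = TRUE)
    sel <- integer()
    for (i in ord) {
      if (!length(sel) || all(abs(cand[sel] - cand[i]) >= minGap))
        sel <- c(sel, i)
    }
    cand <- sort(cand[sel])
  }
  times <- sig@startTime + (cand - 1L) / sig@fs
  if (length(times) < 2L) attr(times, "insufficient") <- TRUE
  times
}

#' Convert peak times to an RR series
#'
#' Successive differences of the detected peak times, scaled to milliseconds.
#'
#' @param pt strictly increasing peak times in seconds (at least two).
#' @return An [RRSeries-class] with `N = length(pt) - 1` intervals.
#' @examples
#' rrIntervals(peaksToRR(c(0, 0.8, 1.6)))  # 800 800
#' @export
peaksToRR <- function(pt) {
  if (length(pt) < 2L) stop("at least two peaks are required")
  RRSeries(rr = 1000 * diff(pt), peakTimes = pt)
}

#' Fixed-window segmentation
#'
#' Cuts a signal, triaxial signal or RR series into contiguous,
#' non-overlapping windows of `windowS` seconds (default 60 s). A partial
#' trailing window is discarded so every segment has equal support. RR
#' intervals are assigned to the window containing their terminal peak.
#'
#' @param x a [RawSignal-class], [TriaxialSignal-class] or [RRSeries-class].
#' @param windowS window length in seconds.
#' @param stride distance between window starts in seconds; defaults to
#'   `windowS` (non-overlapping).
#' @return A list of segments. Each element carries attributes
#'   `windowIndex`, `tStart`, `tEnd` and holds an object of the same class as
#'   `x` restricted to the window. Returns an empty list when the input is
#'   shorter than one window.
#' @export
segmentWindows <- function(x, windowS = 60, stride = windowS) {
  stopifnot(windowS > 0, stride > 0)
  ## RR windows are anchored at session time 0 so they line up with the
  ## signal windows; intervals follow the window of their terminal peak
  t0 <- if (is(x, "RawSignal")) x@startTime else 0
  total <- if (is(x, "RRSeries")) max(x@peakTimes) - t0 else duration(x)
  if (total < windowS) return(list())
  starts <- seq(0, total - windowS, by = stride)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    a <- t0 + starts[i]; b <- a + windowS
    seg <- if (is(x, "RawSignal")) {
      idx <- seq.int(round((a - t0) * x@fs) + 1L, round((b - t0) * x@fs))
      initialize(x, samples = x@samples[idx], startTime = a)
    } else if (is(x, "TriaxialSignal")) {
      idx <- seq.int(round((a - t0) * x@fs) + 1L, round((b - t0) * x@fs))
      TriaxialSignal(x@x[idx], x@y[idx], x@z[idx], x@fs)
    } else {
      ## terminal-peak rule: interval i belongs to the window holding peak i+1
      term <- x@peakTimes[-1L]
      keep <- which(term >= a & term < b)
      if (length(keep) < 1L) NULL else {
        pts <- x@peakTimes[c(keep[1], keep + 1L)]
        RRSeries(x@rr[keep], pts)
      }
    }
    if (!is.null(seg)) {
      attr(seg, "windowIndex") <- i
      attr(seg, "tStart") <- a
      attr(seg, "tEnd") <- b
      out[[i]] <- seg
    }
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Gaussian smoothing for skin-conductance signals
#'
#' Fixed Gaussian-kernel smoother used before decomposition (the adaptive
#' filter of GUI tools is replaced by a reproducible kernel with tunable
#' width).
#'
#' @param sig a [RawSignal-class].
#' @param sigma kernel standard deviation in seconds (default 0.2 s).
#' @return A smoothed `RawSignal` of the same length (edges handled by
#'   kernel renormalization).
#' @export
smoothGaussian <- function(sig, sigma = 0.2) {
  stopifnot(is(sig, "RawSignal"), sigma > 0)
  m <- ceiling(4 * sigma * sig@fs)
  k <- stats::dnorm(seq(-m, m), sd = sigma * sig@fs)
  x <- sig@samples
  num <- stats::convolve(x, rev(k), type = "open")[(m + 1):(m + length(x))]
  den <- stats::convolve(rep(1, length(x)), rev(k),
                         type = "open")[(m + 1):(m + length(x))]
  initialize(sig, samples = num / den)
}
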