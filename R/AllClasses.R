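#' @import methods
NULL

#' Uniformly sampled single-channel signal
#'
#' Container for a uniformly sampled physiological time series, typically a
#' photoplethysmogram (arbitrary units) or a skin-conductance recording
#' (microsiemens), together with its sampling rate and channel tag.
#'
#' @slot samples numeric vector of sample values.
#' @slot fs sampling rate in Hz.
#' @slot channel one of `"ppg"`, `"gsr"`, `"other"`.
#' @slot startTime time of the first sample in seconds.
#'
#' @seealso [RawSignal()] for the constructor, [samples()], [samplingRate()].
#' @export
setClass("RawSignal",
  representation(samples = "numeric", fs = "numeric",
                 channel = "character", startTime = "numeric"),
  prototype(channel = "other", startTime = 0))

setValidity("RawSignal", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "samples must be non-empty")
  if (!object@channel %in% c("ppg", "gsr", "other"))
    msg <- c(msg, "channel must be 'ppg', 'gsr' or 'other'")
  if (length(msg)) msg else TRUE
})

#' Triaxial accelerometer signal
#'
#' Wrist-worn accelerometer recording with three equal-length axes sampled at
#' a common rate.
#'
#' @slot x,y,z numeric per-axis acceleration (g).
#' @slot fs sampling rate in Hz.
#' @export
setClass("TriaxialSignal",
  representation(x = "numeric", y = "numeric", z = "numeric", fs = "numeric"))

setValidity("TriaxialSignal", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  n <- length(object@x)
  if (n < 1L) msg <- c(msg, "axes must be non-empty")
  if (length(object@y) != n || length(object@z) != n)
    msg <- c(msg, "x, y and z must have equal length")
  if (length(msg)) msg else TRUE
})

#' Inter-beat (RR) interval series
#'
#' Ordered inter-beat intervals in milliseconds derived from detected pulse
#' peaks. Holds both the intervals and the peak times they came from; the
#' interval count `N` is always `length(peakTimes) - 1`.
#'
#' @slot rr successive RR intervals in ms, all positive.
#' @slot peakTimes strictly increasing peak times in seconds.
#' @export
setClass("RRSeries",
  representation(rr = "numeric", peakTimes = "numeric"))

setValidity("RRSeries", function(object) {
  msg <- character()
  if (length(object@rr) != length(object@peakTimes) - 1L)
    msg <- c(msg, "length(rr) must equal length(peakTimes) - 1")
  if (any(object@rr <= 0)) msg <- c(msg, "all RR intervals must be positive")
  if (is.unsorted(object@peakTimes, strictly = TRUE))
    msg <- c(msg, "peakTimes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Skin-conductance decomposition
#'
#' Result of continuous decomposition analysis: the (smoothed) observed skin
#' conductance split into a slowly varying tonic level and a phasic component
#' driven by a sparse nonnegative sudomotor driver convolved with a
#' biexponential (Bateman) kernel.
#'
#' @slot sc smoothed observed conductance (uS).
#' @slot tonic tonic level (uS); `tonic + phasic` reconstructs `sc`.
#' @slot phasic phasic response (uS).
#' @slot driver sudomotor driver (uS/s), nonnegative up to solver tolerance.
#' @slot fs sampling rate in Hz.
#' @slot tau kernel time constants `c(tau1, tau2)` in seconds, `tau2 > tau1`.
#' @slot residual root-mean-square deconvolution residual (uS).
#' @slot converged logical solver flag.
#' @export
setClass("SCDecomposition",
  representation(sc = "numeric", tonic = "numeric", phasic = "numeric",
                 driver = "numeric", fs = "numeric", tau = "numeric",
                 residual = "numeric", converged = "logical"),
  prototype(residual = NA_real_, converged = TRUE))

setValidity("SCDecomposition", function(object) {
  msg <- character()
  n <- length(object@sc)
  if (length(object@tonic) != n || length(object@phasic) != n ||
      length(object@driver) != n)
    msg <- c(msg, "sc, tonic, phasic and driver must have equal length")
  if (length(object@tau) != 2L || any(object@tau <= 0) ||
      object@tau[2] <= object@tau[1])
    msg <- c(msg, "tau must satisfy tau2 > tau1 > 0")
  if (length(msg)) msg else TRUE
})

## ---- constructors ----------------------------------------------------------

#' @rdname RawSignal-class
#' @param samples numeric sample values.
#' @param fs sampling rate (Hz).
#' @param channel channel tag.
#' @param startTime start time (s).
#' @return A `RawSignal` object.
#' @examples
#' RawSignal(sin(2 * pi * 1.2 * seq(0, 10, by = 1/50)), fs = 50, channel = "ppg")
#' @export
RawSignal <- function(samples, fs, channel = c("other", "ppg", "gsr"),
                      startTime = 0) {
  channel <- match.arg(channel)
  new("RawSignal", samples = as.numeric(samples), fs = fs,
      channel = channel, startTime = startTime)
}

#' @rdname TriaxialSignal-class
#' @param x,y,z per-axis acceleration.
#' @param fs sampling rate (Hz).
#' @return A `TriaxialSignal` object.
#' @export
TriaxialSignal <- function(x, y, z, fs) {
  new("TriaxialSignal", x = as.numeric(x), y = as.numeric(y),
      z = as.numeric(z), fs = fs)
}

#' @rdname RRSeries-class
#' @param rr RR intervals (ms).
#' @param peakTimes peak times (s).
#' @return An `RRSeries` object.
#' @export
RRSeries <- function(rr, peakTimes) {
  new("RRSeries", rr = as.numeric(rr), peakTimes = as.numeric(peakTimes))
}
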