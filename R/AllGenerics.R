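#' Accessors for signal containers
#'
#' Small accessor family for the S4 containers: sample values, sampling rate,
#' duration, RR intervals and decomposition components. Prefer these over
#' direct slot access.
#'
#' @param object a `RawSignal`, `TriaxialSignal`, `RRSeries` or
#'   `SCDecomposition` object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("rrIntervals", function(object) standardGeneric("rrIntervals"))
#' @rdname accessors
#' @export
setGeneric("peakTimes", function(object) standardGeneric("peakTimes"))
#' @rdname accessors
#' @export
setGeneric("nIntervals", function(object) standardGeneric("nIntervals"))
#' @rdname accessors
#' @export
setGeneric("tonic", function(object) standardGeneric("tonic"))
#' @rdname accessors
#' @export
setGeneric("phasic", function(object) standardGeneric("phasic"))
#' @rdname accessors
#' @export
setGeneric("scDriver", function(object) standardGeneric("scDriver"))

#' @rdname accessors
setMethod("samples", "RawSignal", function(object) object@samples)
#' @rdname accessors
setMethod("samplingRate", "RawSignal", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "TriaxialSignal", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "SCDecomposition", function(object) object@fs)
#' @rdname accessors
setMethod("duration", "RawSignal",
          function(object) length(object@samples) / object@fs)
#' @rdname accessors
setMethod("duration", "TriaxialSignal",
          function(object) length(object@x) / object@fs)
#' @rdname accessors
setMethod("rrIntervals", "RRSeries", function(object) object@rr)
#' @rdname accessors
setMethod("peakTimes", "RRSeries", function(object) object@peakTimes)
#' @rdname accessors
setMethod("nIntervals", "RRSeries", function(object) length(object@rr))
#' @rdname accessors
setMethod("tonic", "SCDecomposition", function(object) object@tonic)
#' @rdname accessors
setMethod("phasic", "SCDecomposition", function(object) object@phasic)
#' @rdname accessors
setMethod("scDriver", "SCDecomposition", function(object) object@driver)
#' @rdname accessors
setMethod("samples", "SCDecomposition", function(object) object@sc)

setMethod("show", "RawSignal", function(object) {
  cat(sprintf("RawSignal [%s]: %d samples @ %g Hz (%.1f s), start %g s\n",
              object@channel, length(object@samples), object@fs,
              duration(object), object@startTime))
})

setMethod("show", "TriaxialSignal", function(object) {
  cat(sprintf("TriaxialSignal: %d samples/axis @ %g Hz (%.1f s)\n",
              length(object@x), object@fs, duration(object)))
})

setMethod("show", "RRSeries", function(object) {
  cat(sprintf("RRSeries: %d intervals, mean RR %.1f ms (HR %.1f bpm)\n",
              length(object@rr), mean(object@rr), 60000 / mean(object@rr)))
})

setMethod("show", "SCDecomposition", function(object) {
  cat(sprintf(
    "SCDecomposition: %d samples @ %g Hz, tau = (%g, %g) s, residual %.4g uS%s\n",
    length(object@sc), object@fs, object@tau[1], object@tau[2],
    object@residual, if (isTRUE(object@converged)) "" else " [not converged]"))
})
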