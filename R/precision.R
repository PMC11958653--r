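#' Pairwise marker-center distances of an assembly pattern
#'
#' Euclidean distances between the centers of every unordered pair of piece
#' markers. Invariant to any rigid motion (or reflection) of the pattern.
#'
#' @param pattern `data.frame` with columns `piece`, `cx`, `cy`; at least 2
#'   pieces with unique ids.
#' @return Named numeric of `choose(n, 2)` distances, names `"a|b"` with the
#'   piece ids sorted within each pair.
#' @examples
#' patternDistances(data.frame(piece = c("a", "b"), cx = c(0, 3), cy = c(0, 4)))
#' @export
patternDistances <- function(pattern) {
  stopifnot(all(c("piece", "cx", "cy") %in% names(pattern)))
  if (nrow(pattern) < 2L) stop("at least 2 pieces are required")
  if (anyDuplicated(pattern$piece)) stop("duplicate piece ids")
  ord <- order(as.character(pattern$piece))
  pattern <- pattern[ord, ]
  n <- nrow(pattern)
  pairs <- utils::combn(n, 2)
  d <- sqrt((pattern$cx[pairs[1, ]] - pattern$cx[pairs[2, ]])^2 +
            (pattern$cy[pairs[1, ]] - pattern$cy[pairs[2, ]])^2)
  names(d) <- paste(pattern$piece[pairs[1, ]], pattern$piece[pairs[2, ]],
                    sep = "|")
  d
}

#' Assembly precision of one trial
#'
#' Compares the observed pairwise marker distances of a constructed pattern
#' with those of the reference pattern. The per-pair deviations are the
#' signed differences `observed - reference`; precision is reported as their
#' sample standard deviation, so a perfectly assembled (or rigidly moved)
#' pattern scores 0 and a lower value means higher precision.
#'
#' @param observed,reference patterns as in [patternDistances()], with
#'   identical piece-id sets.
#' @return List with `deviations` (named, `choose(n, 2)` values) and `sd`.
#' @export
precisionSD <- function(observed, reference) {
  dObs <- patternDistances(observed)
  dRef <- patternDistances(reference)
  if (!setequal(names(dObs), names(dRef))) {
    missing <- c(setdiff(names(dRef), names(dObs)),
                 setdiff(names(dObs), names(dRef)))
    stop("piece-id mismatch between observed and reference: ",
         paste(unique(missing), collapse = ", "))
  }
  dev <- dObs - dRef[names(dObs)]
  list(deviations = dev, sd = stats::sd(dev))
}

#' Session-level assembly precision
#'
#' Arithmetic mean of per-trial precision SDs within one instruction session.
#'
#' @param sds numeric vector of per-trial precision SDs (at least one).
#' @return Mean SD.
#' @export
sessionPrecision <- function(sds) {
  if (!length(sds)) stop("at least one trial is required")
  mean(sds)
}
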