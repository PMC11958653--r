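#' Score the NASA-TLX workload instrument
#'
#' Aggregates the six subscale ratings (mental, physical and temporal demand,
#' performance, effort, frustration; each on 0-100) into an overall
#' cognitive-load score. In `raw` mode (RTLX convention) the score is the
#' unweighted mean of the six ratings; in `weighted` mode it is the
#' pairwise-weighted mean `sum(w * rating) / 15`. Performance enters as rated
#' -- on this instrument a higher performance rating means *worse* perceived
#' performance, so it points in the same direction as the other subscales;
#' any reversal is display-only (see [reversePerformanceForDisplay()]).
#'
#' @param ratings named numeric of the six subscales (`mental`, `physical`,
#'   `temporal`, `performance`, `effort`, `frustration`), each in `[0, 100]`.
#' @param mode `"raw"` or `"weighted"`.
#' @param weights for `weighted` mode, named nonnegative integer tally of
#'   pairwise wins per subscale, summing to 15.
#' @return List with `cl` (overall cognitive load, 0-100) and `subscales`
#'   (the input ratings).
#' @examples
#' scoreTLX(c(mental = 80, physical = 20, temporal = 40,
#'            performance = 60, effort = 70, frustration = 50))$cl
#' @export
scoreTLX <- function(ratings, mode = c("raw", "weighted"), weights = NULL) {
  mode <- match.arg(mode)
  dims <- c("mental", "physical", "temporal", "performance", "effort",
            "frustration")
  if (!all(dims %in% names(ratings)))
    stop("ratings must be named with the six TLX subscales")
  r <- as.numeric(ratings[dims])
  if (any(r < 0 | r > 100)) stop("ratings must lie in [0, 100]")
  cl <- if (mode == "raw") mean(r) else {
    if (is.null(weights) || !all(dims %in% names(weights)))
      stop("weighted mode requires named pairwise weights")
    w <- as.numeric(weights[dims])
    if (sum(w) != 15) stop("pairwise weights must sum to 15")
    sum(w * r) / 15
  }
  list(cl = cl, subscales = stats::setNames(r, dims))
}

#' Reverse the performance subscale for radar display
#'
#' Presentation-only transform: flips performance to `100 - performance` so
#' that on a radar chart every spoke reads "more is better-performing
#' self-report". The overall cognitive-load score is computed from the
#' unreversed ratings and is unaffected.
#'
#' @param subscales named numeric vector including `performance`.
#' @return The vector with `performance` complemented.
#' @export
reversePerformanceForDisplay <- function(subscales) {
  if (!"performance" %in% names(subscales))
    stop("subscales must include 'performance'")
  subscales["performance"] <- 100 - subscales["performance"]
  subscales
}

#' Score the short Dundee Stress State Questionnaire
#'
#' Each of the three states (task engagement, distress, worry) is measured by
#' eight items rated 0-4; the state score is the item sum, hence lies in
#' 0-32. Reverse-keyed items are assumed pre-coded in the input.
#'
#' @param items named list with components `engagement`, `distress`, `worry`,
#'   each a numeric vector of exactly 8 item ratings in `{0, ..., 4}`.
#' @return Named numeric `c(engagement, distress, worry)`, each in `[0, 32]`.
#' @export
scoreDSSQ <- function(items) {
  states <- c("engagement", "distress", "worry")
  if (!all(states %in% names(items)))
    stop("items must contain engagement, distress and worry")
  vapply(stats::setNames(states, states), function(s) {
    v <- items[[s]]
    if (length(v) != 8L) stop(s, ": exactly 8 items are required")
    if (any(v < 0 | v > 4 | v != round(v)))
      stop(s, ": item ratings must be integers in 0..4")
    sum(v)
  }, numeric(1))
}
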