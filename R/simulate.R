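## truncated normal via inverse-CDF; vectorized over n
rtruncnorm <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm(lo, mean, sd); b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, a, b), mean, sd)
}

defaultPatterns <- function() {
  ## four fixed 6-piece layouts (marker-center coordinates, pixels)
  base <- list(
    cbind(c(0, 60, 120, 0, 60, 120), c(0, 0, 0, 60, 60, 60)),
    cbind(c(0, 60, 120, 180, 90, 90), c(0, 0, 0, 0, 60, 120)),
    cbind(c(0, 60, 0, 60, 30, 30), c(0, 0, 60, 60, 120, 180)),
    cbind(c(0, 60, 120, 60, 60, 120), c(0, 0, 0, 60, 120, 120)))
  lapply(seq_along(base), function(i)
    data.frame(piece = paste0("p", 1:6),
               cx = base[[i]][, 1], cy = base[[i]][, 2]))
}

defaultGroupScheme <- function() {
  ## counterbalanced two-session protocol: four subgroups
  data.frame(
    subgroup = c("Sub_G1.1", "Sub_G1.2", "Sub_G2.1", "Sub_G2.2"),
    firstCondition = c("code", "code", "visual", "visual"),
    firstPatterns = c("1,2", "3,4", "1,2", "3,4"),
    secondCondition = c("visual", "visual", "code", "code"),
    secondPatterns = c("3,4", "1,2", "3,4", "1,2"))
}

#' Default per-condition generator parameters
#'
#' The shipped study conditions: per condition (baseline, visual, code) the
#' mean and variability of the RR tachogram (ms), the skin-conductance
#' response rate (events/min), the repetition-duration distribution
#' (log-normal, seconds), the placement-noise SD (pixels) and the
#' questionnaire score distributions (mean, SD). Modify a copy of this list
#' to inject different condition effects (or none).
#'
#' @return Named list with `baseline`, `visual`, `code` components.
#' @export
defaultConditionEffects <- function() {
  list(
    baseline = list(
      meanRR = 850, sdRR = 55, scrRate = 2,
      dssq = list(engagement = c(25.06, 5.33), distress = c(9.00, 5.52),
                  worry = c(15.86, 5.85))),
    visual = list(
      meanRR = 800, sdRR = 45, scrRate = 4,
      repDurationS = 32, repDurationSdLog = 0.3, placementSd = 2.0,
      tlx = c(39.84, 13.74),
      dssq = list(engagement = c(27.43, 5.21), distress = c(6.56, 4.76),
                  worry = c(8.60, 4.86))),
    code = list(
      meanRR = 780, sdRR = 40, scrRate = 6,
      repDurationS = 84, repDurationSdLog = 0.3, placementSd = 1.4,
      tlx = c(57.24, 14.71),
      dssq = list(engagement = c(26.83, 4.75), distress = c(11.83, 6.02),
                  worry = c(9.23, 6.88))))
}

#' Configuration of a synthetic instruction study
#'
#' Describes a counterbalanced two-session assembly study: participants are
#' cycled through four subgroups that cross instruction order (code first vs
#' visual first) with pattern allocation, after a 3-minute physiological
#' baseline. Sessions last at least `sessionLengthS` seconds and extend
#' until every assigned pattern has been repeated `minRepetitions` times.
#' Per-condition effect parameters drive the mean/variability of the RR
#' tachogram, the skin-conductance-response rate, repetition tempo,
#' questionnaire score distributions and placement noise.
#'
#' @param nParticipants number of participants (>= 2; default 30).
#' @param fs sampling rate of the physiological channels, Hz (default 250).
#' @param sessionLengthS nominal session length, seconds (default 300,
#'   minimum 60).
#' @param baselineLengthS baseline recording length, seconds (default 180).
#' @param minRepetitions minimum repetitions per pattern (default 3).
#' @param patterns list of 4 reference patterns (data frames `piece`, `cx`,
#'   `cy`, 6 pieces each).
#' @param groupScheme counterbalancing table (4 subgroups).
#' @param conditionEffects per-condition generator parameters; see
#'   `defaultConditionEffects` in the package source for the shipped values.
#' @param includeSignals simulate the raw physiological channels (set FALSE
#'   for questionnaire/performance-only studies, which is much faster).
#' @param seed integer master seed.
#' @return A validated `StudyConfig` list.
#' @export
studyConfig <- function(nParticipants = 30, fs = 250, sessionLengthS = 300,
                        baselineLengthS = 180, minRepetitions = 3,
                        patterns = defaultPatterns(),
                        groupScheme = defaultGroupScheme(),
                        conditionEffects = defaultConditionEffects(),
                        includeSignals = TRUE, seed = 1L) {
  if (!is.numeric(nParticipants) || nParticipants < 2)
    stop("invalid field 'nParticipants': must be >= 2")
  if (!is.numeric(fs) || fs <= 0) stop("invalid field 'fs': must be > 0")
  if (!is.numeric(sessionLengthS) || sessionLengthS < 60)
    stop("invalid field 'sessionLengthS': must be >= 60")
  if (minRepetitions < 1) stop("invalid field 'minRepetitions': must be >= 1")
  if (length(patterns) != 4L ||
      !all(vapply(patterns, nrow, integer(1)) == 6L))
    stop("invalid field 'patterns': need 4 patterns of 6 pieces")
  if (nrow(groupScheme) != 4L)
    stop("invalid field 'groupScheme': need 4 subgroups")
  need <- c("baseline", "visual", "code")
  if (!all(need %in% names(conditionEffects)))
    stop("invalid field 'conditionEffects': need baseline, visual, code")
  structure(list(nParticipants = as.integer(nParticipants), fs = fs,
                 sessionLengthS = sessionLengthS,
                 baselineLengthS = baselineLengthS,
                 minRepetitions = as.integer(minRepetitions),
                 patterns = patterns, groupScheme = groupScheme,
                 conditionEffects = conditionEffects,
                 includeSignals = isTRUE(includeSignals),
                 seed = as.integer(seed)),
            class = "StudyConfig")
}

#' Simulate a photoplethysmogram from beat times
#'
#' One asymmetric Gaussian pulse per beat (fast rise, slower fall), peaking
#' exactly at each beat time, plus a configurable DC offset, a slow
#' (< 0.1 Hz) sinusoidal trend and additive white noise.
#'
#' @param beatTimes strictly increasing beat times, seconds.
#' @param fs sampling rate, Hz.
#' @param dcOffset constant offset (a.u.).
#' @param trendAmplitude amplitude of the low-frequency trend (a.u.).
#' @param noiseSd white-noise SD (a.u.).
#' @param durationS signal length, seconds (default: last beat + 0.5 s).
#' @return A `ppg` [RawSignal-class]; true beat times are attached as
#'   attribute `beatTimes`.
#' @export
simulatePPG <- function(beatTimes, fs, dcOffset = 0, trendAmplitude = 0,
                        noiseSd = 0, durationS = NULL) {
  if (is.unsorted(beatTimes, strictly = TRUE))
    stop("beatTimes must be strictly increasing")
  if (is.null(durationS)) durationS <- max(beatTimes) + 0.5
  t <- seq(0, durationS - 1 / fs, by = 1 / fs)
  x <- numeric(length(t))
  riseW <- 0.06; fallW <- 0.15
  for (b in beatTimes) {
    idx <- which(t >= b - 0.4 & t <= b + 0.7)
    dt <- t[idx] - b
    w <- ifelse(dt < 0, riseW, fallW)
    x[idx] <- x[idx] + exp(-(dt / w)^2)
  }
  if (trendAmplitude > 0) {
    ph <- stats::runif(3, 0, 2 * pi)
    fr <- c(0.015, 0.041, 0.087)
    x <- x + trendAmplitude *
      (0.5 * sin(2 * pi * fr[1] * t + ph[1]) +
       0.3 * sin(2 * pi * fr[2] * t + ph[2]) +
       0.2 * sin(2 * pi * fr[3] * t + ph[3]))
  }
  x <- x + dcOffset
  if (noiseSd > 0) x <- x + stats::rnorm(length(x), 0, noiseSd)
  out <- RawSignal(x, fs, channel = "ppg")
  attr(out, "beatTimes") <- beatTimes
  out
}

#' Simulate a skin-conductance signal
#'
#' Smooth spline interpolation of tonic knots plus a sparse sudomotor driver
#' convolved with the biexponential Bateman kernel, with optional white
#' noise. The generating components are stored as attributes for
#' round-trip tests.
#'
#' @param driverEvents data frame with columns `time` (s) and `amplitude`
#'   (uS, nonnegative); may have zero rows.
#' @param tonicKnots data frame with columns `time` (s) and `level` (uS).
#' @param tau Bateman time constants `(tau1, tau2)`, `tau2 > tau1 > 0`.
#' @param fs sampling rate, Hz.
#' @param durationS signal length, seconds.
#' @param noiseSd white-noise SD (uS).
#' @return A `gsr` [RawSignal-class] with attributes `driverEvents`,
#'   `tonicCurve`, `phasicCurve`.
#' @export
simulateGSR <- function(driverEvents, tonicKnots, tau = c(1, 3.75), fs,
                        durationS, noiseSd = 0) {
  if (length(tau) != 2L || any(tau <= 0) || tau[2] <= tau[1])
    stop("tau must satisfy tau2 > tau1 > 0")
  if (nrow(driverEvents) && any(driverEvents$amplitude < 0))
    stop("driver amplitudes must be nonnegative")
  n <- round(durationS * fs)
  t <- (seq_len(n) - 1L) / fs
  tonicC <- if (nrow(tonicKnots) >= 4)
    stats::spline(tonicKnots$time, tonicKnots$level, xout = t)$y
  else stats::approx(tonicKnots$time, tonicKnots$level, xout = t, rule = 2)$y
  driver <- numeric(n)
  if (nrow(driverEvents)) {
    idx <- pmin(n, pmax(1L, round(driverEvents$time * fs) + 1L))
    driver[idx] <- driver[idx] + driverEvents$amplitude
  }
  kern <- batemanKernel(tau, fs, durationS = min(20, durationS))
  phasicC <- convolveCausal(driver, kern)
  x <- tonicC + phasicC
  if (noiseSd > 0) x <- x + stats::rnorm(n, 0, noiseSd)
  out <- RawSignal(x, fs, channel = "gsr")
  attr(out, "driverEvents") <- driverEvents
  attr(out, "tonicCurve") <- tonicC
  attr(out, "phasicCurve") <- phasicC
  out
}

#' Simulate a wrist accelerometer recording
#'
#' Gravity baseline (1 g on Z) plus one damped-oscillation movement burst
#' per task repetition on the X and Y axes, plus sensor noise.
#'
#' @param repetitionTimes burst (repetition) onset times, seconds.
#' @param fs sampling rate, Hz.
#' @param durationS signal length, seconds.
#' @param burstAmplitude peak burst acceleration, g.
#' @param burstDuration burst envelope width, seconds.
#' @param burstFreq oscillation frequency within a burst, Hz.
#' @param noiseSd sensor noise SD, g.
#' @return A [TriaxialSignal-class]; repetition times attached as attribute
#'   `repetitionTimes`.
#' @export
simulateAccel <- function(repetitionTimes, fs, durationS,
                          burstAmplitude = 0.5, burstDuration = 1.5,
                          burstFreq = 3, noiseSd = 0.02) {
  if (length(repetitionTimes) && any(repetitionTimes > durationS))
    stop("repetitionTimes must lie within the session duration")
  n <- round(durationS * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n); y <- numeric(n)
  for (r in repetitionTimes) {
    idx <- which(t >= r & t <= r + 3 * burstDuration)
    dt <- t[idx] - r
    env <- exp(-(dt / burstDuration)^2)
    x[idx] <- x[idx] + burstAmplitude * env * sin(2 * pi * burstFreq * dt)
    y[idx] <- y[idx] + 0.6 * burstAmplitude * env *
      cos(2 * pi * burstFreq * dt)
  }
  z <- rep(1, n)
  if (noiseSd > 0) {
    x <- x + stats::rnorm(n, 0, noiseSd)
    y <- y + stats::rnorm(n, 0, noiseSd)
    z <- z + stats::rnorm(n, 0, noiseSd)
  }
  out <- TriaxialSignal(x, y, z, fs)
  attr(out, "repetitionTimes") <- repetitionTimes
  out
}

#' Simulate assembly trials against a reference pattern
#'
#' Each trial applies a random rigid motion (rotation uniform on `[0, 2 pi)`,
#' translation uniform in a square box) to the whole reference assembly,
#' then perturbs every piece center with isotropic Gaussian noise of SD
#' `placementSd`. The rigid motion leaves pairwise distances -- and hence
#' the precision metric -- unchanged; only the placement noise degrades
#' precision.
#'
#' @param reference reference pattern data frame (`piece`, `cx`, `cy`,
#'   at least 2 pieces).
#' @param nTrials number of trials (>= 1).
#' @param placementSd isotropic placement noise SD (same units as the
#'   coordinates; >= 0).
#' @param motionBox half-width of the translation box.
#' @return Data frame with columns `trial`, `piece`, `cx`, `cy`.
#' @export
simulateTrials <- function(reference, nTrials, placementSd, motionBox = 50) {
  if (nrow(reference) < 2L) stop("reference needs at least 2 pieces")
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (placementSd < 0) stop("placementSd must be >= 0")
  out <- lapply(seq_len(nTrials), function(tr) {
    th <- stats::runif(1, 0, 2 * pi)
    shift <- stats::runif(2, -motionBox, motionBox)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    xy <- as.matrix(reference[, c("cx", "cy")]) %*% t(R)
    xy <- sweep(xy, 2, -shift)
    if (placementSd > 0)
      xy <- xy + matrix(stats::rnorm(2 * nrow(xy), 0, placementSd), ncol = 2)
    data.frame(trial = tr, piece = reference$piece,
               cx = xy[, 1], cy = xy[, 2])
  })
  do.call(rbind, out)
}

## DSSQ item allocation: spread a target state score over 8 items 0..4
dssqItemsFromScore <- function(score) {
  score <- max(0, min(32, round(score)))
  base <- score %/% 8
  extra <- score %% 8
  items <- rep(base, 8)
  if (extra > 0) items[seq_len(extra)] <- items[seq_len(extra)] + 1
  items
}

simulateRepetitionSchedule <- function(eff, cfg) {
  nPat <- 2L
  needed <- nPat * cfg$minRepetitions
  mu <- log(eff$repDurationS) - eff$repDurationSdLog^2 / 2
  durs <- numeric(0); patSeq <- integer(0); tEnd <- numeric(0)
  cum <- 0; i <- 0L
  repeat {
    i <- i + 1L
    d <- stats::rlnorm(1, mu, eff$repDurationSdLog)
    if (i > needed && cum + d > cfg$sessionLengthS) break
    cum <- cum + d
    durs <- c(durs, d); tEnd <- c(tEnd, cum)
    patSeq <- c(patSeq, ((i - 1L) %% nPat) + 1L)
    if (i >= needed && cum >= cfg$sessionLengthS) break
    if (i > 500L) break
  }
  tMinMet <- tEnd[needed]
  tct <- max(cfg$sessionLengthS, tMinMet)
  list(repStart = tEnd - durs, repEnd = tEnd, patternSlot = patSeq,
       ntr = length(durs), tct = tct)
}

simulateSessionSignals <- function(eff, durationS, cfg, repTimes) {
  fs <- cfg$fs
  ## RR tachogram with LF/HF modulation around the condition mean
  nBeat <- ceiling(durationS * 1000 / (eff$meanRR - 3 * eff$sdRR)) + 10
  idx <- seq_len(nBeat)
  tApprox <- cumsum(rep(eff$meanRR / 1000, nBeat))
  ph <- stats::runif(2, 0, 2 * pi)
  rr <- eff$meanRR +
    eff$sdRR * (0.55 * sin(2 * pi * 0.1 * tApprox + ph[1]) +
                0.35 * sin(2 * pi * 0.25 * tApprox + ph[2])) +
    stats::rnorm(nBeat, 0, 0.35 * eff$sdRR)
  rr <- pmax(rr, 350)
  beats <- cumsum(rr) / 1000
  beats <- beats[beats < durationS - 0.3]
  ppg <- simulatePPG(beats, fs, dcOffset = 2, trendAmplitude = 0.4,
                     noiseSd = 0.02, durationS = durationS)
  ## SCR events as a Poisson process at the condition rate
  nEv <- stats::rpois(1, eff$scrRate * durationS / 60)
  ev <- data.frame(time = sort(stats::runif(nEv, 2, durationS - 10)),
                   amplitude = stats::rlnorm(nEv, log(0.3), 0.4))
  knots <- data.frame(time = seq(0, durationS, by = 30))
  knots$level <- 2 + cumsum(stats::rnorm(nrow(knots), 0, 0.05))
  gsr <- simulateGSR(ev, knots, fs = fs, durationS = durationS,
                     noiseSd = 0.005)
  accel <- simulateAccel(repTimes, fs = fs, durationS = durationS)
  list(ppg = ppg, gsr = gsr, accel = accel)
}

#' Generate a complete synthetic instruction study
#'
#' Produces the full counterbalanced study described by a [studyConfig()]:
#' for every participant a baseline recording plus two instruction sessions
#' (visual/code, order and pattern allocation per subgroup), each with raw
#' PPG/GSR/accelerometer channels (optional), questionnaire item responses,
#' repetition schedules, assembly trials with condition-dependent placement
#' noise, and the generating ground truth. A single master seed spawns one
#' deterministic substream per participant, so identical `(config, seed)`
#' yield identical studies.
#'
#' @param config a [studyConfig()].
#' @return A `SyntheticStudy` list: `config`, `scheme`, and `participants`
#'   (named list; each has `subgroup` and `sessions`, each session holding
#'   `condition`, `durationS`, signal objects, `dssqItems`, `tlxRatings`
#'   (task sessions), `trials`, `patterns`, `ntr`, `tct`, and `truth`).
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  set.seed(config$seed)
  pSeeds <- sample.int(.Machine$integer.max, config$nParticipants)
  scheme <- config$groupScheme
  eff <- config$conditionEffects
  participants <- list()
  for (i in seq_len(config$nParticipants)) {
    set.seed(pSeeds[i])
    sg <- scheme[((i - 1L) %% 4L) + 1L, ]
    sessions <- list()
    ## baseline
    bEff <- eff$baseline
    bl <- list(condition = "baseline", durationS = config$baselineLengthS,
               dssqItems = lapply(
                 stats::setNames(nm = c("engagement", "distress", "worry")),
                 function(s) dssqItemsFromScore(
                   rtruncnorm(1, bEff$dssq[[s]][1], bEff$dssq[[s]][2], 0, 32))))
    bl$truth <- list(dssqMeans = vapply(bEff$dssq, `[`, numeric(1), 1))
    if (config$includeSignals) {
      sig <- simulateSessionSignals(bEff, config$baselineLengthS, config,
                                    repTimes = numeric(0))
      bl <- c(bl, sig)
      bl$truth$beatTimes <- attr(sig$ppg, "beatTimes")
      bl$truth$driverEvents <- attr(sig$gsr, "driverEvents")
    }
    sessions$baseline <- bl
    ## the two instruction sessions
    for (half in 1:2) {
      cond <- if (half == 1) sg$firstCondition else sg$secondCondition
      pats <- as.integer(strsplit(
        if (half == 1) sg$firstPatterns else sg$secondPatterns, ",")[[1]])
      cEff <- eff[[cond]]
      sched <- simulateRepetitionSchedule(cEff, config)
      dur <- sched$tct
      sess <- list(condition = cond, durationS = dur, patterns = pats,
                   ntr = sched$ntr, tct = sched$tct,
                   repStart = sched$repStart, repEnd = sched$repEnd)
      ## one trial (placement record) per completed repetition
      trials <- do.call(rbind, lapply(seq_len(sched$ntr), function(r) {
        pat <- config$patterns[[pats[sched$patternSlot[r]]]]
        tr <- simulateTrials(pat, 1, cEff$placementSd)
        tr$trial <- r
        tr$pattern <- pats[sched$patternSlot[r]]
        tr
      }))
      sess$trials <- trials
      cl <- rtruncnorm(1, cEff$tlx[1], cEff$tlx[2], 0, 100)
      sess$tlxRatings <- stats::setNames(
        rtruncnorm(6, cl, 10, 0, 100),
        c("mental", "physical", "temporal", "performance", "effort",
          "frustration"))
      sess$dssqItems <- lapply(
        stats::setNames(nm = c("engagement", "distress", "worry")),
        function(s) dssqItemsFromScore(
          rtruncnorm(1, cEff$dssq[[s]][1], cEff$dssq[[s]][2], 0, 32)))
      sess$truth <- list(placementSd = cEff$placementSd, clLatent = cl,
                         tlxMean = cEff$tlx[1],
                         dssqMeans = vapply(cEff$dssq, `[`, numeric(1), 1),
                         scrRate = cEff$scrRate, meanRR = cEff$meanRR)
      if (config$includeSignals) {
        sig <- simulateSessionSignals(cEff, dur, config,
                                      repTimes = sched$repStart)
        sess <- c(sess, sig)
        sess$truth$beatTimes <- attr(sig$ppg, "beatTimes")
        sess$truth$driverEvents <- attr(sig$gsr, "driverEvents")
      }
      sessions[[paste0("session", half)]] <- sess
    }
    participants[[sprintf("P%02d", i)]] <-
      list(subgroup = sg$subgroup, sessions = sessions)
  }
  list(config = config, scheme = scheme, participants = participants)
}
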