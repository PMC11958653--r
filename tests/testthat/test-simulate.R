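test_that("study config validates its fields by name", {
  expect_error(studyConfig(nParticipants = 1), "nParticipants")
  expect_error(studyConfig(fs = 0), "fs")
  expect_error(studyConfig(sessionLengthS = 30), "sessionLengthS")
  expect_error(studyConfig(patterns = list()), "patterns")
  expect_s3_class(tinyConfig(), "StudyConfig")
})

test_that("four participants cover the four counterbalanced subgroups", {
  st <- simulateStudy(tinyConfig(seed = 90, n = 4))
  sgs <- vapply(st$participants, `[[`, character(1), "subgroup")
  expect_setequal(unname(sgs),
                  c("Sub_G1.1", "Sub_G1.2", "Sub_G2.1", "Sub_G2.2"))
  ## order and pattern allocation per scheme: G1 starts code, G2 visual
  first <- vapply(st$participants, function(p)
    p$sessions$session1$condition, character(1))
  expect_equal(unname(first), c("code", "code", "visual", "visual"))
  ## each condition uses exactly two patterns
  for (p in st$participants)
    for (s in c("session1", "session2"))
      expect_length(p$sessions[[s]]$patterns, 2L)
})

test_that("identical config and seed give identical studies", {
  a <- simulateStudy(tinyConfig(seed = 91, n = 2, signals = TRUE, fs = 25))
  b <- simulateStudy(tinyConfig(seed = 91, n = 2, signals = TRUE, fs = 25))
  expect_identical(a, b)
  c2 <- simulateStudy(tinyConfig(seed = 92, n = 2, signals = TRUE, fs = 25))
  expect_false(identical(a, c2))
})

test_that("PPG construction honours spacing, offset and trivial cases", {
  beats <- seq(0.8, 10, by = 0.8)
  s <- simulatePPG(beats, fs = 100)
  x <- samples(s)
  ## noiseless periodic train: autocovariance peaks at the true period
  pk <- detectPeaks(removeDC(s))
  expect_equal(diff(pk), rep(0.8, length(pk) - 1), tolerance = 1e-9)
  s5 <- simulatePPG(beats, fs = 100, dcOffset = 5)
  expect_equal(mean(samples(s5)), 5, tolerance = 0.05)
  expect_error(simulatePPG(c(1, 1, 2), fs = 100), "increasing")
})

test_that("GSR construction is tonic plus kernel-convolved driver", {
  flat <- simulateGSR(data.frame(time = numeric(), amplitude = numeric()),
                      data.frame(time = c(0, 60), level = c(2, 2)),
                      fs = 25, durationS = 60)
  expect_equal(samples(flat), rep(2, 1500), tolerance = 1e-12)
  expect_error(
    simulateGSR(data.frame(time = 5, amplitude = -1),
                data.frame(time = c(0, 60), level = c(2, 2)),
                fs = 25, durationS = 60),
    "nonnegative")
  one <- simulateGSR(data.frame(time = 10, amplitude = 1),
                     data.frame(time = c(0, 60), level = c(2, 2)),
                     fs = 25, durationS = 60)
  ## phasic peak equals the event amplitude (unit-peak kernel)
  expect_equal(max(attr(one, "phasicCurve")), 1, tolerance = 1e-6)
})

test_that("SCR-rate differences propagate to the event-count feature", {
  countEvents <- function(rate, seed) {
    set.seed(seed)
    nEv <- rpois(1, rate * 2)    # two minutes
    ev <- data.frame(time = sort(runif(nEv, 2, 110)),
                     amplitude = rlnorm(nEv, log(0.3), 0.4))
    g <- simulateGSR(ev, data.frame(time = c(0, 120), level = c(2, 2)),
                     fs = 25, durationS = 120, noiseSd = 0.003)
    nrow(detectSCRs(cdaDecompose(g, workingFs = 25), 0.05))
  }
  lo <- vapply(1:5, function(s) countEvents(2, s), numeric(1))
  hi <- vapply(1:5, function(s) countEvents(6, s + 50), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("accelerometer bursts scale with repetition count", {
  quiet <- simulateAccel(numeric(0), fs = 50, durationS = 60, noiseSd = 0.02)
  expect_lt(sd(quiet@x), 0.05)
  res <- function(nRep, seed) {
    set.seed(seed)
    a <- simulateAccel(seq(5, 55, length.out = nRep), fs = 50,
                       durationS = 60)
    mean(sqrt(a@x^2 + a@y^2 + a@z^2))
  }
  expect_gt(mean(vapply(1:5, function(s) res(10, s), numeric(1))),
            mean(vapply(1:5, function(s) res(3, s + 9), numeric(1))))
  expect_error(simulateAccel(100, fs = 50, durationS = 60), "within")
})

test_that("task completion time follows the minimum-repetition extension rule", {
  st <- simulateStudy(tinyConfig(seed = 93, n = 8))
  for (p in st$participants) {
    for (sn in c("session1", "session2")) {
      s <- p$sessions[[sn]]
      needed <- 2 * st$config$minRepetitions
      expect_gte(s$ntr, needed)
      tMin <- s$repEnd[needed]
      expect_equal(s$tct, max(st$config$sessionLengthS, tMin))
      ## trials: one placement record per completed repetition
      expect_equal(length(unique(s$trials$trial)), s$ntr)
    }
  }
})

test_that("a null generator produces near-zero paired effect sizes", {
  eff <- defaultConditionEffects()
  eff$code <- eff$visual               # no condition difference at all
  cfg <- studyConfig(nParticipants = 60, includeSignals = FALSE,
                     conditionEffects = eff, seed = 94)
  st <- simulateStudy(cfg)
  sc <- questionnaireScores(st)
  cl <- cogload:::pairedByParticipant(sc, "cl")
  d <- mean(cl$x - cl$y) / sd(cl$x - cl$y)
  expect_lt(abs(d), 0.35)
})
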