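test_that("time-domain HRV features match hand computation", {
  const <- rrFixture(rep(800, 4))
  f <- hrvTimeFeatures(const)
  expect_equal(unname(f[c("RMSSD", "SDRR", "PNN50")]), c(0, 0, 0))
  expect_equal(unname(f["HR"]), 75)

  ## formula oracle: hand summation of squared successive differences
  f2 <- hrvTimeFeatures(rrFixture(c(800, 850, 790, 820)))
  expect_equal(unname(f2["RMSSD"]), sqrt((50^2 + 60^2 + 30^2) / 3))

  ## counting oracle: one of two successive differences exceeds 50 ms
  f3 <- hrvTimeFeatures(rrFixture(c(800, 860, 820)))
  expect_equal(unname(f3["PNN50"]), 50)
  expect_equal(unname(f3["PNN25"]), 100)

  expect_error(hrvTimeFeatures(rrFixture(800)), "2 RR")
})

test_that("printed RMSSD variant divides the radical by N - 1", {
  rr <- rrFixture(c(800, 850, 790, 820))
  expect_equal(
    unname(hrvTimeFeatures(rr, rmssdVariant = "printed")["RMSSD"]),
    sqrt(50^2 + 60^2 + 30^2) / 3)
})

test_that("Poincare descriptors satisfy the rotated-coordinate identities", {
  expect_equal(unname(hrvPoincare(rrFixture(rep(800, 5)))), c(0, 0))
  ## identity oracle: direct rotated-coordinate computation
  set.seed(21)
  for (i in 1:5) {
    rr <- rrFixture(800 + rnorm(30, 0, 30))
    x1 <- rrIntervals(rr)[-nIntervals(rr)]
    x2 <- rrIntervals(rr)[-1]
    sd1Direct <- sd((x2 - x1) / sqrt(2))
    p <- hrvPoincare(rr)
    expect_equal(unname(p["SD1"]), sd1Direct, tolerance = 1e-12)
    expect_equal(p[["SD1"]]^2, 0.5 * sd(diff(rrIntervals(rr)))^2)
  }
  ## alternating series: short-term spread dominates
  alt <- hrvPoincare(rrFixture(rep(c(790, 810), 10)))
  expect_gt(alt[["SD1"]], alt[["SD2"]])
})

test_that("spectral features localize modulation in the right band", {
  makeModulated <- function(freq, durationS = 300) {
    beats <- numeric(0); t <- 0
    while (t < durationS) {
      rr <- 0.8 + 0.05 * sin(2 * pi * freq * t)
      t <- t + rr
      beats <- c(beats, t)
    }
    peaksToRR(beats)
  }
  hfMod <- hrvSpectral(makeModulated(0.25))
  expect_gte(hfMod[["HF"]] / (hfMod[["HF"]] + hfMod[["LF"]]), 0.9)
  lfMod <- hrvSpectral(makeModulated(0.10))
  expect_gt(lfMod[["LF"]], lfMod[["HF"]])
  ## reciprocal identity
  expect_equal(hfMod[["LF_HF"]] * hfMod[["HF_LF"]], 1)
})

test_that("the HRV vector has exactly 19 named features", {
  set.seed(22)
  rr <- peaksToRR(cumsum(runif(80, 0.7, 0.9)))
  f <- hrvFeatures(rr)
  expect_length(f, 19L)
  expect_named(f, c("RMSSD", "MEAN", "MEDIAN", "SDRR", "SDSD", "SDRR_RMSSD",
                    "HR", "PNN25", "PNN50", "SD1", "SD2", "KURT_RR",
                    "SKEW_RR", "VLF", "LF", "HF", "TP", "LF_HF", "HF_LF"))
  expect_lte(f[["PNN50"]], f[["PNN25"]])
  expect_equal(f[["HR"]], 60000 / f[["MEAN"]])
  expect_gte(f[["TP"]], f[["VLF"]] + f[["LF"]] + f[["HF"]] - 1e-9)
})

test_that("RR rescaling scales features equivariantly", {
  set.seed(23)
  base <- cumsum(runif(80, 0.7, 0.9))
  rr1 <- peaksToRR(base)
  rr2 <- peaksToRR(base * 1.1)   # all intervals scaled by c = 1.1
  f1 <- hrvTimeFeatures(rr1); f2 <- hrvTimeFeatures(rr2)
  for (nm in c("RMSSD", "MEAN", "MEDIAN", "SDRR", "SDSD"))
    expect_equal(f2[[nm]], 1.1 * f1[[nm]], tolerance = 1e-9)
  expect_equal(f2[["HR"]], f1[["HR"]] / 1.1, tolerance = 1e-9)
  p1 <- hrvPoincare(rr1); p2 <- hrvPoincare(rr2)
  expect_equal(unname(p2), 1.1 * unname(p1), tolerance = 1e-9)
})

test_that("GSR features match quadrature and degenerate-case oracles", {
  fs <- 25
  n <- 60 * fs
  flat <- new("SCDecomposition", sc = rep(2, n), tonic = rep(2, n),
              phasic = numeric(n), driver = numeric(n), fs = fs,
              tau = c(1, 3.75))
  f <- gsrFeatures(flat, detectSCRs(flat))
  expect_length(f, 9L)
  expect_named(f, c("AreaSCR", "AreaGSR", "No_Peakes", "AvgRiseTime",
                    "AvgDecayTime", "Entropy", "STDGSRdata", "STDSCRdata",
                    "BandPower"))
  expect_equal(unname(f[c("AreaSCR", "No_Peakes", "AvgRiseTime",
                          "AvgDecayTime", "STDSCRdata")]),
               c(0, 0, 0, 0, 0))

  ## quadrature oracle: triangular bump, base 2 s, height 1 uS -> area 1
  tri <- numeric(n)
  up <- seq(0, 1, length.out = fs + 1)
  tri[(10 * fs):(12 * fs)] <- c(up, rev(up)[-1])
  d <- new("SCDecomposition", sc = 2 + tri, tonic = rep(2, n), phasic = tri,
           driver = numeric(n), fs = fs, tau = c(1, 3.75))
  fTri <- gsrFeatures(d, detectSCRs(d))
  expect_equal(unname(fTri["AreaSCR"]), 1.0, tolerance = 0.01)
  expect_equal(unname(fTri["No_Peakes"]), 1)
})

test_that("entropy of a constant signal is zero and of a uniform spread positive", {
  expect_equal(shannonEntropy(rep(2, 100)), 0)
  expect_gt(shannonEntropy(seq(0, 1, length.out = 160)), 3.9)
})

test_that("accelerometer features match hand statistics", {
  static <- TriaxialSignal(rep(1, 100), rep(0, 100), rep(0, 100), fs = 50)
  f <- accelFeatures(static)
  expect_length(f, 24L)
  expect_equal(unname(f["meanR"]), 1)
  expect_equal(unname(f[c("stdX", "rangeX", "stdR", "rangeR")]),
               c(0, 0, 0, 0))

  v <- c(1, 2, 3, 4, 5)
  f2 <- accelFeatures(TriaxialSignal(v, v, v, fs = 5))
  expect_equal(unname(f2["meanX"]), 3)
  expect_equal(unname(f2["medianX"]), 3)
  expect_equal(unname(f2["stdX"]), sqrt(2.5))
  expect_equal(unname(f2["minX"]), 1)
  expect_equal(unname(f2["maxX"]), 5)
  expect_equal(unname(f2["rangeX"]), 4)
  ## min <= median <= max per axis
  expect_true(all(f2[paste0("min", c("X","Y","Z","R"))] <=
                  f2[paste0("median", c("X","Y","Z","R"))]))
})

test_that("feature table has labelled rows and the documented width", {
  cfg <- tinyConfig(seed = 31, n = 2, signals = TRUE, fs = 50)
  st <- simulateStudy(cfg)
  ft <- buildFeatureTable(st)
  expect_s4_class(ft, "SummarizedExperiment")
  expect_equal(nrow(ft), 28L)   # 19 HRV + 9 GSR
  cd <- SummarizedExperiment::colData(ft)
  expect_true(all(cd$session %in% c("baseline", "visual", "code")))
  ## 2-minute baseline -> two 60-s segments per participant
  expect_equal(sum(cd$session == "baseline"), 4L)
  ftA <- buildFeatureTable(st, includeAccel = TRUE)
  expect_equal(nrow(ftA), 52L)
  ff <- featureFrame(ftA)
  expect_true(all(c("participant", "session", "RMSSD", "BandPower",
                    "rangeR") %in% names(ff)))
  expect_false(anyNA(ff))
})
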