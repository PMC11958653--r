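test_that("likelihood-ratio df is (classes - 1) x predictors", {
  expect_equal(lrDf(12, 2), 12L)
  expect_equal(lrDf(15, 3), 30L)
  expect_equal(lrDf(1, 2), 1L)
  expect_error(lrDf(0, 2))
})

test_that("a single binary predictor recovers the table log odds ratio", {
  ## contingency oracle: closed-form log-OR of a 2x2 table
  tab <- expand.grid(x = c(0, 1), y = c("a", "b"))
  counts <- c(40, 10, 15, 35)       # x=0/a, x=1/a, x=0/b, x=1/b
  data <- tab[rep(seq_len(4), counts), ]
  fit <- fitLogistic(data, "x", "y", referenceClass = "a",
                     standardize = FALSE)
  logOR <- log((counts[1] * counts[4]) / (counts[2] * counts[3]))
  expect_equal(unname(fit$B[1, "x"]), logOR, tolerance = 1e-6)
  expect_equal(fit$df, 1L)
  expect_gt(fit$chiSquare, 0)
})

test_that("null model scores zero chi-square on zero df", {
  set.seed(81)
  data <- data.frame(y = rep(c("a", "b"), each = 20), x = rnorm(40))
  fit <- fitLogistic(data, character(0), "y")
  expect_equal(fit$chiSquare, 0)
  expect_equal(fit$df, 0L)
})

test_that("multinomial fit uses the requested reference and df invariant", {
  set.seed(82)
  n <- 60
  data <- data.frame(y = rep(c("baseline", "visual", "code"), each = n))
  data$f1 <- rnorm(3 * n) + (data$y == "code") * 2
  data$f2 <- rnorm(3 * n) + (data$y == "visual") * 1.5
  fit <- fitLogistic(data, c("f1", "f2"), "y", referenceClass = "baseline")
  expect_equal(fit$kind, "multinomial")
  expect_equal(fit$referenceClass, "baseline")
  expect_equal(fit$df, lrDf(2, 3))
  expect_equal(rownames(fit$B), c("code", "visual"))
  expect_true(all(fit$pValues < 0.05))
})

test_that("backward elimination keeps signal and sheds noise", {
  set.seed(83)
  n <- 500
  y <- rep(c("a", "b"), each = n / 2)
  data <- data.frame(y = y, strong = rnorm(n) + (y == "b") * 1.5)
  for (j in 1:9) data[[paste0("noise", j)]] <- rnorm(n)
  keep <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    data2 <- data
    for (j in 1:9) data2[[paste0("noise", j)]] <- rnorm(n)
    sel <- backwardEliminate(data2, setdiff(names(data2), "y"), "y")
    if ("strong" %in% sel$selected) keep <- keep + 1
  }
  expect_gte(keep, 10 * 0.95)

  ## all-noise candidates end near-empty with small chi-square
  set.seed(84)
  noise <- data.frame(y = y)
  for (j in 1:6) noise[[paste0("n", j)]] <- rnorm(n)
  selN <- backwardEliminate(noise, paste0("n", 1:6), "y")
  expect_lte(length(selN$selected), 2L)
  expect_lt(selN$fit$chiSquare, 15)
})

test_that("the elimination trace shrinks monotonically, chi-square nested", {
  set.seed(85)
  n <- 200
  y <- rep(c("a", "b"), each = n / 2)
  data <- data.frame(y = y, s = rnorm(n) + (y == "b"))
  for (j in 1:4) data[[paste0("x", j)]] <- rnorm(n)
  sel <- backwardEliminate(data, c("s", paste0("x", 1:4)), "y")
  tr <- sel$trace
  expect_false(any(duplicated(na.omit(tr$removed))))
  expect_true(all(diff(tr$chiSquare) <= 1e-8))   # removing never adds fit
  if (length(sel$selected) > 0) {
    expect_equal(sel$fit$df, lrDf(length(sel$selected), 2))
  } else {
    expect_equal(sel$fit$df, 0L)
  }
  ## constant features are dropped up front
  data$flat <- 1
  expect_warning(backwardEliminate(data, c("s", "flat"), "y"), "constant")
})

test_that("classification metrics match confusion-matrix arithmetic", {
  truth <- factor(c(rep("a", 10), rep("b", 10)), levels = c("a", "b"))
  pred <- factor(c(rep("a", 8), rep("b", 2), rep("a", 3), rep("b", 7)),
                 levels = c("a", "b"))
  cm <- cogload:::confusionMetrics(truth, pred)
  expect_equal(cm$accuracy, 75)
  expect_equal(cm$precision, mean(c(8 / 11, 7 / 9)) * 100)
  expect_equal(cm$recall, mean(c(8 / 10, 7 / 10)) * 100)

  perfect <- cogload:::confusionMetrics(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall),
               c(100, 100, 100))
})

test_that("in-sample evaluation of a strong model beats permuted labels", {
  set.seed(86)
  n <- 300
  y <- rep(c("baseline", "code"), each = n / 2)
  data <- data.frame(y = y, f = rnorm(n) + (y == "code") * 2.5)
  fit <- fitLogistic(data, "f", "y", referenceClass = "baseline")
  real <- evaluateModel(fit, data)$accuracy
  perm <- data
  perm$y <- sample(perm$y)
  fitP <- fitLogistic(perm, "f", "y", referenceClass = "baseline")
  permAcc <- evaluateModel(fitP, perm)$accuracy
  expect_gte(real - permAcc, 20)
})

test_that("k-fold evaluation refits the selection inside folds", {
  set.seed(87)
  n <- 200
  y <- rep(c("a", "b"), each = n / 2)
  data <- data.frame(y = y, f = rnorm(n) + (y == "b") * 2, g = rnorm(n))
  sel <- backwardEliminate(data, c("f", "g"), "y")
  m <- evaluateModel(sel$fit, data, scheme = "k-fold", k = 4,
                     candidates = c("f", "g"))
  expect_equal(m$scheme, "k-fold")
  expect_gt(m$accuracy, 75)
})

test_that("row order never changes the fitted model", {
  set.seed(88)
  n <- 120
  y <- rep(c("a", "b"), each = n / 2)
  data <- data.frame(y = y, f = rnorm(n) + (y == "b"))
  fit1 <- fitLogistic(data, "f", "y", referenceClass = "a")
  fit2 <- fitLogistic(data[sample(n), ], "f", "y", referenceClass = "a")
  expect_equal(fit1$B, fit2$B, tolerance = 1e-6)
  expect_equal(fit1$chiSquare, fit2$chiSquare, tolerance = 1e-6)
})
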