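test_that("the normality gate routes by the Shapiro-Wilk p-value", {
  set.seed(61)
  xN <- rnorm(30); yN <- rnorm(30)
  gN <- shapiroGate(xN, yN)
  expect_equal(gN$shapiroP, shapiro.test(xN - yN)$p.value)
  ## heavy-tailed differences push to the Wilcoxon route
  d <- rt(30, df = 1)
  gT <- shapiroGate(d + rnorm(30, 0, 1e-6), rnorm(30, 0, 1e-6))
  if (gT$shapiroP < 0.05) expect_equal(gT$test, "wilcoxon-signed-rank")
  expect_error(shapiroGate(1:2, 1:2), "at least 3")
  ## simulation oracle: normal differences keep the Student route mostly
  set.seed(62)
  routes <- vapply(1:100, function(i)
    shapiroGate(rnorm(30), rnorm(30))$test == "student-paired", logical(1))
  expect_gte(mean(routes), 0.9)
})

## independent brute-force enumeration of the signed-rank distribution
bruteWilcoxonP <- function(d) {
  r <- rank(abs(d))
  nz <- d != 0
  rNz <- r[nz]
  wObs <- sum(rNz[d[nz] > 0])
  m <- sum(nz)
  ws <- vapply(0:(2^m - 1), function(mask) {
    bits <- as.integer(intToBits(mask))[1:m]
    sum(rNz[bits == 1])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= wObs), mean(ws >= wObs)))
}

test_that("Wilcoxon signed-rank equals exact enumeration for n <= 10", {
  set.seed(63)
  for (i in 1:8) {
    d <- round(rnorm(sample(5:10, 1), 0.3, 1), 2)
    if (all(d == 0)) next
    res <- wilcoxonSignedRank(d)
    expect_equal(res$method, "exact")
    expect_equal(res$pValue, bruteWilcoxonP(d))
  }
  ## Pratt zeros: a zero keeps its rank slot but is dropped afterwards
  dz <- c(0, 1, 2, -3, 4)
  expect_equal(wilcoxonSignedRank(dz)$pValue, bruteWilcoxonP(dz))
})

test_that("rank-biserial is +-1 for one-sided differences and bounded", {
  dAllPos <- abs(rnorm(10)) + 0.1
  expect_equal(wilcoxonSignedRank(dAllPos)$effectSize, 1)
  expect_equal(wilcoxonSignedRank(-dAllPos)$effectSize, -1)
  set.seed(64)
  for (i in 1:10) {
    es <- wilcoxonSignedRank(rnorm(15))$effectSize
    expect_lte(abs(es), 1)
  }
})

test_that("the normal-approximation Z matches the tie-corrected formula", {
  set.seed(65)
  d <- rnorm(40, 0.4)
  res <- wilcoxonSignedRank(d)
  expect_equal(res$method, "normal")
  expect_equal(res$pValue, 2 * pnorm(-abs(res$Z)))
})

test_that("paired comparison reports Cohen's d and degenerate guards", {
  set.seed(66)
  x <- rnorm(30, 1); y <- rnorm(30)
  pc <- pairedCompare(x, y)
  if (pc$test == "student-paired")
    expect_equal(pc$effectSize, mean(x - y) / sd(x - y))
  ## effect size is negative when the second sample exceeds the first
  pc2 <- pairedCompare(y, x)
  expect_lt(pc2$effectSize, 0)
  ## constant shift: zero-variance differences carry no statistic
  pc3 <- pairedCompare(y + 2, y)
  expect_true(pc3$degenerate)
  expect_true(is.na(pc3$statistic))
})

test_that("Mauchly test agrees with the base-R mlm implementation", {
  set.seed(67)
  for (i in 1:3) {
    Y <- matrix(rnorm(25 * 4), 25, 4) %*% matrix(rnorm(16), 4)
    mine <- mauchlyTest(Y)
    ref <- mauchly.test(lm(Y ~ 1), X = ~1,
                        idata = data.frame(cond = factor(1:4)))
    expect_equal(mine$W, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$pValue, ref$p.value, tolerance = 1e-8)
  }
  expect_equal(mauchlyTest(matrix(rnorm(40), 20, 2))$pValue, 1)
})

test_that("Mauchly is calibrated under compound symmetry", {
  set.seed(68)
  n <- 200; k <- 3
  ps <- vapply(1:40, function(i) {
    subj <- rnorm(n, 0, 1)
    Y <- matrix(rnorm(n * k, 0, 1), n, k) + subj
    mauchlyTest(Y)$pValue
  }, numeric(1))
  ## p-values roughly uniform: no gross inflation at either tail
  expect_gt(mean(ps > 0.05), 0.75)
  expect_gt(min(ps), 0)
})

test_that("epsilons agree with car and satisfy the ordering bounds", {
  skip_if_not_installed("car")
  set.seed(69)
  for (i in 1:3) {
    Y <- matrix(rnorm(20 * 3), 20, 3) %*% matrix(rnorm(9), 3)
    eps <- sphericityEpsilon(Y)
    fit <- lm(Y ~ 1)
    a <- summary(car::Anova(fit, idata = data.frame(cond = factor(1:3)),
                            idesign = ~cond, type = 3),
                 multivariate = FALSE)
    expect_equal(eps$gg, unname(a$pval.adjustments[, "GG eps"]),
                 tolerance = 1e-6)
    expect_equal(eps$hf, min(1, unname(a$pval.adjustments[, "HF eps"])),
                 tolerance = 1e-6)
    expect_gte(eps$hf, eps$gg)
    expect_gte(eps$gg, 1 / 2)
    expect_lte(eps$hf, 1)
  }
})

test_that("repeated-measures ANOVA applies the Huynh-Feldt gate", {
  set.seed(70)
  ## identical columns: no effect at all
  v <- rnorm(15)
  a0 <- rmAnova(cbind(v, v, v))
  expect_equal(a0$F, 0)
  expect_equal(a0$pValue, 1)

  ## F statistic equals the aov Error-term fit
  Y <- matrix(rnorm(18 * 3), 18, 3); Y[, 2] <- Y[, 2] + 0.8
  long <- data.frame(y = as.vector(Y),
                     cond = factor(rep(1:3, each = 18)),
                     id = factor(rep(1:18, 3)))
  ref <- summary(aov(y ~ cond + Error(id / cond), data = long))
  refF <- ref[["Error: id:cond"]][[1]]["cond", "F value"]
  mine <- rmAnova(Y)
  expect_equal(mine$F, refF, tolerance = 1e-10)
  ## correction engages exactly when Mauchly rejects
  expect_equal(mine$correction == "huynh-feldt",
               mine$mauchly$pValue < 0.05)
  expect_equal(nrow(mine$posthoc), 3L)
  expect_error(rmAnova(cbind(c(1, NA, 3), c(1, 2, 3))), "complete")
})

test_that("post-hoc Holm adjustment is applied over the pairs", {
  set.seed(71)
  Y <- matrix(rnorm(20 * 3), 20, 3); Y[, 3] <- Y[, 3] + 1
  a <- rmAnova(Y, posthocAdjust = "holm")
  expect_equal(a$posthoc$pAdjusted,
               p.adjust(a$posthoc$pValue, method = "holm"))
  b <- rmAnova(Y, posthocAdjust = "none")
  expect_equal(b$posthoc$pAdjusted, b$posthoc$pValue)
})
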