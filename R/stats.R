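## numerically zero variance (constant differences up to rounding)
zeroVar <- function(d) stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))

#' Normality-gated choice of paired test
#'
#' Shapiro-Wilk test on the paired differences decides which paired
#' comparison to run: below `alpha` the differences are treated as
#' non-normal and the Wilcoxon signed-rank test is used, otherwise the paired
#' Student t-test.
#'
#' @param x,y paired numeric samples of equal length, `n >= 3`.
#' @param alpha gate level (default 0.05).
#' @return List with `test` (`"student-paired"` or `"wilcoxon-signed-rank"`)
#'   and `shapiroP`.
#' @export
shapiroGate <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 3L) stop("at least 3 pairs are required")
  d <- x - y
  sp <- if (zeroVar(d)) 1 else stats::shapiro.test(d)$p.value
  list(test = if (sp < alpha) "wilcoxon-signed-rank" else "student-paired",
       shapiroP = sp)
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Signed-rank test on paired differences. Zero differences are handled by
#' Pratt's method: they participate in the ranking of absolute values and
#' are dropped afterwards. Ties receive mid-ranks. For `n` nonzero
#' differences up to `exactMax` the p-value is computed by exact enumeration
#' of all `2^n` sign assignments; beyond that, a normal approximation with
#' tie and zero corrections and no continuity correction is used. The
#' matched rank-biserial correlation `(W+ - W-) / (W+ + W-)` is reported as
#' the effect size, signed so that predominantly positive differences give a
#' positive value.
#'
#' @param d numeric vector of paired differences.
#' @param exactMax largest nonzero count for the exact route (default 10).
#' @return List with `statistic` (W+, sum of positive ranks), `Z` (normal
#'   approximation score, `NA` on the exact route), `pValue` (two-sided),
#'   `effectSize` (rank-biserial), `method` (`"exact"` or `"normal"`).
#' @export
wilcoxonSignedRank <- function(d, exactMax = 10) {
  d <- as.numeric(d)
  r <- rank(abs(d))                       # zeros included in ranking (Pratt)
  nz <- d != 0
  m <- sum(nz)
  if (m == 0L)
    return(list(statistic = 0, Z = NA_real_, pValue = 1, effectSize = 0,
                method = "degenerate"))
  rNz <- r[nz]
  sgn <- sign(d[nz])
  wPos <- sum(rNz[sgn > 0])
  wNeg <- sum(rNz[sgn < 0])
  rb <- (wPos - wNeg) / (wPos + wNeg)
  if (m <= exactMax) {
    ## enumerate all sign assignments of the nonzero ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    wAll <- as.vector(signs %*% rNz)
    pv <- min(1, 2 * min(mean(wAll <= wPos), mean(wAll >= wPos)))
    list(statistic = wPos, Z = NA_real_, pValue = pv, effectSize = rb,
         method = "exact")
  } else {
    n <- length(d)
    z0 <- n - m
    mu <- (n * (n + 1) / 2 - z0 * (z0 + 1) / 2) / 2
    tieTab <- table(r[nz])
    v <- (n * (n + 1) * (2 * n + 1) - z0 * (z0 + 1) * (2 * z0 + 1)) / 24 -
      sum(tieTab^3 - tieTab) / 48
    z <- (wPos - mu) / sqrt(v)
    list(statistic = wPos, Z = z,
         pValue = 2 * stats::pnorm(-abs(z)), effectSize = rb,
         method = "normal")
  }
}

#' Gated paired comparison with effect size
#'
#' Runs [shapiroGate()] on the paired differences `x - y` and executes the
#' selected test: paired Student t with Cohen's d (`mean(d) / sd(d)`), or the
#' Wilcoxon signed-rank test with the matched rank-biserial correlation.
#' With the first-listed condition as `x`, the effect size is negative when
#' the second condition exceeds the first.
#'
#' @inheritParams shapiroGate
#' @param alpha normality-gate level.
#' @return List with `test`, `statistic`, `Z` (Wilcoxon only), `pValue`,
#'   `effectSize`, `shapiroP`, and `degenerate = TRUE` when the differences
#'   have zero variance (no test statistic is defined).
#' @export
pairedCompare <- function(x, y, alpha = 0.05) {
  gate <- shapiroGate(x, y, alpha)
  d <- x - y
  if (zeroVar(d)) {
    return(list(test = gate$test, statistic = NA_real_, Z = NA_real_,
                pValue = NA_real_, effectSize = NA_real_,
                shapiroP = gate$shapiroP, degenerate = TRUE))
  }
  if (gate$test == "student-paired") {
    tt <- stats::t.test(x, y, paired = TRUE)
    list(test = gate$test, statistic = unname(tt$statistic), Z = NA_real_,
         pValue = tt$p.value, effectSize = mean(d) / stats::sd(d),
         shapiroP = gate$shapiroP, degenerate = FALSE)
  } else {
    w <- wilcoxonSignedRank(d)
    list(test = gate$test, statistic = w$statistic, Z = w$Z,
         pValue = w$pValue, effectSize = w$effectSize,
         shapiroP = gate$shapiroP, degenerate = FALSE)
  }
}

## orthonormal contrast matrix spanning the space orthogonal to the unit
## vector, used by the sphericity machinery
orthonormalContrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))
  t(C)
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance matrix of the within-subject conditions is
#' spherical, via Mauchly's W on the orthonormalized covariance and the
#' standard chi-square approximation. With only two levels sphericity holds
#' trivially and `p = 1` is returned.
#'
#' @param data numeric matrix, subjects x conditions (`k >= 2`, `n > k`
#'   recommended).
#' @return List with `W`, `pValue`, `df`.
#' @export
mauchlyTest <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (k < 2L) stop("at least 2 conditions are required")
  if (k == 2L) return(list(W = 1, pValue = 1, df = 0))
  C <- orthonormalContrasts(k)
  S <- C %*% stats::cov(data) %*% t(C)
  p <- k - 1
  df <- p * (p + 1) / 2 - 1
  totVar <- sum(diag(stats::cov(data)))
  if (sum(diag(S)) <= 1e-10 * max(totVar, 1e-300))  # no within-subject spread
    return(list(W = 1, pValue = 1, df = df))
  W <- det(S) / (sum(diag(S)) / p)^p
  ## Box approximation with the second-order correction term, matching the
  ## classical mlm treatment
  nd <- n - 1
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nd)
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * k + 2) /
    (288 * (nd * p * rho)^2)
  z <- -nd * rho * log(W)
  pr1 <- stats::pchisq(z, df, lower.tail = FALSE)
  pr2 <- stats::pchisq(z, df + 4, lower.tail = FALSE)
  list(W = W, pValue = pr1 + w2 * (pr2 - pr1), df = df)
}

#' Greenhouse-Geisser and Huynh-Feldt epsilons
#'
#' Degrees-of-freedom deflation factors for a one-way repeated-measures
#' design. Both are reported after capping into `[1/(k-1), 1]`; the
#' Huynh-Feldt value is never below the Greenhouse-Geisser value.
#'
#' @inheritParams mauchlyTest
#' @return List with `gg` and `hf`.
#' @export
sphericityEpsilon <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  C <- orthonormalContrasts(k)
  S <- C %*% stats::cov(data) %*% t(C)
  p <- k - 1
  if (sum(S^2) <= 1e-20 * max(1, sum(diag(stats::cov(data)))^2))
    return(list(gg = 1, hf = 1))
  gg <- sum(diag(S))^2 / (p * sum(S^2))
  hf <- (n * p * gg - 2) / (p * (n - 1 - p * gg))
  clamp <- function(e) min(1, max(1 / p, e))
  list(gg = clamp(gg), hf = clamp(max(hf, gg)))
}

#' One-way repeated-measures ANOVA with sphericity correction
#'
#' Classical within-subject F test on a complete subjects x conditions
#' matrix. Mauchly's test decides whether the Huynh-Feldt correction is
#' applied: when its p-value falls below `alphaSphericity` both degrees of
#' freedom are multiplied by the Huynh-Feldt epsilon before computing the
#' corrected p-value. All pairwise conditions are then compared post hoc
#' with [pairedCompare()] (ordering first-listed minus second-listed) and
#' the chosen p-adjustment.
#'
#' @param data numeric matrix or data frame, subjects x conditions, complete
#'   cases only; column names label the conditions.
#' @param alphaSphericity level of the sphericity gate (default 0.05).
#' @param posthocAdjust p-adjustment method for the pairwise tests
#'   (default `"holm"`; any [stats::p.adjust] method or `"none"`).
#' @return List with `F`, `df`, `pValue` (uncorrected), `mauchly`,
#'   `correction` (`"none"` or `"huynh-feldt"`), `epsilonHF`, `correctedP`,
#'   and `posthoc` (data frame: pair, test, Z, effectSize, pValue,
#'   pAdjusted).
#' @export
rmAnova <- function(data, alphaSphericity = 0.05, posthocAdjust = "holm") {
  data <- as.matrix(data)
  if (anyNA(data)) stop("complete cases are required (missing cells found)")
  n <- nrow(data); k <- ncol(data)
  if (k < 2L) stop("at least 2 conditions are required")
  grand <- mean(data)
  condMeans <- colMeans(data)
  subjMeans <- rowMeans(data)
  ssCond <- n * sum((condMeans - grand)^2)
  ssSubj <- k * sum((subjMeans - grand)^2)
  ssTot <- sum((data - grand)^2)
  ssErr <- ssTot - ssCond - ssSubj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fv <- if (ssErr <= 0) 0 else (ssCond / df1) / (ssErr / df2)
  pRaw <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  mt <- mauchlyTest(data)
  eps <- sphericityEpsilon(data)
  correct <- k > 2L && mt$pValue < alphaSphericity
  pCorr <- if (correct)
    stats::pf(Fv, df1 * eps$hf, df2 * eps$hf, lower.tail = FALSE)
  else pRaw
  cn <- colnames(data)
  if (is.null(cn)) cn <- paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2)
  ph <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    pc <- pairedCompare(data[, i1], data[, i2])
    data.frame(pair = paste(cn[i1], "vs", cn[i2]), test = pc$test,
               Z = pc$Z, effectSize = pc$effectSize, pValue = pc$pValue)
  }))
  ph$pAdjusted <- stats::p.adjust(ph$pValue, method = posthocAdjust)
  list(F = Fv, df = c(df1, df2), pValue = pRaw, mauchly = mt,
       correction = if (correct) "huynh-feldt" else "none",
       epsilonHF = eps$hf, epsilonGG = eps$gg, correctedP = pCorr,
       posthoc = ph)
}
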