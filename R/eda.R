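#' Biexponential (Bateman) impulse response
#'
#' The canonical sudomotor impulse response
#' `k(t) = exp(-t / tau2) - exp(-t / tau1)`, `t >= 0`, normalized to unit
#' peak. Its maximum sits at `log(tau2 / tau1) * tau1 * tau2 / (tau2 - tau1)`.
#'
#' @param tau numeric length-2, time constants `(tau1, tau2)` in seconds with
#'   `tau2 > tau1 > 0`. Defaults `c(1, 3.75)`.
#' @param fs sampling rate in Hz.
#' @param durationS kernel support in seconds.
#' @return Numeric kernel of length `round(durationS * fs)`, first sample at
#'   `t = 0` (hence 0), peak value 1.
#' @export
batemanKernel <- function(tau = c(1, 3.75), fs, durationS = 20) {
  if (length(tau) != 2L || any(tau <= 0) || tau[2] <= tau[1])
    stop("tau must satisfy tau2 > tau1 > 0")
  t <- seq(0, by = 1 / fs, length.out = round(durationS * fs))
  k <- exp(-t / tau[2]) - exp(-t / tau[1])
  k / max(k)
}

## Nonnegative ridge-regularized deconvolution of one chunk: Lawson-Hanson
## active-set NNLS on the normal equations of the (full) convolution system
## K x ~ y plus ridge lambda. The Gram matrix K'K + lambda I is Toeplitz
## (kernel autocorrelation), so it is never materialized: rows are generated
## from the autocorrelation on demand, keeping each iteration O(n * active).
nnlsDeconvChunk <- function(y, kernel, lambda, maxActive = 150L) {
  n <- length(y)
  kl <- length(kernel)
  ypad <- c(y, numeric(kl))
  ## stats::convolve(x, y, "open") computes conv(x, rev(y)), so passing the
  ## kernel unreversed yields the cross-correlation needed for K'y
  cc <- stats::convolve(ypad, kernel, type = "open")
  f <- cc[seq_len(n) + kl - 1L]                     # K'y
  r <- vapply(0:(kl - 1L), function(d)
    sum(kernel[seq_len(kl - d)] * kernel[(1L + d):kl]), numeric(1))
  rExt <- c(r, numeric(n))                          # autocorrelation, padded
  rExt[1] <- rExt[1] + lambda
  tol <- 1e-9 * max(abs(f), 1)
  x <- numeric(n)
  inP <- logical(n)
  w <- f
  for (it in seq_len(3L * n)) {
    cand <- which(!inP)
    ## cap the active set: the steepest-gradient columns (the SCR impulses)
    ## enter first, so the cap only curtails diffuse baseline fitting
    if (!length(cand) || sum(inP) >= maxActive) break
    j <- cand[which.max(w[cand])]
    if (w[j] <= tol) break
    inP[j] <- TRUE
    repeat {
      P <- which(inP)
      G <- matrix(rExt[abs(outer(P, P, "-")) + 1L], length(P))
      z <- tryCatch(solve(G, f[P]), error = function(e) qr.solve(G, f[P]))
      if (all(z > 0)) { x[] <- 0; x[P] <- z; break }
      neg <- which(z <= 0)
      alpha <- min(x[P][neg] / (x[P][neg] - z[neg]))
      x[P] <- x[P] + alpha * (z - x[P])
      drop <- P[x[P] <= tol]
      inP[drop] <- FALSE
      x[drop] <- 0
      if (!any(inP)) break
    }
    P <- which(inP)
    w <- f
    for (jj in P) {                       # gram rows vanish beyond the
      idx <- max(1L, jj - kl + 1L):min(n, jj + kl - 1L)  # kernel support
      w[idx] <- w[idx] - x[jj] * rExt[abs(idx - jj) + 1L]
    }
  }
  x
}

#' Continuous decomposition analysis of skin conductance
#'
#' Splits a smoothed skin-conductance signal into tonic and phasic components.
#' A coarse tonic baseline is first estimated as a cubic spline through
#' low-percentile levels of consecutive blocks; the remainder is deconvolved
#' against the Bateman kernel by nonnegative least squares with ridge penalty
#' `lambda`, at a decimated working rate, yielding a sparse nonnegative
#' sudomotor driver. The phasic component is the driver reconvolved with the
#' kernel (upsampled back to `fs`), and the tonic component is defined as
#' `sc - phasic` so that the decomposition reconstructs the input exactly.
#'
#' @param sig a smoothed, nonnegative [RawSignal-class] (uS).
#' @param tau Bateman time constants, seconds (default `c(1, 3.75)`).
#' @param lambda ridge penalty on the driver (default `1e-3`).
#' @param workingFs decimated rate for the deconvolution, Hz (default 25;
#'   capped at the signal rate).
#' @param chunkS chunk length for the block solver, seconds.
#' @param baselineQ percentile used for the coarse tonic baseline.
#' @return An [SCDecomposition-class]. `residual` is the RMS mismatch between
#'   `driver (*) kernel` and the phasic target at the working rate; a solve
#'   that ends with non-finite driver values is flagged via `converged`.
#' @export
cdaDecompose <- function(sig, tau = c(1, 3.75), lambda = 1e-3,
                         workingFs = 25, chunkS = 60, baselineQ = 0.1) {
  stopifnot(is(sig, "RawSignal"))
  fs <- sig@fs
  workingFs <- min(workingFs, fs)
  dec <- max(1L, round(fs / workingFs))
  wfs <- fs / dec
  y <- sig@samples[seq(1L, length(sig@samples), by = dec)]
  n <- length(y)

  ## coarse tonic: low percentile per ~10 s block, interpolating spline
  bl <- max(1L, round(10 * wfs))
  blocks <- split(seq_len(n), ceiling(seq_len(n) / bl))
  bx <- vapply(blocks, function(i) mean(i), numeric(1))
  bq <- vapply(blocks, function(i) stats::quantile(y[i], baselineQ, names = FALSE),
               numeric(1))
  tonic0 <- if (length(bx) >= 4)
    stats::spline(bx, bq, xout = seq_len(n))$y
  else stats::approx(bx, bq, xout = seq_len(n), rule = 2)$y

  kern <- batemanKernel(tau, wfs, durationS = min(20, n / wfs))

  ## block NNLS with overlap; keep chunk interiors
  chunk <- max(16L, round(chunkS * wfs))
  pad <- round(10 * wfs)
  solveDriver <- function(target) {
    driver <- numeric(n)
    for (s in seq(1L, n, by = chunk)) {
      e <- min(n, s + chunk - 1L)
      a <- max(1L, s - pad); b <- min(n, e + pad)
      d <- nnlsDeconvChunk(target[a:b], kern, lambda)
      driver[s:e] <- d[(s - a + 1L):(e - a + 1L)]
    }
    driver
  }

  ## stage 1: deconvolve against the coarse percentile baseline, then
  ## re-estimate the tonic level through inter-impulse sections (where the
  ## provisional phasic is negligible) and deconvolve again
  tonic1 <- tonic0
  driver <- solveDriver(y - tonic1)
  bi <- ceiling(seq_len(n) / bl)
  for (pass in 1:2) {
    ph0 <- convolveCausal(driver, kern)
    quiet <- ph0 <= pmax(0.02 * max(ph0), 1e-4)
    if (sum(quiet) <= max(8, n / 20)) break
    qx <- as.numeric(tapply(seq_len(n)[quiet], bi[quiet], mean))
    qv <- as.numeric(tapply((y - ph0)[quiet], bi[quiet], stats::median))
    if (length(qx) < 2L) break
    tonic1 <- stats::approx(qx, qv, xout = seq_len(n), rule = 2)$y
    tonic1 <- pmin(pmax(tonic1, min(y)), max(y))
    driver <- solveDriver(y - tonic1)
  }
  converged <- all(is.finite(driver))
  phasicW <- convolveCausal(driver, kern)
  resid <- sqrt(mean((phasicW - (y - tonic1))^2))

  ## back to the acquisition rate
  tW <- (seq_len(n) - 1L) / wfs
  tF <- (seq_along(sig@samples) - 1L) / fs
  phasic <- if (dec > 1L)
    stats::approx(tW, phasicW, xout = tF, rule = 2)$y
  else phasicW
  driverF <- if (dec > 1L)
    stats::approx(tW, driver, xout = tF, rule = 2)$y
  else driver
  tonicF <- sig@samples - phasic

  new("SCDecomposition", sc = sig@samples, tonic = tonicF, phasic = phasic,
      driver = driverF, fs = fs, tau = as.numeric(tau),
      residual = resid, converged = converged)
}

## causal discrete convolution truncated to length(x)
convolveCausal <- function(x, kernel) {
  n <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(n)]
}

#' Detect skin-conductance responses in a decomposition
#'
#' One event per local maximum of the phasic component whose amplitude (peak
#' minus the preceding trough) reaches `minAmplitude`. Rise time runs from
#' the preceding trough (onset) to the peak, decay time from the peak to the
#' following trough.
#'
#' @param decomp an [SCDecomposition-class].
#' @param minAmplitude detection threshold in uS (default 0.01).
#' @return A `data.frame` with columns `onset`, `peak`, `trough` (seconds),
#'   `amplitude` (uS), `riseTime`, `decayTime` (seconds); zero rows when no
#'   event qualifies.
#' @export
detectSCRs <- function(decomp, minAmplitude = 0.01) {
  stopifnot(is(decomp, "SCDecomposition"))
  p <- decomp@phasic
  fs <- decomp@fs
  d <- diff(sign(diff(p)))
  peaks <- which(d < 0) + 1L
  troughs <- c(1L, which(d > 0) + 1L, length(p))
  rows <- lapply(peaks, function(pk) {
    pre <- troughs[troughs < pk]
    post <- troughs[troughs > pk]
    if (!length(pre) || !length(post)) return(NULL)
    on <- max(pre); tr <- min(post)
    amp <- p[pk] - p[on]
    if (amp < minAmplitude) return(NULL)
    data.frame(onset = (on - 1L) / fs, peak = (pk - 1L) / fs,
               trough = (tr - 1L) / fs, amplitude = amp,
               riseTime = (pk - on) / fs, decayTime = (tr - pk) / fs)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(onset = numeric(), peak = numeric(), trough = numeric(),
                      amplitude = numeric(), riseTime = numeric(),
                      decayTime = numeric()))
  do.call(rbind, rows)
}
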