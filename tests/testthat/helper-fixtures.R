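# shared fixtures: all synthetic, built in code at test time

tinyConfig <- function(seed = 101, n = 4, signals = FALSE, fs = 50) {
  studyConfig(nParticipants = n, fs = fs, sessionLengthS = 120,
              baselineLengthS = 120, includeSignals = signals, seed = seed)
}

# clean pulse train fixture: beats at a fixed rate with optional jitter
pulseFixture <- function(bpm = 75, durationS = 60, fs = 100, jitterSd = 0,
                         dc = 0, trend = 0, noise = 0) {
  period <- 60 / bpm
  beats <- seq(period, durationS - 0.5, by = period)
  if (jitterSd > 0) beats <- sort(beats + rnorm(length(beats), 0, jitterSd))
  simulatePPG(beats, fs = fs, dcOffset = dc, trendAmplitude = trend,
              noiseSd = noise, durationS = durationS)
}

rrFixture <- function(rr) RRSeries(rr, peakTimes = c(0, cumsum(rr)) / 1000)

squarePattern <- function() {
  data.frame(piece = c("a", "b", "c", "d"),
             cx = c(0, 10, 10, 0), cy = c(0, 0, 10, 10))
}
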