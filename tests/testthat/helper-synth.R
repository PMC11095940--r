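# Shared fixtures: all inputs are generated in code at test time.

withSeed <- AxonValence:::withSeed

# A small, fast simulation configuration for structural tests.
smallCfg <- function(...) {
  simulationConfig(nAxons = 6L, nTrials = 6L, seed = 11L, ...)
}

# Brute-force sliding-percentile baseline (the independent oracle for
# computeDff): per frame, stats::quantile type 7 over the centered,
# truncated window.
oracleF0 <- function(trace, fs, windowS = 30, percentile = 50) {
  width <- as.integer(round(windowS * fs))
  back <- (width - 1) %/% 2
  fwd <- width %/% 2
  n <- length(trace)
  vapply(seq_len(n), function(t) {
    idx <- max(1, t - back):min(n, t + fwd)
    unname(quantile(trace[idx], percentile / 100, type = 7))
  }, numeric(1))
}

oracleDff <- function(trace, fs, windowS = 30, percentile = 50) {
  f0 <- oracleF0(trace, fs, windowS, percentile)
  (trace - f0) / f0
}

# Construct a tiny but complete SessionBundle by hand (no simulator),
# used by I/O tests.
tinyBundle <- function(nTrials = 3, withFacial = TRUE) {
  fs <- 10
  tl <- data.frame(trial_id = seq_len(nTrials), condition = "reward",
                   cs_onset_s = 10 * seq_len(nTrials),
                   cs_freq_hz = 9000,
                   us_onset_s = 10 * seq_len(nTrials) + 3,
                   day_index = 1L)
  nF <- as.integer((10 * nTrials + 10) * fs)
  set.seed(99)
  fl <- fluorescenceMatrix(matrix(runif(3 * nF, 50, 150), 3), fs)
  fac <- if (withFacial) array(rnorm(nTrials * 4 * 5),
                               dim = c(nTrials, 4, 5)) else NULL
  bt <- behaviorTraces(rnorm(nF), fs, abs(rnorm(nF)), fs,
                       fac, if (withFacial) seq(0, 0.75, by = 0.25)
                       else numeric(0))
  sessionBundle(tl, fl, matrix(rnorm(2 * nF, 0, 0.2), ncol = 2), 5 / 16,
                bt, meta = list(animal = "m1", day = 1L,
                                cs_us_interval_s = 3))
}

# Field-by-field bundle equality (bit-exact arrays).
expectBundleEqual <- function(a, b) {
  expect_identical(a@timeline, b@timeline)
  expect_identical(a@fluor@values, b@fluor@values)
  expect_identical(a@fluor@fsHz, b@fluor@fsHz)
  expect_identical(a@fluor@roiIds, b@fluor@roiIds)
  expect_identical(unname(a@shifts), unname(b@shifts))
  expect_identical(a@pixelSizeUm, b@pixelSizeUm)
  expect_identical(a@behavior@tongue, b@behavior@tongue)
  expect_identical(a@behavior@speed, b@behavior@speed)
  expect_identical(a@behavior@tongueFsHz, b@behavior@tongueFsHz)
  expect_identical(a@behavior@speedFsHz, b@behavior@speedFsHz)
  if (is.null(a@behavior@facial)) expect_null(b@behavior@facial)
  else expect_identical(unname(a@behavior@facial),
                        unname(b@behavior@facial))
}
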