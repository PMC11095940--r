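# Helper: a DffMatrix wrapping a given matrix at fs Hz.
asDff <- function(m, fs = 30) {
  new("DffMatrix", values = m, fsHz = fs,
      roiIds = sprintf("ax%d", seq_len(nrow(m))),
      f0 = matrix(100, nrow(m), ncol(m)))
}

unconditionedTl <- function(usTimes, condition = "reward") {
  data.frame(trial_id = seq_along(usTimes), condition = condition,
             cs_onset_s = NA_real_, cs_freq_hz = NA_real_,
             us_onset_s = usTimes, day_index = 1L)
}

test_that("a US-aligned tensor spans [-2, 2) with fs * 4 frames", {
  fs <- 30
  d <- asDff(matrix(0, 1, 200 * fs), fs)
  tl <- unconditionedTl(100)
  tens <- extractTrials(d, tl, "us_reward")
  expect_identical(dim(tens@values)[3], 120L)
  expect_identical(range(tens@relTime), c(-2, 2 - 1 / fs))
  expect_identical(dim(tens@control)[3], 60L)
})

test_that("conditioned US responses use the pre-CS control window", {
  fs <- 30
  n <- 200 * fs
  m <- matrix(0, 1, n)
  cs <- 100; us <- 103
  # contaminate the CS-to-US interval: must not leak into the control
  m[1, (floor(cs * fs) + 1):(floor(us * fs))] <- 5
  m[1, (floor(us * fs) + 1):(floor((us + 2) * fs))] <- 2
  tl <- data.frame(trial_id = 1L, condition = "reward", cs_onset_s = cs,
                   cs_freq_hz = 9000, us_onset_s = us, day_index = 1L)
  tens <- extractTrials(asDff(m, fs), tl, "us_reward")
  amp <- responseAmplitude(tens)
  expect_equal(amp$amplitude, 2, tolerance = 1e-12)  # control is pre-CS zero
})

test_that("omission trials take a 4 s signal window at the expected reward time", {
  fs <- 30
  n <- 200 * fs
  m <- matrix(0, 1, n)
  cs <- 100
  m[1, (floor((cs + 3) * fs) + 1):(floor((cs + 7) * fs))] <- -0.4
  tl <- data.frame(trial_id = 1L, condition = "reward_omission",
                   cs_onset_s = cs, cs_freq_hz = 9000,
                   us_onset_s = NA_real_, day_index = 1L)
  tens <- extractTrials(asDff(m, fs), tl, "reward_omission", postS = 4)
  expect_identical(dim(tens@values)[3], as.integer(6 * fs))
  amp <- responseAmplitude(tens)
  expect_equal(amp$amplitude, -0.4, tolerance = 1e-12)
})

test_that("amplitude of a boxcar filling the signal window equals its height", {
  fs <- 30
  m <- matrix(0, 1, 200 * fs)
  m[1, (floor(50 * fs) + 1):(floor(52 * fs))] <- 0.7
  tens <- extractTrials(asDff(m, fs), unconditionedTl(50), "us_reward")
  expect_equal(responseAmplitude(tens)$amplitude, 0.7, tolerance = 1e-12)
})

test_that("exponential-transient amplitude matches the window integral", {
  fs <- 200   # fine sampling: discrete mean ~ continuous integral
  A <- 1.3; tau <- 0.5
  n <- 60 * fs
  m <- matrix(0, 1, n)
  t0 <- 30
  i0 <- floor(t0 * fs)
  tRel <- (seq(i0, n - 1) - i0) / fs
  m[1, (i0 + 1):n] <- A * exp(-tRel / tau)
  tens <- extractTrials(asDff(m, fs), unconditionedTl(t0), "us_reward")
  amp <- responseAmplitude(tens)$amplitude
  closedForm <- A * tau * (1 - exp(-4)) / 2
  expect_equal(amp, closedForm, tolerance = 0.01)
  # exact against the discrete oracle
  oracle <- mean(m[1, (i0 + 1):(i0 + 2 * fs)]) - mean(m[1, (i0 - 2 * fs + 1):i0])
  expect_equal(amp, oracle, tolerance = 1e-12)
})

test_that("a constant offset trace yields zero amplitude and amplitudes are linear", {
  fs <- 30
  set.seed(5)
  base <- matrix(rnorm(1 * 200 * fs), 1)
  tl <- unconditionedTl(c(50, 100, 150))
  a1 <- responseAmplitude(extractTrials(asDff(base, fs), tl, "us_reward"))
  scaled <- responseAmplitude(extractTrials(asDff(3 * base + 7, fs), tl,
                                            "us_reward"))
  expect_equal(scaled$amplitude, 3 * a1$amplitude, tolerance = 1e-12)
  const <- responseAmplitude(extractTrials(asDff(matrix(2.5, 1, 200 * fs),
                                                 fs), tl, "us_reward"))
  expect_equal(const$amplitude, 0, tolerance = 1e-12)
})

test_that("per-trial amplitudes equal a brute-force re-slice of the raw dF/F", {
  fs <- 30
  set.seed(17)
  m <- matrix(rnorm(3 * 300 * fs), 3)
  us <- c(40, 90, 160, 250)
  tl <- unconditionedTl(us)
  tens <- extractTrials(asDff(m, fs), tl, "us_reward")
  tab <- responseAmplitude(tens)
  for (ax in 1:3) for (tr in seq_along(us)) {
    i0 <- floor(us[tr] * fs)
    expected <- mean(m[ax, (i0 + 1):(i0 + 2 * fs)]) -
      mean(m[ax, (i0 - 2 * fs + 1):i0])
    expect_lt(abs(tab$per_trial[[ax]][tr] - expected), 1e-12)
  }
})

test_that("trials at recording edges are dropped and counted", {
  fs <- 30
  m <- matrix(0, 1, 60 * fs)
  tl <- unconditionedTl(c(1, 30, 59.5))   # first and last are at edges
  tens <- extractTrials(asDff(m, fs), tl, "us_reward")
  expect_identical(dim(tens@values)[2], 1L)
  expect_identical(tens@alignment$n_dropped_edge, 2L)
  expect_error(extractTrials(asDff(m, fs), unconditionedTl(0.5),
                             "us_reward"), "edges")
})

test_that("signed-rank significance behaves at the boundaries", {
  x <- rnorm(20)
  expect_identical(responseSignificance(x, x)$p, 1)
  expect_false(responseSignificance(x, x)$significant)
  out <- responseSignificance(rnorm(3), rnorm(3))
  expect_true(is.na(out$p)); expect_true(is.na(out$significant))
  set.seed(2)
  ctl <- rnorm(50, 0, 0.1)
  sig <- ctl + 1
  r <- responseSignificance(ctl, sig)
  expect_lt(r$p, 1e-6); expect_true(r$significant)
  # one-sided: a strong *decrease* is not significant under "greater"
  r2 <- responseSignificance(ctl, ctl - 1)
  expect_gt(r2$p, 0.99)
})

test_that("overall axon significance is an OR over reward and aversive", {
  tab <- data.frame(axon_id = rep(c("a", "b", "c"), each = 2),
                    event_kind = rep(c("us_reward", "us_aversive"), 3),
                    significant = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  out <- axonSignificance(tab)
  expect_identical(out$significant[out$axon_id == "a"], TRUE)
  expect_identical(out$significant[out$axon_id == "b"], FALSE)
  expect_identical(out$significant[out$axon_id == "c"], TRUE)
})

test_that("locomotion responses exclude initiations near a US", {
  fs <- 30
  set.seed(31)
  m <- matrix(rnorm(1 * 300 * fs, 0, 0.05), 1)
  tl <- unconditionedTl(c(100, 200), condition = "aversive")
  inits <- c(30, 60, 90, 101, 150, 199.5, 240, 270)
  tab <- locomotionResponse(asDff(m, fs), tl, inits)
  expect_identical(attr(tab, "n_spontaneous"), 6L)   # 101 and 199.5 excluded
  expect_false(tab$significant[1])
  few <- locomotionResponse(asDff(m, fs), tl, c(30, 101))
  expect_true(isTRUE(attr(few, "undetermined")))
})

test_that("type-I error of the significance pipeline is calibrated", {
  set.seed(77)
  nRep <- 2000; nTrial <- 20
  p <- vapply(seq_len(nRep), function(i)
    responseSignificance(rnorm(nTrial), rnorm(nTrial))$p, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
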