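test_that("a point-mass angle mixture yields a constant preference angle", {
  cfg <- smallCfg(mixture = data.frame(meanDeg = 45, kappa = 1e8,
                                       weight = 1))
  pop <- sampleAxonPopulation(cfg, nAxons = 50)
  expect_true(all(abs(pop$theta_true_deg - 45) < 0.1))
})

test_that("mixture weights control the fraction of aversive-preferring axons", {
  # tight components at 15/75 degrees: cross-mode leakage is negligible,
  # so the fraction above 45 degrees recovers the 0.75 weight
  cfg <- smallCfg(mixture = data.frame(meanDeg = c(15, 75),
                                       kappa = c(30, 30),
                                       weight = c(0.25, 0.75)))
  pop <- sampleAxonPopulation(cfg, nAxons = 10000, seed = 2)
  frac <- mean(pop$theta_true_deg > 45)
  expect_gt(frac, 0.72)
  expect_lt(frac, 0.78)
})

test_that("the generator is deterministic under a seed", {
  cfg <- smallCfg()
  expect_identical(sampleAxonPopulation(cfg, seed = 5),
                   sampleAxonPopulation(cfg, seed = 5))
  s1 <- simulateSession(cfg, seed = 5)
  s2 <- simulateSession(cfg, seed = 5)
  expect_identical(s1$bundle@fluor@values, s2$bundle@fluor@values)
  expect_identical(s1$bundle@behavior@facial, s2$bundle@behavior@facial)
  s3 <- simulateSession(cfg, seed = 6)
  expect_false(identical(s1$bundle@fluor@values, s3$bundle@fluor@values))
})

test_that("trial scheduling reproduces the 7:1:1 mix and 3 s CS-to-US interval", {
  cfg <- smallCfg()
  counts <- c(reward = 0, aversive = 0, control = 0)
  for (seed in 1:40) {
    tl <- generateTimeline(cfg, nTrials = 30, conditioned = TRUE,
                           seed = seed)
    counts <- counts + table(factor(tl$condition, names(counts)))
    iti <- diff(tl$cs_onset_s)
    expect_true(all(iti >= 55 & iti <= 65))
    both <- !is.na(tl$cs_onset_s) & !is.na(tl$us_onset_s)
    expect_true(all(abs(tl$us_onset_s[both] - tl$cs_onset_s[both] - 3)
                    < 1e-9))
  }
  props <- as.numeric(counts / sum(counts))
  expect_lt(max(abs(props - c(7, 1, 1) / 9)), 0.03)
})

test_that("omission trials carry a CS but no US", {
  cfg <- smallCfg()
  tl <- generateTimeline(cfg, nTrials = 60, conditioned = TRUE,
                         omissionRate = 1, seed = 8)
  om <- tl$condition == "reward_omission"
  expect_gt(sum(om), 0)
  expect_true(all(!is.na(tl$cs_onset_s[om])))
  expect_true(all(is.na(tl$us_onset_s[om])))
  # with rate 1 no plain reward trials remain
  expect_false(any(tl$condition == "reward"))
})

test_that("a noiseless reward transient has the ground-truth peak and decay", {
  cfg <- smallCfg(noiseSd = 0, driftAmp = 0, spontRateHz = 0,
                  duplicateProbs = 1, amplitudeRange = c(1, 1))
  axons <- data.frame(axon_id = c("a1", "a2"),
                      theta_true_deg = c(0, 90), magnitude = 1,
                      amp_reward = c(1, 0), amp_aversive = c(0, 1),
                      n_duplicate_rois = 1L)
  tl <- data.frame(trial_id = 1L, condition = "reward", cs_onset_s = NA,
                   cs_freq_hz = NA, us_onset_s = 100, day_index = 1L)
  r <- renderFluorescence(axons, tl, cfg, seed = 1)
  d <- computeDff(r$fluor)
  i0 <- floor(100 * 30) + 1
  # theta = 0 axon: single exponential with peak = amp_reward
  expect_equal(max(d@values[1, ]), 1, tolerance = 0.02)
  expect_equal(which.max(d@values[1, ]), i0)
  decay <- unname(d@values[1, i0 + 15] / d@values[1, i0])  # 0.5 s later
  expect_equal(decay, exp(-1), tolerance = 0.02)
  # theta = 90 axon: no transient on reward
  expect_lt(max(abs(d@values[2, ])), 1e-6)
})

test_that("duplicate ROIs exceed the dedup threshold at default noise", {
  cfg <- smallCfg(duplicateProbs = c(0, 1))    # every axon has 2 ROIs
  rs <- c()
  for (seed in 1:10) {
    s <- simulateSession(cfg, seed = seed)
    d <- computeDff(s$bundle@fluor)
    map <- s$truth$roiMap
    for (ax in unique(map$axon_id)) {
      rois <- which(map$axon_id == ax)
      rs <- c(rs, cor(d@values[rois[1], ], d@values[rois[2], ]))
    }
  }
  expect_gte(mean(rs > 0.65), 0.95)
})

test_that("reward lick latency matches the configured distribution", {
  cfg <- smallCfg()
  lats <- c()
  for (seed in 1:8) {
    tl <- generateTimeline(cfg, nTrials = 25, conditioned = FALSE,
                           seed = seed)
    b <- renderBehavior(tl, cfg, seed = seed)
    lats <- c(lats, b$truth$lick_latencies)
    # and the detector recovers the first post-US lick near that latency
    licks <- detectLicks(b$traces@tongue, b$traces@tongueFsHz, cfg$spoutPos)
    us <- tl$us_onset_s[tl$condition == "reward"]
    first <- vapply(us, function(u) {
      post <- licks[licks >= u]
      if (length(post)) post[1] - u else NA_real_
    }, numeric(1))
    expect_lt(abs(mean(first, na.rm = TRUE) - 0.538), 0.1)
  }
  expect_gt(length(lats), 100)
  expect_lt(abs(mean(lats) - 0.538), 0.02)
  expect_lt(abs(sd(lats) - 0.065), 0.02)
})

test_that("shocks evoke running bouts at the configured probability", {
  cfg <- smallCfg(trialMix = c(reward = 1, aversive = 8, control = 0))
  hits <- 0; total <- 0
  for (seed in 1:12) {
    tl <- generateTimeline(cfg, nTrials = 10, conditioned = FALSE,
                           seed = seed)
    b <- renderBehavior(tl, cfg, seed = seed)
    bouts <- detectRunningBouts(b$traces@speed, b$traces@speedFsHz)
    shocks <- tl$us_onset_s[tl$condition == "aversive"]
    for (u in shocks) {
      total <- total + 1
      hits <- hits + any(bouts$intervals$start_s >= u &
                           bouts$intervals$start_s < u + 2)
    }
  }
  expect_gt(total, 60)
  expect_gt(hits / total, 0.8)
  expect_lt(hits / total, 0.98)
})

test_that("day-1 anticipatory licking sits at the configured floor", {
  cfg <- smallCfg(anticipatoryFloor = 0.05)
  flags <- c()
  for (seed in 1:10) {
    tl <- generateTimeline(cfg, nTrials = 18, conditioned = TRUE,
                           seed = seed)
    b <- renderBehavior(tl, cfg, day = 1, seed = seed)
    flags <- c(flags, b$truth$anticipatory_lick[
      tl$condition %in% c("reward", "reward_omission")])
  }
  expect_lt(mean(flags, na.rm = TRUE), 0.15)
})

test_that("facial features are deterministic, with the configured informative set", {
  cfg <- smallCfg(nFeatures = 60L, nInformative = 5L,
                  facialEffectSize = 2)
  tl <- generateTimeline(cfg, nTrials = 30, conditioned = TRUE, seed = 4)
  f1 <- renderFacialFeatures(tl, cfg, seed = 4)
  f2 <- renderFacialFeatures(tl, cfg, seed = 4)
  expect_identical(f1$features, f2$features)
  expect_length(f1$informative, 5L)
  # informative features separate conditions during the cue window only
  av <- tl$condition == "aversive"
  cue <- f1$timesS >= 0
  if (any(av)) {
    inf <- f1$informative[1]
    sep <- mean(f1$features[av, cue, inf]) -
      mean(f1$features[!av, cue, inf])
    expect_gt(sep, 1)
    pre <- mean(f1$features[av, !cue, inf]) -
      mean(f1$features[!av, !cue, inf])
    expect_lt(abs(pre), 0.8)
  }
})

test_that("generator output satisfies the bundle invariants (no NaN, validity)", {
  s <- simulateSession(smallCfg(), seed = 13)
  expect_true(validObject(s$bundle))
  expect_false(anyNA(s$bundle@fluor@values))
  expect_lt(s$truth$clippedFrac, 0.01)
})
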