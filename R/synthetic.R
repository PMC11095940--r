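# Synthetic-session generator: produces SessionBundles with the statistical
# structure the analysis assumes (transient kernels on a drifting baseline,
# duplicated ROIs per axon, 7:1:1 trial scheduling, trace-conditioning
# timing, learning curves) together with ground truth for recovery tests.

#' Simulation configuration
#'
#' Builds the parameter list that defines the synthetic study conditions.
#' Defaults follow the experimental design the analysis targets: a 7:1:1
#' reward:aversive:control trial mix with 55-65 s inter-trial intervals, a
#' 2 s tone plus 1 s trace delay before the unconditioned stimulus, a lick
#' latency of 0.538 +/- 0.065 s after reward, shock-evoked running, and a
#' bimodal axon-preference angle mixture with modes near 15 and 75 degrees
#' (aversive-preferring majority).
#'
#' @param nAxons number of ground-truth axons per population.
#' @param nTrials trials per session.
#' @param mixture data.frame with columns `meanDeg`, `kappa`, `weight`
#'   describing the von Mises mixture of preference angles.
#' @param amplitudeRange range of peak dF/F response magnitudes per axon.
#' @param kernelTauS calcium transient decay constant, seconds.
#' @param noiseSd per-frame Gaussian noise, as a fraction of baseline F.
#' @param baselineRange raw baseline fluorescence range (arbitrary units).
#' @param driftAmp,driftPeriodS slow multiplicative baseline drift
#'   (fractional amplitude; period in seconds).
#' @param trialMix named weights for reward/aversive/control scheduling.
#' @param itiRangeS inter-trial-interval range, seconds.
#' @param csDurationS,traceDelayS tone duration and stimulus-free delay, s.
#' @param lickLatencyMeanS,lickLatencySdS latency of the first lick after
#'   reward delivery.
#' @param lickRateHz within-bout lick rate.
#' @param anticipatoryFloor,anticipatoryCeiling,learningMidDay,learningRateDays
#'   logistic learning curve for anticipatory licking after the reward cue
#'   (probability per trial); the same curve shape drives anticipatory
#'   running after the aversive cue between `anticipatoryRunFloor` and
#'   `anticipatoryRunCeiling`.
#' @param anticipatoryRunFloor,anticipatoryRunCeiling see above.
#' @param runShockProb probability of a running bout within 2 s of a shock.
#' @param spontRateHz spontaneous calcium-transient rate per axon.
#' @param spontRunRateHz spontaneous locomotion-bout rate.
#' @param csBaseAmpFrac day-1 conditioned-cue response amplitude, as a
#'   fraction of the axon's unconditioned amplitude (equal for both cues:
#'   cue preference is absent before learning).
#' @param csAversiveGainRamp late-learning multiplier of the aversive-cue
#'   response in aversive-preferring axons.
#' @param usHabituation late-learning multiplier on unconditioned responses.
#' @param duplicateProbs probabilities that an axon is captured by 1, 2, 3
#'   ROIs.
#' @param dupScaleRange per-duplicate multiplicative gain range.
#' @param fsImagingHz,fsTongueHz,fsSpeedHz sampling rates.
#' @param spoutPos spout position in camera units (tongue trace crosses
#'   half of it during a lick).
#' @param shiftSdPx frame-to-frame registration shift SD, pixels.
#' @param pixelSizeUm microns per pixel (16 px = 5 um).
#' @param nFeatures,nInformative,facialEffectSize facial-feature array:
#'   total features, condition-coupled features, and their standardized
#'   mean shift (0 makes the array uninformative).
#' @param facialFsHz,facialSpanS,facialEffectWindowS facial frame rate,
#'   covered span and effect window relative to CS onset, seconds.
#' @param locomotionCouplingAmp dF/F transient added at spontaneous
#'   locomotion initiations (0 = no coupling, the study's null).
#' @param correctnessCoupling extra multiplicative gain on the aversive-cue
#'   response in behaviorally correct aversive trials (0 = none).
#' @param seed default seed for generator calls.
#' @return a named list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    nAxons = 40L, nTrials = 18L,
    mixture = data.frame(meanDeg = c(15, 75), kappa = c(20, 20),
                         weight = c(0.25, 0.75)),
    amplitudeRange = c(0.5, 1.5), kernelTauS = 0.5, noiseSd = 0.03,
    baselineRange = c(80, 120), driftAmp = 0.05, driftPeriodS = 300,
    trialMix = c(reward = 7, aversive = 1, control = 1),
    itiRangeS = c(55, 65), csDurationS = 2, traceDelayS = 1,
    lickLatencyMeanS = 0.538, lickLatencySdS = 0.065, lickRateHz = 8,
    anticipatoryFloor = 0.05, anticipatoryCeiling = 0.85,
    learningMidDay = 6, learningRateDays = 2,
    anticipatoryRunFloor = 0.05, anticipatoryRunCeiling = 0.7,
    runShockProb = 0.9, spontRateHz = 0.1, spontRunRateHz = 1 / 60,
    csBaseAmpFrac = 0.4, csAversiveGainRamp = 3, usHabituation = 0.6,
    duplicateProbs = c(0.70, 0.25, 0.05), dupScaleRange = c(0.7, 1.3),
    fsImagingHz = 30, fsTongueHz = 65, fsSpeedHz = 100, spoutPos = 1,
    shiftSdPx = 0.5, pixelSizeUm = 5 / 16,
    nFeatures = 500L, nInformative = 20L, facialEffectSize = 1.5,
    facialFsHz = 10, facialSpanS = c(-1, 2), facialEffectWindowS = c(0, 2),
    locomotionCouplingAmp = 0, correctnessCoupling = 0, seed = 1L) {
  cfg <- as.list(environment())
  if (!nrow(cfg$mixture) || any(cfg$mixture$weight < 0) ||
      sum(cfg$mixture$weight) <= 0)
    stop("mixture must have nonnegative weights with positive sum")
  if (any(cfg$trialMix < 0) || sum(cfg$trialMix) <= 0)
    stop("trialMix weights must be >= 0 and sum > 0")
  stopifnot(cfg$itiRangeS[1] <= cfg$itiRangeS[2], cfg$kernelTauS > 0)
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

# von Mises sampler (Best & Fisher rejection scheme); mu, result in radians.
rVonMises <- function(n, muRad, kappa) {
  if (kappa < 1e-8) return(runif(n, muRad - pi, muRad + pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1]); f <- (1 + r * z) / (r + z); cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- muRad + sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  out
}

#' Sample a ground-truth axon population
#'
#' Draws preference angles from the configured circular (von Mises)
#' mixture and assigns response amplitudes `ampReward = A cos(theta)`,
#' `ampAversive = A sin(theta)` plus a duplicate-ROI count per axon.
#'
#' @param cfg a [simulationConfig()].
#' @param nAxons number of axons (defaults to `cfg$nAxons`).
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return data.frame: `axon_id`, `theta_true_deg`, `magnitude`,
#'   `amp_reward`, `amp_aversive`, `n_duplicate_rois`.
#' @export
sampleAxonPopulation <- function(cfg, nAxons = cfg$nAxons,
                                 seed = cfg$seed) {
  mx <- cfg$mixture
  withSeed(deriveSeed(seed, "axons"), {
    comp <- sample.int(nrow(mx), nAxons, replace = TRUE,
                       prob = mx$weight / sum(mx$weight))
    theta <- numeric(nAxons)
    for (k in seq_len(nrow(mx))) {
      idx <- which(comp == k)
      if (length(idx))
        theta[idx] <- wrapDeg(rVonMises(length(idx),
                                        mx$meanDeg[k] * pi / 180,
                                        mx$kappa[k]) / pi * 180)
    }
    A <- runif(nAxons, cfg$amplitudeRange[1], cfg$amplitudeRange[2])
    ndup <- sample.int(length(cfg$duplicateProbs), nAxons, replace = TRUE,
                       prob = cfg$duplicateProbs)
    data.frame(axon_id = sprintf("axon_%03d", seq_len(nAxons)),
               theta_true_deg = theta, magnitude = A,
               amp_reward = A * cos(theta * pi / 180),
               amp_aversive = A * sin(theta * pi / 180),
               n_duplicate_rois = as.integer(ndup),
               stringsAsFactors = FALSE)
  })
}

#' Generate a trial timeline
#'
#' Schedules `nTrials` trials with inter-trial intervals drawn uniformly
#' from `cfg$itiRangeS` and conditions drawn multinomially from
#' `cfg$trialMix`. In conditioned sessions each non-control trial carries
#' a CS onset with the US following `csDurationS + traceDelayS` later;
#' a fraction `omissionRate` of reward trials become reward-omission
#' trials (CS but no US). Control trials store their scheduled (silent)
#' anchor time in `cs_onset_s` for bookkeeping.
#'
#' @param cfg a [simulationConfig()].
#' @param nTrials number of trials (>= 1).
#' @param conditioned is this a conditioned (tone-paired) session?
#' @param omissionRate fraction of reward trials with the reward withheld.
#' @param day day index recorded in the timeline.
#' @param seed integer seed.
#' @param leadInS quiet time before the first trial, seconds.
#' @return a timeline data.frame (see [validateTimeline()]).
#' @export
generateTimeline <- function(cfg, nTrials = cfg$nTrials, conditioned = TRUE,
                             omissionRate = 0, day = 1L, seed = cfg$seed,
                             leadInS = 35) {
  stopifnot(nTrials >= 1)
  csUs <- cfg$csDurationS + cfg$traceDelayS
  withSeed(deriveSeed(seed, paste0("timeline", day)), {
    iti <- runif(nTrials, cfg$itiRangeS[1], cfg$itiRangeS[2])
    anchor <- leadInS + cumsum(iti) - iti[1]
    cond <- sample(names(cfg$trialMix), nTrials, replace = TRUE,
                   prob = cfg$trialMix / sum(cfg$trialMix))
    if (conditioned && omissionRate > 0) {
      rew <- which(cond == "reward")
      om <- rew[runif(length(rew)) < omissionRate]
      cond[om] <- "reward_omission"
    }
    cs <- us <- freq <- rep(NA_real_, nTrials)
    if (conditioned) {
      cs <- anchor
      us <- ifelse(cond %in% c("reward", "aversive"), anchor + csUs, NA_real_)
      freq <- ifelse(cond %in% c("reward", "reward_omission"), 9000,
                     ifelse(cond == "aversive", 13000, NA_real_))
    } else {
      us <- ifelse(cond %in% c("reward", "aversive"), anchor, NA_real_)
      cs[cond == "control"] <- anchor[cond == "control"]
    }
    tl <- data.frame(trial_id = seq_len(nTrials), condition = cond,
                     cs_onset_s = cs, cs_freq_hz = freq, us_onset_s = us,
                     day_index = as.integer(day), stringsAsFactors = FALSE)
    validateTimeline(tl, csUsIntervalS = csUs)
    canonicalTimeline(tl)
  })
}

# Logistic learning level in [0, 1]; ~0 on day 1 by construction of the
# default midpoint.
learnLevel <- function(cfg, day) {
  raw <- function(d) 1 / (1 + exp(-(d - cfg$learningMidDay) /
                                    cfg$learningRateDays))
  (raw(day) - raw(1)) / (1 - raw(1))
}

# Per-axon CS amplitudes for a given day. Aversive-preferring axons
# (theta > 45) gain aversive-cue response across learning; reward-
# preferring axons grow both cue responses moderately.
csAmplitudes <- function(cfg, axons, day) {
  g <- learnLevel(cfg, day)
  base <- cfg$csBaseAmpFrac * axons$magnitude
  aversivePref <- axons$theta_true_deg > 45
  csRew <- ifelse(aversivePref, base * (1 - 0.3 * g), base * (1 + 0.5 * g))
  csAv <- ifelse(aversivePref,
                 base * (1 + (cfg$csAversiveGainRamp - 1) * g),
                 base * (1 + 0.3 * g))
  list(cs_reward = csRew, cs_aversive = csAv,
       usGain = 1 - (1 - cfg$usHabituation) * g)
}

# Add an instantaneous-rise, exponential-decay kernel to `sig` (in place
# semantics via return) for each event row (time_s, amp).
addKernels <- function(sig, events, fs, tau) {
  n <- length(sig)
  span <- ceiling(8 * tau * fs)
  for (k in seq_len(nrow(events))) {
    i0 <- floor(events$time_s[k] * fs) + 1L
    if (i0 > n) next
    idx <- i0:min(n, i0 + span)
    tRel <- ((idx - 1L) / fs) - events$time_s[k]
    tRel[tRel < 0] <- 0
    sig[idx] <- sig[idx] + events$amp[k] * exp(-tRel / tau)
  }
  sig
}

#' Render synthetic raw fluorescence for an axon population
#'
#' Each ROI trace is `B0 * (1 + drift + signal + noise)` where `signal`
#' is a sum of instantaneous-rise exponential-decay transients (decay
#' `cfg$kernelTauS`) triggered by the axon's unconditioned, conditioned
#' and spontaneous events. Duplicate ROIs of one axon share the event
#' train exactly (with a per-ROI gain) but receive independent noise, so
#' their dF/F correlation exceeds the deduplication threshold at default
#' noise. Negative raw values are clipped at zero (with a warning above
#' 1 percent clipping).
#'
#' @param axons population from [sampleAxonPopulation()].
#' @param tl timeline from [generateTimeline()].
#' @param cfg a [simulationConfig()].
#' @param day day index (drives learning-dependent CS/US gains).
#' @param seed integer seed.
#' @param extraEvents optional data.frame (`time_s`, `amp`) of transients
#'   added to every axon (e.g. locomotion-coupled activity).
#' @param trialGain optional numeric vector (one entry per timeline row)
#'   multiplying that trial's CS response amplitude.
#' @return list: `fluor` ([FluorescenceMatrix-class]), `roiMap`
#'   (data.frame `roi_id`, `axon_id`, `gain`), `clippedFrac`.
#' @export
renderFluorescence <- function(axons, tl, cfg, day = 1L, seed = cfg$seed,
                               extraEvents = NULL, trialGain = NULL) {
  fs <- cfg$fsImagingHz
  span <- sessionSpan(tl) + 20
  nFrames <- as.integer(ceiling(span * fs))
  tGrid <- (seq_len(nFrames) - 1L) / fs
  csAmp <- csAmplitudes(cfg, axons, day)
  if (is.null(trialGain)) trialGain <- rep(1, nrow(tl))
  withSeed(deriveSeed(seed, paste0("fluor", day)), {
    nRoi <- sum(axons$n_duplicate_rois)
    values <- matrix(0, nRoi, nFrames)
    roiMap <- data.frame(roi_id = character(0), axon_id = character(0),
                         gain = numeric(0), stringsAsFactors = FALSE)
    clipped <- 0
    roi <- 0L
    for (a in seq_len(nrow(axons))) {
      ev <- list()
      rewUS <- which(tl$condition == "reward" & !is.na(tl$us_onset_s))
      avUS <- which(tl$condition == "aversive" & !is.na(tl$us_onset_s))
      if (length(rewUS))
        ev[[length(ev) + 1L]] <- data.frame(
          time_s = tl$us_onset_s[rewUS],
          amp = axons$amp_reward[a] * csAmp$usGain)
      if (length(avUS))
        ev[[length(ev) + 1L]] <- data.frame(
          time_s = tl$us_onset_s[avUS],
          amp = axons$amp_aversive[a] * csAmp$usGain)
      csRew <- which(tl$condition %in% c("reward", "reward_omission") &
                       !is.na(tl$cs_onset_s) & !is.na(tl$cs_freq_hz))
      csAv <- which(tl$condition == "aversive" & !is.na(tl$cs_onset_s) &
                      !is.na(tl$cs_freq_hz))
      if (length(csRew))
        ev[[length(ev) + 1L]] <- data.frame(
          time_s = tl$cs_onset_s[csRew],
          amp = csAmp$cs_reward[a] * trialGain[csRew])
      if (length(csAv))
        ev[[length(ev) + 1L]] <- data.frame(
          time_s = tl$cs_onset_s[csAv],
          amp = csAmp$cs_aversive[a] * trialGain[csAv])
      nSpont <- rpois(1, cfg$spontRateHz * span)
      if (nSpont > 0)
        ev[[length(ev) + 1L]] <- data.frame(
          time_s = runif(nSpont, 0, span),
          amp = axons$magnitude[a] * runif(nSpont, 0.5, 1))
      if (!is.null(extraEvents) && nrow(extraEvents))
        ev[[length(ev) + 1L]] <- extraEvents
      events <- do.call(rbind, ev)
      sig <- addKernels(numeric(nFrames), events, fs, cfg$kernelTauS)
      for (d in seq_len(axons$n_duplicate_rois[a])) {
        roi <- roi + 1L
        gain <- if (d == 1L) 1 else runif(1, cfg$dupScaleRange[1],
                                          cfg$dupScaleRange[2])
        b0 <- runif(1, cfg$baselineRange[1], cfg$baselineRange[2])
        drift <- cfg$driftAmp * sin(2 * pi * tGrid / cfg$driftPeriodS +
                                      runif(1, 0, 2 * pi))
        tr <- b0 * (1 + drift + gain * sig + rnorm(nFrames, 0, cfg$noiseSd))
        clipped <- clipped + sum(tr < 0)
        values[roi, ] <- pmax(tr, 0)
        roiMap <- rbind(roiMap, data.frame(
          roi_id = sprintf("roi_%03d", roi), axon_id = axons$axon_id[a],
          gain = gain, stringsAsFactors = FALSE))
      }
    }
    clippedFrac <- clipped / length(values)
    if (clippedFrac > 0.01)
      warning(sprintf("%.2f%% of frames clipped at zero fluorescence",
                      100 * clippedFrac))
    list(fluor = fluorescenceMatrix(values, fs, roiMap$roi_id),
         roiMap = roiMap, clippedFrac = clippedFrac)
  })
}

# Stamp a lick bout (licks at cfg$lickRateHz, two-frame tongue protrusions
# above the spout) into a tongue trace; returns the modified trace.
stampLickBout <- function(tongue, fs, startS, durS, cfg) {
  n <- length(tongue)
  lickTimes <- seq(startS, startS + durS, by = 1 / cfg$lickRateHz)
  for (lt in lickTimes) {
    i0 <- floor(lt * fs) + 1L
    if (i0 > n) next
    idx <- i0:min(n, i0 + 1L)
    tongue[idx] <- 1.1 * cfg$spoutPos
  }
  tongue
}

#' Render synthetic behavior traces
#'
#' Generates the tongue-position and treadmill-speed traces implied by a
#' timeline: consummatory lick bouts follow reward delivery at the
#' configured latency, anticipatory licking after the reward cue follows
#' the logistic learning curve, shocks evoke running (probability
#' `cfg$runShockProb`), anticipatory running after the aversive cue
#' grows with learning, and spontaneous locomotion bouts occur at
#' `cfg$spontRunRateHz`. The speed baseline is noisy-positive.
#'
#' @param tl timeline data.frame.
#' @param cfg a [simulationConfig()].
#' @param day day index (drives the learning curves).
#' @param seed integer seed.
#' @return list: `traces` ([BehaviorTraces-class], facial slot empty) and
#'   `truth` (per-trial anticipatory-lick/run flags, reward lick
#'   latencies, spontaneous bout start times).
#' @export
renderBehavior <- function(tl, cfg, day = 1L, seed = cfg$seed) {
  span <- sessionSpan(tl) + 20
  fsT <- cfg$fsTongueHz; fsS <- cfg$fsSpeedHz
  nT <- as.integer(ceiling(span * fsT)); nS <- as.integer(ceiling(span * fsS))
  csUs <- cfg$csDurationS + cfg$traceDelayS
  withSeed(deriveSeed(seed, paste0("behavior", day)), {
    tongue <- rnorm(nT, 0, 0.02)
    speed <- pmax(0, rnorm(nS, 0.3, 0.1))
    g <- learnLevel(cfg, day)
    pLick <- cfg$anticipatoryFloor +
      (cfg$anticipatoryCeiling - cfg$anticipatoryFloor) * g
    pRun <- cfg$anticipatoryRunFloor +
      (cfg$anticipatoryRunCeiling - cfg$anticipatoryRunFloor) * g
    antLick <- antRun <- rep(NA, nrow(tl))
    latencies <- numeric(0)
    conditioned <- !is.na(tl$cs_onset_s) & !is.na(tl$cs_freq_hz)
    stampRun <- function(speed, startS, durS, amp = 3) {
      i0 <- floor(startS * fsS) + 1L
      idx <- i0:min(nS, i0 + ceiling(durS * fsS))
      if (i0 <= nS) speed[idx] <- speed[idx] + amp
      speed
    }
    for (i in seq_len(nrow(tl))) {
      cond <- tl$condition[i]
      if (cond == "reward" && !is.na(tl$us_onset_s[i])) {
        lat <- max(0.2, rnorm(1, cfg$lickLatencyMeanS, cfg$lickLatencySdS))
        latencies <- c(latencies, lat)
        tongue <- stampLickBout(tongue, fsT, tl$us_onset_s[i] + lat, 2, cfg)
      }
      if (cond == "aversive" && !is.na(tl$us_onset_s[i]) &&
          runif(1) < cfg$runShockProb)
        speed <- stampRun(speed, tl$us_onset_s[i] + runif(1, 0.1, 0.3),
                          runif(1, 1, 2))
      if (conditioned[i]) {
        usT <- tl$cs_onset_s[i] + csUs
        if (cond %in% c("reward", "reward_omission")) {
          antLick[i] <- runif(1) < pLick
          if (antLick[i])
            tongue <- stampLickBout(tongue, fsT,
                                    tl$cs_onset_s[i] + runif(1, 1.5, 2.2),
                                    usT - tl$cs_onset_s[i] - 2.3, cfg)
          antRun[i] <- FALSE
        } else if (cond == "aversive") {
          antLick[i] <- runif(1) < cfg$anticipatoryFloor
          if (antLick[i])
            tongue <- stampLickBout(tongue, fsT,
                                    tl$cs_onset_s[i] + runif(1, 1.5, 2.2),
                                    0.5, cfg)
          antRun[i] <- runif(1) < pRun
          if (antRun[i])
            speed <- stampRun(speed, tl$cs_onset_s[i] + runif(1, 1.5, 2.2),
                              1)
        }
      }
    }
    nSpont <- rpois(1, cfg$spontRunRateHz * span)
    spont <- sort(runif(nSpont, 5, span - 5))
    for (s in spont) speed <- stampRun(speed, s, runif(1, 0.5, 1.5))
    list(traces = behaviorTraces(tongue, fsT, speed, fsS),
         truth = list(anticipatory_lick = antLick, anticipatory_run = antRun,
                      lick_latencies = latencies, spont_run_starts = spont))
  })
}

#' Render synthetic facial-feature arrays
#'
#' Emulates precomputed per-frame facial-expression embeddings: i.i.d.
#' standard-normal features for every trial and frame, with
#' `cfg$nInformative` features shifted by `cfg$facialEffectSize` standard
#' deviations during the effect window on aversive trials. An effect size
#' of zero makes the array carry no class information.
#'
#' @param tl timeline data.frame (one array row per timeline row).
#' @param cfg a [simulationConfig()].
#' @param seed integer seed.
#' @return list: `features` (trial x frame x feature array), `timesS`
#'   (frame times relative to CS onset), `informative` (feature indices).
#' @export
renderFacialFeatures <- function(tl, cfg, seed = cfg$seed) {
  stopifnot(cfg$nFeatures >= 1)
  times <- seq(cfg$facialSpanS[1], cfg$facialSpanS[2] - 1e-9,
               by = 1 / cfg$facialFsHz)
  nTr <- nrow(tl); nFr <- length(times); nFt <- cfg$nFeatures
  withSeed(deriveSeed(seed, "facial"), {
    arr <- array(rnorm(nTr * nFr * nFt), dim = c(nTr, nFr, nFt))
    inf <- sample.int(nFt, min(cfg$nInformative, nFt))
    if (cfg$facialEffectSize != 0) {
      effFr <- which(times >= cfg$facialEffectWindowS[1] &
                       times < cfg$facialEffectWindowS[2])
      avTr <- which(tl$condition == "aversive")
      if (length(avTr) && length(effFr))
        arr[avTr, effFr, inf] <- arr[avTr, effFr, inf] +
          cfg$facialEffectSize
    }
    list(features = arr, timesS = times, informative = sort(inf))
  })
}

#' Simulate one complete session
#'
#' Composes [generateTimeline()], [renderFluorescence()],
#' [renderBehavior()] and (for conditioned sessions)
#' [renderFacialFeatures()] into a validated [SessionBundle-class], with
#' full ground truth for parameter-recovery tests.
#'
#' @param cfg a [simulationConfig()].
#' @param axons optional fixed axon population (sampled if `NULL`); pass
#'   the same population across days to emulate longitudinal imaging.
#' @param day day index.
#' @param conditioned conditioned (tone-paired) session?
#' @param nTrials trials in the session.
#' @param omissionRate fraction of reward trials with reward withheld.
#' @param seed integer seed.
#' @return list: `bundle` ([SessionBundle-class]) and `truth` (axon table,
#'   ROI map, behavior truth, informative facial features).
#' @export
simulateSession <- function(cfg, axons = NULL, day = 1L, conditioned = TRUE,
                            nTrials = cfg$nTrials, omissionRate = 0,
                            seed = cfg$seed) {
  if (is.null(axons)) axons <- sampleAxonPopulation(cfg, seed = seed)
  tl <- generateTimeline(cfg, nTrials, conditioned, omissionRate, day, seed)
  beh <- renderBehavior(tl, cfg, day, seed)
  trialGain <- NULL
  if (cfg$correctnessCoupling > 0 && conditioned) {
    trialGain <- rep(1, nrow(tl))
    correctAv <- which(tl$condition == "aversive" &
                         !beh$truth$anticipatory_lick)
    trialGain[correctAv] <- 1 + cfg$correctnessCoupling
  }
  extra <- NULL
  if (cfg$locomotionCouplingAmp > 0 &&
      length(beh$truth$spont_run_starts))
    extra <- data.frame(time_s = beh$truth$spont_run_starts,
                        amp = cfg$locomotionCouplingAmp)
  fl <- renderFluorescence(axons, tl, cfg, day, seed,
                           extraEvents = extra, trialGain = trialGain)
  nFrames <- ncol(traceValues(fl$fluor))
  shifts <- withSeed(deriveSeed(seed, paste0("shifts", day)),
                     matrix(rnorm(2 * nFrames, 0, cfg$shiftSdPx),
                            ncol = 2, dimnames = list(NULL, c("x_px", "y_px"))))
  traces <- beh$traces
  facialInf <- integer(0)
  if (conditioned) {
    fac <- renderFacialFeatures(tl, cfg, seed = deriveSeed(seed,
                                                           paste0("fac", day)))
    traces <- behaviorTraces(traces@tongue, traces@tongueFsHz,
                             traces@speed, traces@speedFsHz,
                             fac$features, fac$timesS)
    facialInf <- fac$informative
  }
  bundle <- sessionBundle(
    timeline = tl, fluor = fl$fluor, shifts = shifts,
    pixelSizeUm = cfg$pixelSizeUm, behavior = traces,
    meta = list(animal = "sim", day = as.integer(day),
                cs_us_interval_s = cfg$csDurationS + cfg$traceDelayS,
                conditioned = conditioned, seed = as.integer(seed)))
  list(bundle = bundle,
       truth = list(axons = axons, roiMap = fl$roiMap,
                    behavior = beh$truth, facialInformative = facialInf,
                    clippedFrac = fl$clippedFrac))
}

#' Simulate a multi-day conditioning experiment
#'
#' One unconditioned pre-training session (day 0; used to define valence
#' preference before learning, as in the study design) followed by
#' `nDays` conditioned sessions sharing the same axon population.
#'
#' @param cfg a [simulationConfig()].
#' @param nDays number of conditioned days.
#' @param seed integer seed.
#' @param omissionLastDay apply `omissionRate` (1/7 of reward trials) on
#'   the last day?
#' @return list: `pretraining` (a [simulateSession()] result), `days`
#'   (list of results, one per day), `axons` (shared ground truth).
#' @export
simulateExperiment <- function(cfg, nDays = 12L, seed = cfg$seed,
                               omissionLastDay = FALSE) {
  axons <- sampleAxonPopulation(cfg, seed = seed)
  pre <- simulateSession(cfg, axons, day = 0L, conditioned = FALSE,
                         seed = deriveSeed(seed, "day0"))
  days <- lapply(seq_len(nDays), function(d) {
    om <- if (omissionLastDay && d == nDays) 1 / 7 else 0
    simulateSession(cfg, axons, day = d, conditioned = TRUE,
                    omissionRate = om, seed = deriveSeed(seed, paste0("d", d)))
  })
  list(pretraining = pre, days = days, axons = axons)
}
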