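# Lick and locomotion event detection, anticipatory-behavior rates,
# learning-phase partitioning. All detectors are pure functions of their
# inputs.

#' Detect lick events from a tongue-position keypoint trace
#'
#' A lick is an upward crossing of the tongue position past
#' `spoutPos * extendFrac` (the tongue extending toward the spout),
#' debounced so that crossings closer than `minGapS` count once. The
#' event rule itself is a configurable artifact of this pipeline (a
#' TTL lick-sensor stream can be passed downstream instead).
#'
#' @param tongue per-frame tongue position (camera units).
#' @param fs camera rate, Hz.
#' @param spoutPos spout position in the same units.
#' @param extendFrac crossing threshold as a fraction of `spoutPos`.
#' @param minGapS debounce interval, seconds.
#' @return numeric vector of lick times (s), sorted.
#' @export
detectLicks <- function(tongue, fs, spoutPos, extendFrac = 0.5,
                        minGapS = 0.05) {
  thr <- spoutPos * extendFrac
  above <- tongue > thr
  onsets <- which(above & !c(FALSE, head(above, -1)))
  times <- (onsets - 1) / fs
  if (length(times) > 1) {
    # debounce relative to the last *kept* event
    last <- times[1]; out <- times[1]
    for (t in times[-1]) if (t - last >= minGapS) { out <- c(out, t); last <- t }
    times <- out
  }
  times
}

#' Detect locomotion bouts and initiations from treadmill speed
#'
#' The locomotion threshold is the session median plus `kSd` times the
#' session standard deviation of the speed trace (population SD, rank
#' and affine invariant as a detector). Bouts are maximal
#' supra-threshold runs lasting at least `minDurS`; an initiation is a
#' bout start preceded by at least `quiesceS` seconds below threshold.
#' A constant trace (SD = 0) yields no bouts (strict inequality).
#'
#' @param speed per-sample treadmill speed.
#' @param fs sampling rate, Hz.
#' @param kSd threshold multiplier on the SD (default 0.5).
#' @param minDurS minimum bout duration, seconds (default 0.2).
#' @param quiesceS minimum pre-initiation quiescence, seconds (0.5).
#' @return list: `intervals` (data.frame `start_s`, `end_s`, half-open),
#'   `initiations_s`, `threshold`.
#' @export
detectRunningBouts <- function(speed, fs, kSd = 0.5, minDurS = 0.2,
                               quiesceS = 0.5) {
  stopifnot(length(speed) >= quiesceS * fs)
  thr <- median(speed) + kSd * sd(speed)
  above <- speed > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runIdx <- which(r$values & r$lengths >= minDurS * fs)
  intervals <- data.frame(start_s = (starts[runIdx] - 1L) / fs,
                          end_s = ends[runIdx] / fs)
  inits <- numeric(0)
  for (k in runIdx) {
    pre <- starts[k] - 1L
    if (pre >= quiesceS * fs &&
        all(!above[(pre - floor(quiesceS * fs) + 1L):pre]))
      inits <- c(inits, (starts[k] - 1L) / fs)
  }
  list(intervals = intervals, initiations_s = inits, threshold = thr)
}

#' Anticipatory behavior between CS and US onsets
#'
#' Flags each conditioned trial in which at least one behavioral event
#' (a lick time, or any overlap of a locomotion bout) falls in the
#' half-open window from the CS onset to the (expected) US onset, and
#' summarises rates per condition. An event exactly at the US onset is
#' not anticipatory.
#'
#' @param events either a numeric vector of lick times or the bout list
#'   returned by [detectRunningBouts()].
#' @param tl conditioned timeline data.frame.
#' @param csUsIntervalS expected CS-to-US interval (locates the window
#'   end on omission trials).
#' @return list: `perTrial` (data.frame `trial_id`, `condition`,
#'   `anticipatory`) and `rates` (per condition with trial counts).
#' @export
anticipatoryResponse <- function(events, tl, csUsIntervalS = 3) {
  hasCs <- !is.na(tl$cs_onset_s) & !is.na(tl$cs_freq_hz)
  if (!any(hasCs))
    stop("anticipatory analysis requires a conditioned session")
  idx <- which(hasCs)
  w0 <- tl$cs_onset_s[idx]
  w1 <- ifelse(is.na(tl$us_onset_s[idx]), w0 + csUsIntervalS,
               tl$us_onset_s[idx])
  flag <- if (is.list(events)) {
    iv <- events$intervals
    vapply(seq_along(idx), function(i)
      any(iv$start_s < w1[i] & iv$end_s > w0[i]), logical(1))
  } else {
    vapply(seq_along(idx), function(i)
      any(events >= w0[i] & events < w1[i]), logical(1))
  }
  perTrial <- data.frame(trial_id = tl$trial_id[idx],
                         condition = tl$condition[idx],
                         anticipatory = flag, stringsAsFactors = FALSE)
  rates <- aggregate(anticipatory ~ condition, perTrial, mean)
  rates$n_trials <- as.integer(table(perTrial$condition)[rates$condition])
  names(rates)[2] <- "rate"
  list(perTrial = perTrial, rates = rates)
}

#' Partition conditioning days into learning phases
#'
#' Day 1 is always its own `first_day` phase; the remaining days are
#' split into `nPhases` contiguous blocks of as-equal-as-possible
#' duration, earlier blocks taking the extra day. With `nPhases = 3` the
#' blocks are labeled `early`, `middle`, `late`; other values get
#' `phase_1 ... phase_n` (the six-period variant included).
#'
#' @param days ordered vector of day indices (>= nPhases + 1 days).
#' @param nPhases number of post-first-day phases (default 3).
#' @return data.frame `day`, `phase` (factor in temporal order).
#' @export
splitPhases <- function(days, nPhases = 3) {
  days <- sort(unique(days))
  if (length(days) < nPhases + 1)
    stop("need at least ", nPhases + 1, " days for ", nPhases, " phases")
  rest <- days[-1]
  sizes <- rep(length(rest) %/% nPhases, nPhases)
  extra <- length(rest) %% nPhases
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- if (nPhases == 3) c("early", "middle", "late") else
    sprintf("phase_%d", seq_len(nPhases))
  phase <- c("first_day", rep(labels, times = sizes))
  data.frame(day = days,
             phase = factor(phase, levels = c("first_day", labels)))
}
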