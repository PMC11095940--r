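# Event-triggered response extraction, amplitude quantification and
# per-axon significance testing.

EVENT_KINDS <- c("us_reward", "us_aversive", "cs_reward", "cs_aversive",
                 "locomotion_init", "reward_omission")

# Select trials and the (t0, control anchor) pair for an event kind.
# For conditioned trials the control window is anchored at the CS onset
# (baseline before the predictive cue) for both CS and US responses.
eventAnchors <- function(tl, eventKind, csUsIntervalS) {
  hasCs <- !is.na(tl$cs_onset_s) & !is.na(tl$cs_freq_hz)
  switch(eventKind,
    us_reward = {
      i <- which(tl$condition == "reward" & !is.na(tl$us_onset_s))
      list(idx = i, t0 = tl$us_onset_s[i],
           anchor = ifelse(hasCs[i], tl$cs_onset_s[i], tl$us_onset_s[i]))
    },
    us_aversive = {
      i <- which(tl$condition == "aversive" & !is.na(tl$us_onset_s))
      list(idx = i, t0 = tl$us_onset_s[i],
           anchor = ifelse(hasCs[i], tl$cs_onset_s[i], tl$us_onset_s[i]))
    },
    cs_reward = {
      i <- which(tl$condition %in% c("reward", "reward_omission") & hasCs)
      list(idx = i, t0 = tl$cs_onset_s[i], anchor = tl$cs_onset_s[i])
    },
    cs_aversive = {
      i <- which(tl$condition == "aversive" & hasCs)
      list(idx = i, t0 = tl$cs_onset_s[i], anchor = tl$cs_onset_s[i])
    },
    reward_omission = {
      i <- which(tl$condition == "reward_omission" & !is.na(tl$cs_onset_s))
      list(idx = i, t0 = tl$cs_onset_s[i] + csUsIntervalS,
           anchor = tl$cs_onset_s[i])
    },
    stop("unknown event kind: ", eventKind))
}

#' Extract event-aligned dF/F trial slices
#'
#' Slices the dF/F matrix around each qualifying event into an
#' axon x trial x time tensor. Window boundaries are snapped to the
#' nearest frame at or before the boundary (frame `i` covers
#' `[i/fs, (i+1)/fs)`); no interpolation is performed. The signal window
#' is `[0, postS)` from the aligning onset; the control window is
#' `[-preS, 0)` from the control anchor, which for conditioned trials is
#' the CS onset (for both CS- and US-aligned tensors) and otherwise the
#' event onset itself. Trials whose windows fall outside the recording
#' are dropped and counted in the alignment metadata.
#'
#' @param dff a [DffMatrix-class] (typically axon representatives).
#' @param tl timeline data.frame.
#' @param eventKind one of `us_reward`, `us_aversive`, `cs_reward`,
#'   `cs_aversive`, `reward_omission`, `locomotion_init`.
#' @param preS,postS control/signal window lengths, seconds. For
#'   reward-omission analyses use `postS = 4` (the suppression window).
#' @param csUsIntervalS CS-to-US onset interval (locates the expected
#'   reward time on omission trials).
#' @param eventTimes required for `locomotion_init`: initiation times, s.
#' @return a [TrialTensor-class].
#' @export
extractTrials <- function(dff, tl, eventKind, preS = 2, postS = 2,
                          csUsIntervalS = 3, eventTimes = NULL) {
  stopifnot(is(dff, "DffMatrix"))
  eventKind <- match.arg(eventKind, EVENT_KINDS)
  fs <- dff@fsHz
  if (eventKind == "locomotion_init") {
    if (is.null(eventTimes)) stop("locomotion_init requires eventTimes")
    an <- list(idx = seq_along(eventTimes), t0 = as.numeric(eventTimes),
               anchor = as.numeric(eventTimes))
    trialIds <- seq_along(eventTimes)
  } else {
    an <- eventAnchors(tl, eventKind, csUsIntervalS)
    trialIds <- tl$trial_id[an$idx]
  }
  if (!length(an$idx)) stop("no events of kind ", eventKind)
  preN <- as.integer(round(preS * fs)); postN <- as.integer(round(postS * fs))
  nFrames <- ncol(dff@values); nAxon <- nrow(dff@values)
  i0 <- floor(an$t0 * fs + 1e-9)          # 0-based frame of the onset
  c0 <- floor(an$anchor * fs + 1e-9)
  ok <- (i0 - preN) >= 0 & (i0 + postN) <= nFrames &
    (c0 - preN) >= 0 & c0 <= nFrames
  nDropped <- sum(!ok)
  if (!any(ok)) stop("no usable trials for ", eventKind,
                     " (all at recording edges)")
  i0 <- i0[ok]; c0 <- c0[ok]; trialIds <- trialIds[ok]
  nTr <- length(i0)
  vals <- array(NA_real_, c(nAxon, nTr, preN + postN))
  ctrl <- array(NA_real_, c(nAxon, nTr, preN))
  for (j in seq_len(nTr)) {
    vals[, j, ] <- dff@values[, (i0[j] - preN + 1L):(i0[j] + postN),
                              drop = FALSE]
    ctrl[, j, ] <- dff@values[, (c0[j] - preN + 1L):c0[j], drop = FALSE]
  }
  new("TrialTensor", values = vals,
      relTime = ((-preN):(postN - 1L)) / fs,
      control = ctrl, controlRelTime = ((-preN):(-1L)) / fs,
      eventKind = eventKind, trialIds = as.integer(trialIds),
      axonIds = dff@roiIds, fsHz = fs,
      alignment = list(t0 = "event onset",
                       control_anchor = if (eventKind %in%
                         c("us_reward", "us_aversive", "reward_omission"))
                         "cs onset (if conditioned)" else "event onset",
                       pre_s = preS, post_s = postS,
                       n_dropped_edge = nDropped))
}

#' Per-trial and summary response amplitudes
#'
#' The per-trial amplitude is the mean dF/F over the signal window minus
#' the mean over the control window; the summary amplitude per axon is
#' the mean of per-trial amplitudes. The operator is linear in the trace
#' and a constant offset cancels exactly.
#'
#' @param tensor a [TrialTensor-class] from [extractTrials()].
#' @return data.frame with one row per axon: `axon_id`, `event_kind`,
#'   `amplitude`, `n_trials`, and list-columns `signal_means`,
#'   `control_means`, `per_trial` (per-trial vectors).
#' @export
responseAmplitude <- function(tensor) {
  stopifnot(is(tensor, "TrialTensor"), dim(tensor@values)[2] >= 1)
  sigIdx <- which(tensor@relTime >= 0)
  sig <- apply(tensor@values[, , sigIdx, drop = FALSE], c(1, 2), mean)
  ctl <- apply(tensor@control, c(1, 2), mean)
  amp <- sig - ctl
  data.frame(axon_id = tensor@axonIds, event_kind = tensor@eventKind,
             amplitude = rowMeans(amp),
             n_trials = dim(tensor@values)[2],
             signal_means = I(asplit(sig, 1)),
             control_means = I(asplit(ctl, 1)),
             per_trial = I(asplit(amp, 1)),
             trial_ids = I(rep(list(tensor@trialIds), nrow(sig))),
             stringsAsFactors = FALSE)
}

#' Paired signed-rank significance of a response
#'
#' One-sided Wilcoxon signed-rank test of the per-trial signal-window
#' means against the paired control-window means ("statistically larger
#' than baseline"). At least 6 paired trials are required, the smallest
#' n at which one-sided p < 0.05 is attainable; below that the outcome
#' is undetermined (`p = NA`, `significant = NA`). All-zero differences
#' give `p = 1`.
#'
#' @param controlMeans,signalMeans paired per-trial window means.
#' @param alpha significance level (default 0.05).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return list with elements `p` and `significant`.
#' @export
responseSignificance <- function(controlMeans, signalMeans, alpha = 0.05,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(controlMeans) == length(signalMeans))
  n <- length(controlMeans)
  if (n < 6) return(list(p = NA_real_, significant = NA))
  d <- signalMeans - controlMeans
  if (all(d == 0)) return(list(p = 1, significant = FALSE))
  p <- suppressWarnings(
    wilcox.test(signalMeans, controlMeans, paired = TRUE,
                alternative = alternative)$p.value)
  list(p = p, significant = p < alpha)
}

#' Build a per-axon response table over event kinds
#'
#' Runs [extractTrials()], [responseAmplitude()] and
#' [responseSignificance()] for each requested event kind and binds the
#' rows. No correction across axons is applied by default, matching the
#' per-axon p < 0.05 rule; `adjust = "BH"` applies Benjamini-Hochberg
#' within each event kind.
#'
#' @param dff a [DffMatrix-class] of axon representatives.
#' @param tl timeline data.frame.
#' @param kinds event kinds to quantify.
#' @param preS,postS,csUsIntervalS window parameters, see
#'   [extractTrials()]; reward-omission rows use `omissionPostS`.
#' @param omissionPostS signal-window length for omission trials (4 s).
#' @param alpha,alternative significance parameters.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a response table data.frame with columns `axon_id`,
#'   `event_kind`, `amplitude`, `n_trials`, `p`, `significant` plus
#'   per-trial list-columns.
#' @export
responseTable <- function(dff, tl,
                          kinds = c("us_reward", "us_aversive",
                                    "cs_reward", "cs_aversive"),
                          preS = 2, postS = 2, csUsIntervalS = 3,
                          omissionPostS = 4, alpha = 0.05,
                          alternative = "greater", adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- lapply(kinds, function(kind) {
    post <- if (kind == "reward_omission") omissionPostS else postS
    tens <- extractTrials(dff, tl, kind, preS, post, csUsIntervalS)
    tab <- responseAmplitude(tens)
    sig <- lapply(seq_len(nrow(tab)), function(i)
      responseSignificance(tab$control_means[[i]], tab$signal_means[[i]],
                           alpha, alternative))
    tab$p <- vapply(sig, `[[`, numeric(1), "p")
    tab$significant <- vapply(sig, function(s)
      if (is.na(s$p)) NA else s$significant, logical(1))
    if (adjust == "BH") {
      tab$p <- stats::p.adjust(tab$p, method = "BH")
      tab$significant <- ifelse(is.na(tab$p), NA, tab$p < alpha)
    }
    tab
  })
  do.call(rbind, rows)
}

#' Overall per-axon significance across event kinds
#'
#' An axon is significantly responsive if either of the listed activities
#' (reward or aversive by default) is significant; only these axons enter
#' preference clustering.
#'
#' @param table a response table from [responseTable()].
#' @param kinds event kinds combined by logical OR.
#' @return data.frame `axon_id`, `significant`.
#' @export
axonSignificance <- function(table, kinds = c("us_reward", "us_aversive")) {
  sub <- table[table$event_kind %in% kinds, ]
  axons <- unique(sub$axon_id)
  flag <- vapply(axons, function(a) {
    s <- sub$significant[sub$axon_id == a]
    if (any(s %in% TRUE)) TRUE
    else if (anyNA(s)) NA
    else FALSE
  }, logical(1))
  data.frame(axon_id = axons, significant = unname(flag),
             stringsAsFactors = FALSE)
}

#' Calcium response at spontaneous locomotion initiation
#'
#' Applies the amplitude/significance machinery to locomotion-bout
#' initiations that are not explained by stimuli: initiations within
#' `exclusionS` seconds of any US onset are excluded before testing.
#'
#' @param dff a [DffMatrix-class].
#' @param tl timeline data.frame (supplies US onsets for the exclusion).
#' @param initiations locomotion initiation times, seconds (from
#'   [detectRunningBouts()]).
#' @param exclusionS half-width of the US exclusion window (default 2 s).
#' @param preS,postS,alpha,alternative see [responseTable()].
#' @return a response table for `locomotion_init`, or a zero-row table
#'   with attribute `undetermined = TRUE` when fewer than 6 spontaneous
#'   initiations qualify.
#' @export
locomotionResponse <- function(dff, tl, initiations, exclusionS = 2,
                               preS = 2, postS = 2, alpha = 0.05,
                               alternative = "greater") {
  us <- tl$us_onset_s[!is.na(tl$us_onset_s)]
  spont <- initiations[vapply(initiations, function(t0)
    !length(us) || min(abs(us - t0)) > exclusionS, logical(1))]
  if (length(spont) < 6) {
    out <- data.frame(axon_id = character(0), event_kind = character(0),
                      amplitude = numeric(0), n_trials = integer(0),
                      p = numeric(0), significant = logical(0))
    attr(out, "undetermined") <- TRUE
    attr(out, "n_spontaneous") <- length(spont)
    return(out)
  }
  tens <- extractTrials(dff, tl, "locomotion_init", preS, postS,
                        eventTimes = spont)
  tab <- responseAmplitude(tens)
  sig <- lapply(seq_len(nrow(tab)), function(i)
    responseSignificance(tab$control_means[[i]], tab$signal_means[[i]],
                         alpha, alternative))
  tab$p <- vapply(sig, `[[`, numeric(1), "p")
  tab$significant <- vapply(sig, function(s)
    if (is.na(s$p)) NA else s$significant, logical(1))
  attr(tab, "n_spontaneous") <- length(spont)
  tab
}
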