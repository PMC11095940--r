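#' @import methods
#' @importFrom stats median sd cor quantile wilcox.test kmeans rnorm runif
#'   rbinom rpois aggregate setNames var
#' @importFrom utils head tail
#' @importFrom graphics abline arrows axis lines plot.default
#' @importFrom grDevices pdf dev.off
#' @useDynLib AxonValence, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

TIMELINE_CONDITIONS <- c("reward", "aversive", "control", "reward_omission")
TIMELINE_COLUMNS <- c("trial_id", "condition", "cs_onset_s", "cs_freq_hz",
                      "us_onset_s", "day_index")

#' Validate an event timeline data frame
#'
#' A timeline is an ordinary `data.frame` with one row per trial and columns
#' `trial_id` (integer), `condition` (one of `"reward"`, `"aversive"`,
#' `"control"`, `"reward_omission"`), `cs_onset_s`, `cs_freq_hz`,
#' `us_onset_s` (seconds on the session clock, `NA` where absent) and
#' `day_index` (integer >= 1). Trial times must be strictly increasing and,
#' for conditioned trials carrying both onsets, the CS-to-US interval must
#' equal `csUsIntervalS` (2 s tone plus 1 s trace delay by default).
#' Reward-omission trials carry a CS onset but no US onset.
#'
#' @param timeline a data.frame as described above.
#' @param csUsIntervalS expected CS-to-US onset interval in seconds.
#' @return invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validateTimeline <- function(timeline, csUsIntervalS = 3) {
  if (!is.data.frame(timeline))
    stop("timeline must be a data.frame")
  missing <- setdiff(TIMELINE_COLUMNS, names(timeline))
  if (length(missing))
    stop("timeline lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(timeline) == 0L) return(invisible(TRUE))
  bad <- setdiff(unique(timeline$condition), TIMELINE_CONDITIONS)
  if (length(bad))
    stop("unknown trial condition(s): ", paste(bad, collapse = ", "))
  tt <- ifelse(is.na(timeline$cs_onset_s), timeline$us_onset_s,
               timeline$cs_onset_s)
  if (anyNA(tt))
    stop("trials must carry a CS onset, a US onset, or both")
  byday <- split(tt, timeline$day_index)
  for (v in byday)
    if (length(v) > 1L && any(diff(v) <= 0))
      stop("trial times must be strictly increasing within a day")
  both <- !is.na(timeline$cs_onset_s) & !is.na(timeline$us_onset_s)
  if (any(both)) {
    gap <- timeline$us_onset_s[both] - timeline$cs_onset_s[both]
    if (any(abs(gap - csUsIntervalS) > 1e-9))
      stop("conditioned trials must have us_onset_s - cs_onset_s = ",
           csUsIntervalS, " s")
  }
  om <- timeline$condition == "reward_omission"
  if (any(om & (is.na(timeline$cs_onset_s) | !is.na(timeline$us_onset_s))))
    stop("reward_omission trials must have a CS onset and no US onset")
  invisible(TRUE)
}

#' FluorescenceMatrix: raw ROI x frame fluorescence
#'
#' Container for raw (pre-normalisation) fluorescence traces, one row per
#' segmented ROI, at a fixed imaging rate.
#'
#' @slot values numeric matrix, ROI x frame, non-negative, no NA/NaN.
#' @slot fsHz imaging sampling rate (frames per second), > 0.
#' @slot roiIds character vector of ROI identifiers (rownames of `values`).
#' @export
setClass("FluorescenceMatrix",
  representation(values = "matrix", fsHz = "numeric", roiIds = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (anyNA(v) || any(!is.finite(v))) return("values must be finite, no NA")
    if (any(v < 0)) return("raw fluorescence must be >= 0")
    if (length(object@fsHz) != 1L || !is.finite(object@fsHz) ||
        object@fsHz <= 0) return("fsHz must be a single positive number")
    if (length(object@roiIds) != nrow(v))
      return("roiIds length must match the number of ROI rows")
    if (anyDuplicated(object@roiIds)) return("roiIds must be unique")
    TRUE
  })

#' Construct a FluorescenceMatrix
#'
#' @param values ROI x frame numeric matrix of raw fluorescence.
#' @param fsHz imaging sampling rate in Hz.
#' @param roiIds optional ROI identifiers; defaults to rownames or `roi_i`.
#' @return a validated [FluorescenceMatrix-class] object.
#' @export
fluorescenceMatrix <- function(values, fsHz, roiIds = NULL) {
  values <- as.matrix(values)
  if (is.null(roiIds))
    roiIds <- if (!is.null(rownames(values))) rownames(values) else
      sprintf("roi_%03d", seq_len(nrow(values)))
  rownames(values) <- roiIds
  new("FluorescenceMatrix", values = values, fsHz = as.numeric(fsHz),
      roiIds = as.character(roiIds))
}

#' DffMatrix: normalised dF/F traces with their baseline
#'
#' Result of [computeDff()]: dimensionless dF/F per ROI and frame, together
#' with the sliding-percentile baseline F0 actually used.
#'
#' @slot values ROI x frame dF/F matrix (finite).
#' @slot fsHz sampling rate in Hz.
#' @slot roiIds ROI identifiers.
#' @slot f0 ROI x frame baseline matrix, strictly positive.
#' @export
setClass("DffMatrix",
  representation(values = "matrix", fsHz = "numeric", roiIds = "character",
                 f0 = "matrix"),
  validity = function(object) {
    if (anyNA(object@values) || any(!is.finite(object@values)))
      return("dF/F values must be finite")
    if (any(object@f0 <= 0)) return("F0 must be strictly positive")
    if (!identical(dim(object@values), dim(object@f0)))
      return("values and f0 must have identical dimensions")
    if (length(object@roiIds) != nrow(object@values))
      return("roiIds length must match the number of ROI rows")
    if (object@fsHz <= 0) return("fsHz must be positive")
    TRUE
  })

#' BehaviorTraces: session-aligned behavioral time series
#'
#' Tongue-position (camera keypoint) and treadmill-speed traces at their
#' native rates, plus an optional trial x frame x feature array of
#' precomputed facial-expression embeddings.
#'
#' @slot tongue numeric per-frame tongue position (camera units).
#' @slot tongueFsHz camera rate, Hz.
#' @slot speed numeric per-sample treadmill speed (arbitrary units).
#' @slot speedFsHz speed sampling rate, Hz.
#' @slot facial `NULL` or a 3-d array trial x frame x feature.
#' @slot facialTimesS numeric, times of facial frames relative to CS onset.
#' @export
setClass("BehaviorTraces",
  representation(tongue = "numeric", tongueFsHz = "numeric",
                 speed = "numeric", speedFsHz = "numeric",
                 facial = "ANY", facialTimesS = "numeric"),
  validity = function(object) {
    if (object@tongueFsHz <= 0 || object@speedFsHz <= 0)
      return("behavior sampling rates must be positive")
    if (anyNA(object@tongue) || anyNA(object@speed))
      return("behavior traces must not contain NA")
    if (!is.null(object@facial)) {
      if (!(is.array(object@facial) && length(dim(object@facial)) == 3L))
        return("facial must be a trial x frame x feature array")
      if (length(object@facialTimesS) != dim(object@facial)[2L])
        return("facialTimesS must match the facial frame dimension")
    }
    TRUE
  })

#' Construct BehaviorTraces
#'
#' @param tongue,tongueFsHz tongue-position trace and its rate (Hz).
#' @param speed,speedFsHz treadmill-speed trace and its rate (Hz).
#' @param facial optional trial x frame x feature array of facial features.
#' @param facialTimesS frame times (s, relative to CS onset) for `facial`.
#' @return a validated [BehaviorTraces-class] object.
#' @export
behaviorTraces <- function(tongue, tongueFsHz, speed, speedFsHz,
                           facial = NULL, facialTimesS = numeric(0)) {
  new("BehaviorTraces", tongue = as.numeric(tongue),
      tongueFsHz = as.numeric(tongueFsHz), speed = as.numeric(speed),
      speedFsHz = as.numeric(speedFsHz), facial = facial,
      facialTimesS = as.numeric(facialTimesS))
}

#' SessionBundle: one imaging session, fully aligned
#'
#' The unit of I/O for the pipeline: the trial timeline, raw fluorescence,
#' frame-registration shifts, behavior traces and metadata, all sharing
#' t = 0 at session start. All downstream modules consume SessionBundles.
#'
#' @slot timeline data.frame, see [validateTimeline()].
#' @slot fluor a [FluorescenceMatrix-class].
#' @slot shifts frame x 2 matrix of (x, y) registration shifts, pixels.
#' @slot pixelSizeUm microns per pixel, > 0.
#' @slot behavior a [BehaviorTraces-class].
#' @slot meta list; must include `animal`, `day`; `cs_us_interval_s`
#'   (defaults to 3) governs the timeline consistency check.
#' @export
setClass("SessionBundle",
  representation(timeline = "data.frame", fluor = "FluorescenceMatrix",
                 shifts = "matrix", pixelSizeUm = "numeric",
                 behavior = "BehaviorTraces", meta = "list"),
  validity = function(object) {
    iv <- try(validateTimeline(object@timeline,
                csUsIntervalS = metaCsUsInterval(object@meta)), silent = TRUE)
    if (inherits(iv, "try-error"))
      return(conditionMessage(attr(iv, "condition")))
    if (nrow(object@shifts) != ncol(object@fluor@values))
      return("shifts must have one row per imaging frame")
    if (ncol(object@shifts) != 2L) return("shifts must have 2 columns (x, y)")
    if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
    span <- sessionSpan(object@timeline)
    if (nrow(object@timeline) > 0) {
      if (ncol(object@fluor@values) / object@fluor@fsHz < span)
        return("fluorescence does not cover the timeline span")
      if (length(object@behavior@tongue) / object@behavior@tongueFsHz < span)
        return("tongue trace does not cover the timeline span")
      if (length(object@behavior@speed) / object@behavior@speedFsHz < span)
        return("speed trace does not cover the timeline span")
    }
    TRUE
  })

metaCsUsInterval <- function(meta) {
  if (!is.null(meta$cs_us_interval_s)) meta$cs_us_interval_s else 3
}

sessionSpan <- function(timeline) {
  if (nrow(timeline) == 0L) return(0)
  max(c(timeline$cs_onset_s, timeline$us_onset_s), na.rm = TRUE)
}

#' Construct a SessionBundle
#'
#' @param timeline trial timeline data.frame ([validateTimeline()]).
#' @param fluor a [FluorescenceMatrix-class].
#' @param shifts frame x 2 matrix of registration shifts in pixels.
#' @param pixelSizeUm microns per pixel.
#' @param behavior a [BehaviorTraces-class].
#' @param meta metadata list (`animal`, `day`, optional
#'   `cs_us_interval_s`).
#' @return a validated [SessionBundle-class] object.
#' @export
sessionBundle <- function(timeline, fluor, shifts, pixelSizeUm, behavior,
                          meta = list(animal = "sim", day = 1L)) {
  new("SessionBundle", timeline = as.data.frame(timeline), fluor = fluor,
      shifts = as.matrix(shifts), pixelSizeUm = as.numeric(pixelSizeUm),
      behavior = behavior, meta = meta)
}

#' AxonSet: deduplicated ROI -> axon assignment
#'
#' Result of [deduplicateAxons()]: the representative ROI retained for each
#' putative axon and the full membership map.
#'
#' @slot representatives character, representative ROI ids (subset of input).
#' @slot membership named character: every input ROI id -> its
#'   representative's id.
#' @slot threshold the correlation threshold used.
#' @slot dropped character, zero-variance ROIs excluded from the analysis.
#' @export
setClass("AxonSet",
  representation(representatives = "character", membership = "character",
                 threshold = "numeric", dropped = "character"),
  validity = function(object) {
    if (!all(object@representatives %in% object@membership))
      return("representatives must appear in the membership map")
    if (!all(object@membership %in% object@representatives))
      return("every ROI must map to a representative")
    TRUE
  })

#' MotionReport: brain-movement summary
#'
#' @slot rmsUm root-mean-square frame-to-frame displacement, microns.
#' @slot eventTimesS onsets (s) of filtered displacement excursions above
#'   the event threshold.
#' @slot nEvents number of such events.
#' @slot filteredTrace per-frame low-pass-filtered combined shift, microns.
#' @slot combinedTrace per-frame unfiltered combined shift, microns.
#' @export
setClass("MotionReport",
  representation(rmsUm = "numeric", eventTimesS = "numeric",
                 nEvents = "integer", filteredTrace = "numeric",
                 combinedTrace = "numeric"))

#' TrialTensor: event-aligned dF/F slices
#'
#' Axon x trial x relative-time array aligned to an event onset, with the
#' matching control-window slices (anchored per the conditioning design:
#' for conditioned trials the control window precedes the CS onset).
#'
#' @slot values axon x trial x time dF/F array aligned to the event onset.
#' @slot relTime time axis in seconds, event at 0, half-open frames.
#' @slot control axon x trial x time array over the control window.
#' @slot controlRelTime control time axis relative to its anchor.
#' @slot eventKind one of `us_reward`, `us_aversive`, `cs_reward`,
#'   `cs_aversive`, `locomotion_init`, `reward_omission`.
#' @slot trialIds integer trial ids included.
#' @slot axonIds character axon (ROI representative) ids.
#' @slot fsHz sampling rate.
#' @slot alignment list describing which onset anchors t = 0 and which
#'   anchors the control window, plus number of edge-dropped trials.
#' @export
setClass("TrialTensor",
  representation(values = "array", relTime = "numeric", control = "array",
                 controlRelTime = "numeric", eventKind = "character",
                 trialIds = "integer", axonIds = "character",
                 fsHz = "numeric", alignment = "list"))

#' BalancedEnsemble: undersampling ensemble of tree classifiers
#'
#' Each member is a random forest trained on all minority-class trials plus
#' an equal-sized random subsample of majority-class trials; prediction is
#' a majority vote over members.
#'
#' @slot members list of fitted `randomForest` members.
#' @slot classes the two class labels (minority first).
#' @slot seed integer seed the member subsamples were drawn from.
#' @export
setClass("BalancedEnsemble",
  representation(members = "list", classes = "character", seed = "integer"))

#' DiscriminationResult: cross-validated decoding summary
#'
#' @slot predictions data.frame: `trial`, `label`, `predicted`, `fold` for
#'   every held-out trial (each trial predicted exactly once).
#' @slot foldAccuracy per-fold balanced accuracy, percent.
#' @slot balancedAccuracy pooled balanced accuracy over held-out trials,
#'   percent.
#' @slot selectedFeatures list of integer vectors, features chosen within
#'   each training fold.
#' @slot seed integer seed.
#' @slot nMembers ensemble size used.
#' @export
setClass("DiscriminationResult",
  representation(predictions = "data.frame", foldAccuracy = "numeric",
                 balancedAccuracy = "numeric", selectedFeatures = "list",
                 seed = "integer", nMembers = "integer"),
  validity = function(object) {
    if (object@balancedAccuracy < 0 || object@balancedAccuracy > 100)
      return("balanced accuracy must be within [0, 100]")
    if (anyDuplicated(object@predictions$trial))
      return("each trial must be predicted exactly once")
    TRUE
  })
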