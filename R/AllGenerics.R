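#' @name accessors
#' @title Accessors for AxonValence classes
#' @description Accessor generics: `traceValues()` returns the numeric
#'   matrix of a fluorescence or dF/F container, `fsHz()` its sampling
#'   rate, `roiIds()` its ROI identifiers; `timeline()` and `behavior()`
#'   extract the corresponding parts of a [SessionBundle-class];
#'   `representatives()` and `membership()` read an [AxonSet-class].
#' @param x an AxonValence object.
#' @return the slot content described above.
NULL

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("fsHz", function(x) standardGeneric("fsHz"))
#' @rdname accessors
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))
#' @rdname accessors
#' @export
setGeneric("timeline", function(x) standardGeneric("timeline"))
#' @rdname accessors
#' @export
setGeneric("behavior", function(x) standardGeneric("behavior"))
#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname accessors
setMethod("traceValues", "FluorescenceMatrix", function(x) x@values)
#' @rdname accessors
setMethod("traceValues", "DffMatrix", function(x) x@values)
#' @rdname accessors
setMethod("fsHz", "FluorescenceMatrix", function(x) x@fsHz)
#' @rdname accessors
setMethod("fsHz", "DffMatrix", function(x) x@fsHz)
#' @rdname accessors
setMethod("roiIds", "FluorescenceMatrix", function(x) x@roiIds)
#' @rdname accessors
setMethod("roiIds", "DffMatrix", function(x) x@roiIds)
#' @rdname accessors
setMethod("timeline", "SessionBundle", function(x) x@timeline)
#' @rdname accessors
setMethod("behavior", "SessionBundle", function(x) x@behavior)
#' @rdname accessors
setMethod("representatives", "AxonSet", function(x) x@representatives)
#' @rdname accessors
setMethod("membership", "AxonSet", function(x) x@membership)

setMethod("show", "FluorescenceMatrix", function(object) {
  cat(sprintf("FluorescenceMatrix: %d ROI x %d frames at %.3g Hz (%.1f s)\n",
              nrow(object@values), ncol(object@values), object@fsHz,
              ncol(object@values) / object@fsHz))
})

setMethod("show", "DffMatrix", function(object) {
  cat(sprintf("DffMatrix: %d ROI x %d frames at %.3g Hz; dF/F range [%.3g, %.3g]\n",
              nrow(object@values), ncol(object@values), object@fsHz,
              min(object@values), max(object@values)))
})

setMethod("show", "SessionBundle", function(object) {
  tl <- object@timeline
  cat(sprintf("SessionBundle: animal %s, day %s\n",
              as.character(object@meta$animal %||% "?"),
              as.character(object@meta$day %||% "?")))
  cat(sprintf("  %d trials (%s)\n", nrow(tl),
              paste(sprintf("%s:%d", names(table(tl$condition)),
                            as.integer(table(tl$condition))), collapse = ", ")))
  cat("  fluor: "); show(object@fluor)
  cat(sprintf("  behavior: tongue %.3g Hz, speed %.3g Hz, facial %s\n",
              object@behavior@tongueFsHz, object@behavior@speedFsHz,
              if (is.null(object@behavior@facial)) "absent" else
                paste(dim(object@behavior@facial), collapse = " x ")))
})

setMethod("show", "AxonSet", function(object) {
  cat(sprintf("AxonSet: %d ROIs -> %d axons (threshold r > %.2f, %d dropped)\n",
              length(object@membership), length(object@representatives),
              object@threshold, length(object@dropped)))
})

setMethod("show", "MotionReport", function(object) {
  cat(sprintf("MotionReport: rms %.3g um, %d movement events\n",
              object@rmsUm, object@nEvents))
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("TrialTensor[%s]: %d axons x %d trials x %d frames (%.3g Hz)\n",
              object@eventKind, d[1], d[2], d[3], object@fsHz))
})

setMethod("show", "DiscriminationResult", function(object) {
  cat(sprintf("DiscriminationResult: %d trials, balanced accuracy %.1f%% (folds: %s)\n",
              nrow(object@predictions), object@balancedAccuracy,
              paste(sprintf("%.1f", object@foldAccuracy), collapse = ", ")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
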