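# dF/F computation, same-axon ROI deduplication, brain-movement metrics.

#' Compute dF/F with a sliding-percentile baseline
#'
#' The baseline `F0[t]` is the given percentile (default: the 50th, i.e.
#' the running median) of the raw trace over a window of `windowS` seconds
#' centered on frame `t` and truncated at the session edges; this removes
#' slow drifts while leaving brief transients intact. Then
#' `dF/F = (F - F0) / F0`. Percentiles follow the type-7 quantile
#' definition. If a frame's F0 is nonpositive it is floored at the ROI's
#' 1st percentile of raw fluorescence; an error names the ROI if the
#' floor itself is nonpositive.
#'
#' @param fluor a [FluorescenceMatrix-class].
#' @param windowS sliding-window length in seconds (default 30).
#' @param percentile baseline percentile in (0, 100), default 50.
#' @return a [DffMatrix-class].
#' @export
computeDff <- function(fluor, windowS = 30, percentile = 50) {
  stopifnot(is(fluor, "FluorescenceMatrix"))
  fs <- fluor@fsHz
  width <- as.integer(round(windowS * fs))
  if (width < 2) stop("window must span at least 2 frames")
  x <- fluor@values
  f0 <- .slidingPercentile(x, width, percentile / 100)
  bad <- f0 <= 0
  if (any(bad)) {
    floors <- apply(x, 1, quantile, probs = 0.01, type = 7)
    for (i in which(rowSums(bad) > 0)) {
      if (floors[i] <= 0)
        stop("nonpositive baseline for ROI ", fluor@roiIds[i],
             "; trace cannot be normalised")
      f0[i, bad[i, ]] <- floors[i]
    }
  }
  vals <- (x - f0) / f0
  dimnames(vals) <- dimnames(x)
  new("DffMatrix", values = vals, fsHz = fs, roiIds = fluor@roiIds, f0 = f0)
}

# Connected components of an undirected adjacency matrix (logical).
connectedComponents <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Collapse duplicated ROIs onto putative axons
#'
#' Segmented ROI fragments belonging to one axon produce near-identical
#' dF/F traces. Pairs with full-session Pearson correlation above
#' `threshold` are linked, linked ROIs are grouped into connected
#' components, and each component keeps the ROI with the strongest signal
#' (largest temporal SD of dF/F; ties broken by a seeded draw). The
#' procedure is iterated on the survivors until every remaining pair is
#' at or below the threshold. Zero-variance traces are excluded with a
#' warning (their correlation is undefined).
#'
#' @param dff a [DffMatrix-class].
#' @param threshold correlation threshold (default 0.65).
#' @param seed seed for the representative tie-break.
#' @return an [AxonSet-class].
#' @export
deduplicateAxons <- function(dff, threshold = 0.65, seed = 1L) {
  stopifnot(is(dff, "DffMatrix"), nrow(dff@values) >= 1)
  x <- dff@values
  ids <- dff@roiIds
  sds <- apply(x, 1, sd)
  dropped <- ids[sds == 0]
  if (length(dropped)) {
    warning("excluding zero-variance ROI(s): ",
            paste(dropped, collapse = ", "))
    keep <- sds > 0
    x <- x[keep, , drop = FALSE]; ids <- ids[keep]; sds <- sds[keep]
  }
  if (!length(ids))
    return(new("AxonSet", representatives = character(0),
               membership = setNames(character(0), character(0)),
               threshold = threshold, dropped = dropped))
  membership <- setNames(ids, ids)
  alive <- ids
  jitter <- withSeed(seed, runif(length(ids), 0, 1e-9))
  names(jitter) <- ids
  repeat {
    if (length(alive) < 2L) break
    xm <- x[match(alive, ids), , drop = FALSE]
    cm <- cor(t(xm))
    adj <- cm > threshold
    diag(adj) <- FALSE
    if (!any(adj)) break
    comp <- connectedComponents(adj)
    reps <- character(0)
    for (k in unique(comp)) {
      members <- alive[comp == k]
      score <- sds[match(members, ids)] + jitter[members]
      rep <- members[which.max(score)]
      reps <- c(reps, rep)
      membership[membership %in% members] <- rep
    }
    alive <- reps
  }
  new("AxonSet", representatives = sort(alive), membership = membership,
      threshold = threshold, dropped = dropped)
}

#' Subset a dF/F matrix to axon representatives
#'
#' @param dff a [DffMatrix-class].
#' @param axonSet an [AxonSet-class] from [deduplicateAxons()].
#' @return a [DffMatrix-class] with one row per axon.
#' @export
axonTraces <- function(dff, axonSet) {
  keep <- match(representatives(axonSet), dff@roiIds)
  new("DffMatrix", values = dff@values[keep, , drop = FALSE],
      fsHz = dff@fsHz, roiIds = representatives(axonSet),
      f0 = dff@f0[keep, , drop = FALSE])
}

#' Deduplication threshold sensitivity sweep
#'
#' Re-runs [deduplicateAxons()] over a grid of correlation thresholds and
#' reports the representative count at each — a quick check that
#' conclusions do not hinge on the 0.65 default.
#'
#' @param dff a [DffMatrix-class].
#' @param thresholds correlation thresholds to evaluate.
#' @param seed tie-break seed passed through.
#' @return data.frame `threshold`, `n_axons`.
#' @export
dedupThresholdSweep <- function(dff, thresholds = seq(0.5, 0.8, by = 0.05),
                                seed = 1L) {
  data.frame(threshold = thresholds,
             n_axons = vapply(thresholds, function(th)
               length(representatives(deduplicateAxons(dff, th, seed))),
               integer(1)))
}

#' Quantify residual brain movement from registration shifts
#'
#' Frame-to-frame (x, y) shift increments are combined trigonometrically
#' into a scalar displacement in microns. The report carries the
#' root-mean-square of that trace and the onsets of large transient
#' movements: upward crossings of `eventUm` by the low-pass-filtered
#' (2nd-order zero-phase Butterworth at `cutoffHz`) displacement trace,
#' debounced so that each onset is preceded by at least one sub-threshold
#' frame.
#'
#' @param shifts frame x 2 matrix of registration shifts in pixels.
#' @param pixelSizeUm microns per pixel.
#' @param fs frame rate, Hz.
#' @param cutoffHz Butterworth low-pass cutoff (default 1.5 Hz).
#' @param eventUm movement-event threshold in microns (default 5, i.e.
#'   16 pixels at 0.3125 um/px).
#' @return a [MotionReport-class].
#' @export
quantifyMotion <- function(shifts, pixelSizeUm, fs, cutoffHz = 1.5,
                           eventUm = 5) {
  shifts <- as.matrix(shifts)
  stopifnot(nrow(shifts) >= 2, pixelSizeUm > 0)
  if (fs <= 2 * cutoffHz)
    stop("sampling rate must exceed twice the filter cutoff")
  d <- diff(shifts) * pixelSizeUm
  combined <- c(0, sqrt(d[, 1]^2 + d[, 2]^2))
  rms <- sqrt(mean(combined^2))
  bf <- signal::butter(2, cutoffHz / (fs / 2), type = "low")
  filt <- as.numeric(signal::filtfilt(bf, combined))
  above <- filt > eventUm
  onsets <- which(above & !c(TRUE, head(above, -1)))
  new("MotionReport", rmsUm = rms,
      eventTimesS = (onsets - 1) / fs, nEvents = length(onsets),
      filteredTrace = filt, combinedTrace = combined)
}
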