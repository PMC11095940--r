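# Trial-by-trial cue discrimination: four-group trial classification,
# F-value feature selection, class-balanced undersampling ensemble,
# stratified within-day cross-validation, equal-weight balanced accuracy,
# sliding-window accuracy courses and correct-vs-incorrect contrasts.

TRIAL_GROUPS <- c("reward_correct", "reward_incorrect",
                  "aversive_correct", "aversive_incorrect")

#' Classify conditioned trials into four discrimination groups
#'
#' Based on anticipatory licking: licking after the reward cue is a
#' correct reward discrimination and its absence an incorrect one;
#' no licking after the aversive cue is correct and licking after it
#' incorrect. Control and reward-omission trials are excluded.
#'
#' @param tl conditioned timeline data.frame.
#' @param anticipatory per-trial flags, the `perTrial` data.frame of
#'   [anticipatoryResponse()] (columns `trial_id`, `anticipatory`).
#' @return data.frame `trial_id`, `condition`, `group`, with attribute
#'   `basis = "licking"`.
#' @export
classifyTrialsByLicking <- function(tl, anticipatory) {
  keep <- tl$condition %in% c("reward", "aversive") &
    !is.na(tl$cs_onset_s) & !is.na(tl$cs_freq_hz)
  sub <- tl[keep, c("trial_id", "condition")]
  lick <- anticipatory$anticipatory[match(sub$trial_id,
                                          anticipatory$trial_id)]
  if (anyNA(lick)) stop("anticipatory flags missing for some trials")
  sub$group <- ifelse(sub$condition == "reward",
                      ifelse(lick, "reward_correct", "reward_incorrect"),
                      ifelse(lick, "aversive_incorrect", "aversive_correct"))
  attr(sub, "basis") <- "licking"
  rownames(sub) <- NULL
  sub
}

#' Classify conditioned trials into four groups from decoder output
#'
#' Facial-expression analogue of [classifyTrialsByLicking()]: a trial is
#' correct when the (cross-validated) decoder prediction matches its
#' condition.
#'
#' @param tl conditioned timeline data.frame.
#' @param predictions data.frame with columns `trial_id` and `predicted`
#'   (`"reward"` / `"aversive"`), e.g. held-out predictions from
#'   [crossValidate()] joined back to trial ids.
#' @return data.frame `trial_id`, `condition`, `group`, with attribute
#'   `basis = "facial"`.
#' @export
classifyTrialsByDecoder <- function(tl, predictions) {
  keep <- tl$condition %in% c("reward", "aversive") &
    !is.na(tl$cs_onset_s) & !is.na(tl$cs_freq_hz)
  sub <- tl[keep, c("trial_id", "condition")]
  pred <- predictions$predicted[match(sub$trial_id, predictions$trial_id)]
  if (anyNA(pred)) stop("predictions missing for some trials")
  correct <- pred == sub$condition
  sub$group <- ifelse(sub$condition == "reward",
                      ifelse(correct, "reward_correct", "reward_incorrect"),
                      ifelse(correct, "aversive_correct",
                             "aversive_incorrect"))
  attr(sub, "basis") <- "facial"
  rownames(sub) <- NULL
  sub
}

#' Rank features by one-way ANOVA F-value and keep the top k
#'
#' Computes the between/within-class F statistic for every feature and
#' returns the indices of the `k` largest (all features when fewer than
#' `k` exist). Zero-variance features get F = 0.
#'
#' @param x trial x feature numeric matrix.
#' @param labels two-class factor/character vector, one per trial.
#' @param k number of features to keep (default 400).
#' @return integer vector of selected feature indices.
#' @export
selectFeatures <- function(x, labels, k = 400) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2, all(table(labels) >= 2))
  n <- nrow(x)
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums((x[g1, , drop = FALSE] -
                    matrix(m1, n1, ncol(x), byrow = TRUE))^2) +
    colSums((x[!g1, , drop = FALSE] -
               matrix(m2, n2, ncol(x), byrow = TRUE))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[!is.finite(f) | ssw == 0 & ssb == 0] <- 0
  f[ssw == 0 & ssb > 0] <- Inf
  head(order(f, decreasing = TRUE), min(k, ncol(x)))
}

#' Fit a class-balanced undersampling tree ensemble
#'
#' Handles the 7:1 reward/aversive trial imbalance: each of `nMembers`
#' ensemble members is a random forest trained on all minority-class
#' trials plus an equal-sized random subsample (without replacement) of
#' majority-class trials; the ensemble predicts by majority vote across
#' members. Member subsamples and forests are deterministic under the
#' seed.
#'
#' @param x trial x feature matrix.
#' @param labels two-class labels.
#' @param nMembers ensemble size (default 25, odd avoids vote ties).
#' @param memberTrees trees per member forest (default 50).
#' @param seed integer seed.
#' @return a [BalancedEnsemble-class].
#' @export
fitBalancedEnsemble <- function(x, labels, nMembers = 25, memberTrees = 50,
                                seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes are required")
  cnt <- table(labels)
  if (any(cnt < 2)) stop("each class needs at least 2 trials")
  minority <- names(cnt)[which.min(cnt)]
  majority <- setdiff(levels(labels), minority)
  iMin <- which(labels == minority); iMaj <- which(labels == majority)
  members <- withSeed(deriveSeed(seed, "ensemble"),
    lapply(seq_len(nMembers), function(m) {
      sub <- sample(iMaj, length(iMin))
      idx <- c(iMin, sub)
      randomForest::randomForest(x[idx, , drop = FALSE],
                                 droplevels(labels[idx]),
                                 ntree = memberTrees)
    }))
  new("BalancedEnsemble", members = members,
      classes = c(minority, majority), seed = as.integer(seed))
}

#' Predict with a balanced ensemble (majority vote)
#'
#' @param object a [BalancedEnsemble-class].
#' @param newdata trial x feature matrix.
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
setMethod("predict", "BalancedEnsemble", function(object, newdata, ...) {
  votes <- vapply(object@members, function(m)
    as.character(predict(m, newdata)), character(nrow(newdata)))
  if (nrow(newdata) == 1L) votes <- matrix(votes, nrow = 1L)
  pred <- apply(votes, 1, function(v) {
    tb <- table(factor(v, levels = object@classes))
    object@classes[which.max(tb)]
  })
  factor(pred, levels = object@classes)
})

#' Balanced (equal-class-weight) accuracy
#'
#' The discrimination accuracy is computed separately within each class
#' and averaged with equal weights, so that the frequent reward class
#' cannot dominate: uninformative predictions score 50 percent
#' regardless of imbalance.
#'
#' @param predictions predicted class labels.
#' @param labels true class labels (both classes present).
#' @return balanced accuracy in percent.
#' @export
balancedAccuracy <- function(predictions, labels) {
  labels <- factor(labels)
  stopifnot(nlevels(droplevels(labels)) == 2)
  acc <- vapply(levels(droplevels(labels)), function(cl)
    mean(as.character(predictions)[labels == cl] == cl), numeric(1))
  100 * mean(acc)
}

#' Stratified cross-validated discrimination
#'
#' Fivefold (default) stratified cross-validation within a day: feature
#' selection is re-fit inside each training fold (no test-set leakage),
#' a balanced ensemble is trained per fold, and held-out predictions are
#' pooled so that every trial is predicted exactly once. If a class has
#' fewer trials than folds the fold count is reduced with a warning.
#'
#' @param x trial x feature matrix.
#' @param labels two-class labels, one per trial.
#' @param nFolds folds (default 5).
#' @param k features kept per fold (default 400).
#' @param nMembers,memberTrees ensemble parameters.
#' @param seed integer seed.
#' @return a [DiscriminationResult-class].
#' @export
crossValidate <- function(x, labels, nFolds = 5, k = 400, nMembers = 25,
                          memberTrees = 50, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("cross-validation requires both classes on the day")
  labels <- droplevels(labels)
  minCount <- min(table(labels))
  if (minCount < 2) stop("each class needs at least 2 trials")
  if (minCount < nFolds) {
    warning("reducing folds to the minority class count (", minCount, ")")
    nFolds <- minCount
  }
  folds <- withSeed(deriveSeed(seed, "folds"), {
    f <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    f
  })
  preds <- factor(rep(NA_character_, length(labels)),
                  levels = levels(labels))
  foldAcc <- numeric(nFolds); selected <- vector("list", nFolds)
  for (fd in seq_len(nFolds)) {
    tr <- which(folds != fd); te <- which(folds == fd)
    if (length(intersect(tr, te)))
      stop("integrity check failed: train/test folds overlap")
    sel <- selectFeatures(x[tr, , drop = FALSE], labels[tr], k)
    ens <- fitBalancedEnsemble(x[tr, sel, drop = FALSE], labels[tr],
                               nMembers, memberTrees,
                               seed = deriveSeed(seed, paste0("fold", fd)))
    p <- predict(ens, x[te, sel, drop = FALSE])
    preds[te] <- as.character(p)
    foldAcc[fd] <- if (nlevels(droplevels(labels[te])) == 2)
      balancedAccuracy(p, labels[te]) else NA_real_
    selected[[fd]] <- sel
  }
  new("DiscriminationResult",
      predictions = data.frame(trial = seq_along(labels),
                               label = as.character(labels),
                               predicted = as.character(preds),
                               fold = folds, stringsAsFactors = FALSE),
      foldAccuracy = foldAcc,
      balancedAccuracy = balancedAccuracy(preds, labels),
      selectedFeatures = selected, seed = as.integer(seed),
      nMembers = as.integer(nMembers))
}

#' Sliding-window discrimination accuracy
#'
#' Runs the full cross-validated pipeline on within-window feature means:
#' windows of `winS` seconds shifted by `stepS` across the frame span
#' (e.g. a 2 s cue with 0.5 s windows stepped by 0.16 s gives starts
#' 0, 0.16, ..., 1.44). Windows extending past the available frames are
#' skipped with a warning.
#'
#' @param features trial x frame x feature array.
#' @param frameTimes frame times in seconds relative to CS onset.
#' @param labels two-class labels per trial.
#' @param winS window length (default 0.5 s).
#' @param stepS window step (default 0.16 s).
#' @param ... passed to [crossValidate()].
#' @return data.frame `start_s`, `center_s`, `balanced_accuracy`.
#' @export
slidingWindowAccuracy <- function(features, frameTimes, labels,
                                  winS = 0.5, stepS = 0.16, ...) {
  stopifnot(length(dim(features)) == 3,
            dim(features)[2] == length(frameTimes))
  dt <- 1 / median(diff(frameTimes))
  spanEnd <- max(frameTimes) + 1 / dt
  starts <- seq(min(frameTimes), max(frameTimes), by = stepS)
  rows <- list()
  for (s in starts) {
    if (s + winS > spanEnd + 1e-9) {
      warning(sprintf("skipping window at %.2f s: extends past frames", s))
      next
    }
    fr <- which(frameTimes >= s - 1e-9 & frameTimes < s + winS - 1e-9)
    if (!length(fr)) next
    xw <- apply(features[, fr, , drop = FALSE], c(1, 3), mean)
    res <- crossValidate(xw, labels, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = s, center_s = s + winS / 2,
      balanced_accuracy = res@balancedAccuracy)
  }
  do.call(rbind, rows)
}

#' Correct-vs-incorrect cue-response contrast
#'
#' For each axon, compares the mean conditioned-cue amplitude between
#' behaviorally correct and incorrect trials of each condition (paired
#' Wilcoxon signed-rank across axons), and compares the polar angle of
#' the per-axon (reward-cue, aversive-cue) response computed within the
#' correct and the incorrect stratum via [circularCompare()]. Axons
#' lacking trials in a required cell of the condition x correctness
#' design are excluded with a count.
#'
#' @param trialAmps long data.frame of per-trial cue amplitudes:
#'   columns `axon_id`, `trial_id`, `event_kind` (`cs_reward` /
#'   `cs_aversive`), `amplitude`.
#' @param groups four-group table from [classifyTrialsByLicking()] (or
#'   the facial-expression analogue).
#' @param nPerm,seed circular-comparison parameters.
#' @return list: `amplitude` (per condition: per-axon correct/incorrect
#'   means and the paired p), `angles` (per-axon correct/incorrect
#'   angles), `angle_p`, `n_excluded`.
#' @export
correctIncorrectContrast <- function(trialAmps, groups, nPerm = 10000,
                                     seed = 1L) {
  if (!any(groups$group %in% c("reward_incorrect", "aversive_incorrect")))
    stop("no incorrect trials at all: contrast undefined; ",
         "use an earlier phase (e.g. the middle phase) with errors")
  trialAmps$group <- groups$group[match(trialAmps$trial_id,
                                        groups$trial_id)]
  trialAmps <- trialAmps[!is.na(trialAmps$group), ]
  cellMean <- function(axon, kind, grp) {
    v <- trialAmps$amplitude[trialAmps$axon_id == axon &
                               trialAmps$event_kind == kind &
                               trialAmps$group == grp]
    if (length(v)) mean(v) else NA_real_
  }
  axons <- unique(trialAmps$axon_id)
  cells <- data.frame(
    axon_id = axons,
    rew_cor = vapply(axons, cellMean, numeric(1), "cs_reward",
                     "reward_correct"),
    rew_inc = vapply(axons, cellMean, numeric(1), "cs_reward",
                     "reward_incorrect"),
    av_cor = vapply(axons, cellMean, numeric(1), "cs_aversive",
                    "aversive_correct"),
    av_inc = vapply(axons, cellMean, numeric(1), "cs_aversive",
                    "aversive_incorrect"), stringsAsFactors = FALSE)
  complete <- stats::complete.cases(cells)
  nExcluded <- sum(!complete)
  cells <- cells[complete, ]
  if (!nrow(cells))
    stop("no axon has trials in every condition x correctness cell")
  wilcoxP <- function(a, b) suppressWarnings(
    wilcox.test(a, b, paired = TRUE)$p.value)
  amplitude <- data.frame(
    condition = c("reward", "aversive"),
    mean_correct = c(mean(cells$rew_cor), mean(cells$av_cor)),
    mean_incorrect = c(mean(cells$rew_inc), mean(cells$av_inc)),
    p = c(wilcoxP(cells$rew_cor, cells$rew_inc),
          wilcoxP(cells$av_cor, cells$av_inc)))
  ok <- (cells$rew_cor != 0 | cells$av_cor != 0) &
    (cells$rew_inc != 0 | cells$av_inc != 0)
  angles <- data.frame(
    axon_id = cells$axon_id[ok],
    theta_correct = polarAngle(cells$rew_cor[ok], cells$av_cor[ok]),
    theta_incorrect = polarAngle(cells$rew_inc[ok], cells$av_inc[ok]),
    stringsAsFactors = FALSE)
  anglePd <- circularCompare(angles$theta_correct, angles$theta_incorrect,
                             paired = TRUE, nPerm = nPerm, seed = seed)
  list(amplitude = amplitude, angles = angles, angle_p = anglePd,
       n_excluded = nExcluded, cells = cells)
}
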