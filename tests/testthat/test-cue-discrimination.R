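condTl <- function(conds) {
  n <- length(conds)
  data.frame(trial_id = seq_len(n), condition = conds,
             cs_onset_s = 60 * seq_len(n), cs_freq_hz = 9000,
             us_onset_s = ifelse(conds %in% c("reward", "aversive"),
                                 60 * seq_len(n) + 3, NA_real_),
             day_index = 1L)
}

test_that("four-group trial classification follows the licking rule", {
  tl <- condTl(c("reward", "reward", "aversive", "aversive", "control"))
  ant <- data.frame(trial_id = 1:5,
                    anticipatory = c(TRUE, FALSE, FALSE, TRUE, TRUE))
  g <- classifyTrialsByLicking(tl, ant)
  expect_identical(g$group,
                   c("reward_correct", "reward_incorrect",
                     "aversive_correct", "aversive_incorrect"))
  expect_false(5L %in% g$trial_id)   # control excluded
})

test_that("F-value selection ranks, clamps and handles degenerate features", {
  set.seed(10)
  n <- 60
  labels <- rep(c("a", "b"), c(45, 15))
  x <- matrix(rnorm(n * 1000), n)
  sel <- selectFeatures(x, labels, k = 400)
  expect_length(sel, 400L)
  # a perfectly separating feature is ranked first
  x[, 500] <- ifelse(labels == "a", 1, 0) + rnorm(n, 0, 1e-6)
  expect_identical(selectFeatures(x, labels, k = 400)[1], 500L)
  # fewer features than k: all returned
  expect_length(selectFeatures(x[, 1:50], labels, k = 400), 50L)
  # constant features get F = 0 and land last
  x2 <- cbind(matrix(rnorm(2 * n), n), 1)
  expect_identical(selectFeatures(x2, labels, k = 3)[3], 3L)
})

test_that("the balanced ensemble is deterministic and learns separable data", {
  set.seed(3)
  n <- 80
  labels <- factor(rep(c("reward", "aversive"), c(70, 10)))
  x <- matrix(rnorm(n * 20), n)
  x[labels == "aversive", 1] <- x[labels == "aversive", 1] + 6
  e1 <- fitBalancedEnsemble(x, labels, seed = 7)
  e2 <- fitBalancedEnsemble(x, labels, seed = 7)
  expect_identical(as.character(predict(e1, x)), as.character(predict(e2, x)))
  expect_identical(as.character(predict(e1, x)), as.character(labels))
  expect_error(fitBalancedEnsemble(x[1:70, ], labels[1:70]), "two classes")
  expect_error(
    fitBalancedEnsemble(rbind(x, x[1, ]),
                        factor(c(rep("a", 80), "b"))), "at least 2")
})

test_that("balanced accuracy weights classes equally", {
  labels <- rep(c("reward", "aversive"), c(70, 10))
  expect_equal(balancedAccuracy(labels, labels), 100)
  expect_equal(balancedAccuracy(rep("reward", 80), labels), 50)
  # duplicating every majority-class trial changes nothing
  pred <- c(rep("reward", 65), rep("aversive", 5),
            rep("reward", 3), rep("aversive", 7))
  ba1 <- balancedAccuracy(pred, labels)
  dup <- c(seq_along(labels), which(labels == "reward"))
  ba2 <- balancedAccuracy(pred[dup], labels[dup])
  expect_equal(ba1, ba2)
})

test_that("cross-validation predicts every trial once without leakage", {
  set.seed(11)
  n <- 90
  labels <- rep(c("reward", "aversive"), c(75, 15))
  x <- matrix(rnorm(n * 120), n)
  x[labels == "aversive", 1:10] <- x[labels == "aversive", 1:10] + 2
  res <- crossValidate(x, labels, k = 40, nMembers = 7, memberTrees = 20,
                       seed = 5)
  expect_identical(nrow(res@predictions), as.integer(n))
  expect_false(anyNA(res@predictions$predicted))
  expect_identical(sort(unique(res@predictions$fold)), 1:5)
  # selection was re-fit per training fold: fold-wise feature sets differ
  expect_gt(length(unique(res@selectedFeatures)), 1L)
  # the informative block dominates each fold's selection
  for (sel in res@selectedFeatures)
    expect_gte(sum(1:10 %in% sel[1:20]), 8)
  expect_gt(res@balancedAccuracy, 80)
  expect_error(crossValidate(x[labels == "reward", ],
                             labels[labels == "reward"]), "both classes")
})

test_that("fold count shrinks with a warning when the minority class is tiny", {
  set.seed(2)
  labels <- rep(c("reward", "aversive"), c(30, 3))
  x <- matrix(rnorm(33 * 10), 33)
  expect_warning(res <- crossValidate(x, labels, nMembers = 3,
                                      memberTrees = 10, seed = 1),
                 "reducing folds")
  expect_identical(max(res@predictions$fold), 3L)
})

test_that("sliding windows tile the cue period as specified", {
  # 2 s of frames, 0.5 s window, 0.16 s step -> starts 0, 0.16, ..., 1.44
  set.seed(4)
  nTr <- 40
  labels <- rep(c("reward", "aversive"), each = nTr / 2)
  times <- seq(0, 2 - 0.1, by = 0.1)
  feats <- array(rnorm(nTr * length(times) * 12),
                 dim = c(nTr, length(times), 12))
  out <- suppressWarnings(
    slidingWindowAccuracy(feats, times, labels, k = 12, nMembers = 3,
                          memberTrees = 10, nFolds = 3, seed = 1))
  expect_equal(out$start_s, seq(0, 1.44, by = 0.16), tolerance = 1e-9)
  expect_identical(nrow(out), 10L)
})

test_that("decoding accuracy localises a time-confined effect", {
  set.seed(14)
  nTr <- 120
  labels <- rep(c("reward", "aversive"), c(90, 30))
  times <- seq(-1, 2 - 0.1, by = 0.1)
  feats <- array(rnorm(nTr * length(times) * 30),
                 dim = c(nTr, length(times), 30))
  eff <- which(times >= 0.5 & times < 1.0)
  feats[labels == "aversive", eff, 1:10] <-
    feats[labels == "aversive", eff, 1:10] + 2.5
  out <- suppressWarnings(
    slidingWindowAccuracy(feats, times, labels, k = 15, nMembers = 7,
                          memberTrees = 20, seed = 3))
  pre <- out$balanced_accuracy[out$start_s < -0.5]
  peak <- out$center_s[which.max(out$balanced_accuracy)]
  expect_lt(mean(pre), 62)
  expect_gte(peak, 0.4); expect_lte(peak, 1.1)
  expect_gt(max(out$balanced_accuracy), 85)
})

test_that("correct/incorrect contrast recovers an injected coupling", {
  set.seed(8)
  nAx <- 50
  trials <- condTl(rep(c("reward", "aversive"), c(28, 12)))
  ant <- data.frame(trial_id = trials$trial_id,
                    anticipatory = ifelse(trials$condition == "reward",
                                          runif(40) < 0.6, runif(40) < 0.3))
  groups <- classifyTrialsByLicking(trials, ant)
  mk <- function(coupling) {
    do.call(rbind, lapply(seq_len(nAx), function(a) {
      do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
        kind <- if (groups$condition[i] == "reward") "cs_reward" else
          "cs_aversive"
        base <- if (kind == "cs_aversive") 0.5 else 0.3
        gain <- if (groups$group[i] == "aversive_correct") coupling else 1
        data.frame(axon_id = sprintf("ax%02d", a),
                   trial_id = groups$trial_id[i], event_kind = kind,
                   amplitude = base * gain + rnorm(1, 0, 0.05))
      }))
    }))
  }
  res <- correctIncorrectContrast(mk(1.8), groups, nPerm = 500, seed = 2)
  avRow <- res$amplitude[res$amplitude$condition == "aversive", ]
  expect_gt(avRow$mean_correct, avRow$mean_incorrect)
  expect_lt(avRow$p, 0.05)
  expect_lt(res$angle_p, 0.05)
  # correctness-independent amplitudes: p is not systematically small
  res0 <- correctIncorrectContrast(mk(1), groups, nPerm = 500, seed = 3)
  expect_gt(res0$amplitude$p[2], 0.01)
  # all-correct sessions cannot be contrasted
  antAll <- data.frame(trial_id = trials$trial_id,
                       anticipatory = trials$condition == "reward")
  gAll <- classifyTrialsByLicking(trials, antAll)
  expect_error(correctIncorrectContrast(mk(1), gAll, nPerm = 500),
               "no incorrect trials")
})

test_that("decoder-based trial groups mirror the licking rule with predictions", {
  tl <- condTl(c("reward", "reward", "aversive", "aversive", "control"))
  pred <- data.frame(trial_id = 1:4,
                     predicted = c("reward", "aversive", "aversive",
                                   "reward"))
  g <- classifyTrialsByDecoder(tl, pred)
  expect_identical(g$group,
                   c("reward_correct", "reward_incorrect",
                     "aversive_correct", "aversive_incorrect"))
  expect_identical(attr(g, "basis"), "facial")
  expect_error(classifyTrialsByDecoder(tl, pred[-1, ]), "missing")
})
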