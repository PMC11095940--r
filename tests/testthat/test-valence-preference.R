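test_that("polar angle follows the Cartesian valence convention", {
  expect_equal(polarAngle(1, 1), 45)
  expect_equal(polarAngle(0, 0.5), 90)
  expect_equal(polarAngle(0.3, 0), 0)
  expect_equal(polarAngle(1, -1), -45)
  expect_equal(polarAngle(-1, 0), 180)
  # invariance to positive rescaling
  set.seed(4)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(polarAngle(x, y), polarAngle(10 * x, 10 * y),
               tolerance = 1e-12)
  expect_error(polarAngle(0, 0), "undefined")
})

test_that("angle density integrates to one and peaks at a point mass", {
  d <- angleDensity(rep(30, 10), bandwidthDeg = 5)
  integral <- sum(d$density * diff(c(d$grid_deg, d$grid_deg[1] + 360)))
  expect_lt(abs(integral - 1), 1e-6)
  expect_equal(d$grid_deg[which.max(d$density)], 30, tolerance = 1)
  # integral invariant for arbitrary data and auto bandwidth
  set.seed(8)
  d2 <- angleDensity(runif(200, -180, 180))
  integral2 <- sum(d2$density * diff(c(d2$grid_deg, d2$grid_deg[1] + 360)))
  expect_lt(abs(integral2 - 1), 1e-6)
})

test_that("a bimodal angle sample produces two modes with one trough between", {
  cfg <- smallCfg()
  pop <- sampleAxonPopulation(cfg, nAxons = 400, seed = 3)
  d <- angleDensity(pop$theta_true_deg)
  sub <- d$density[d$grid_deg > -30 & d$grid_deg < 120]
  grid <- d$grid_deg[d$grid_deg > -30 & d$grid_deg < 120]
  locmax <- which(diff(sign(diff(sub))) == -2) + 1
  expect_identical(length(locmax), 2L)
  expect_lt(abs(grid[locmax[1]] - 15), 12)
  expect_lt(abs(grid[locmax[2]] - 75), 12)
  between <- locmax[1]:locmax[2]
  trough <- between[which.min(sub[between])]
  expect_gt(grid[trough], 30); expect_lt(grid[trough], 65)
})

test_that("uniform angles give a nearly flat density", {
  set.seed(12)
  d <- angleDensity(runif(10000, -180, 180))
  expect_lt(max(d$density) / min(d$density), 1.3)
})

test_that("well-separated clusters are labeled perfectly and stably across seeds", {
  set.seed(21)
  n <- 50
  th1 <- (10 + rnorm(n, 0, 3)) * pi / 180
  th2 <- (80 + rnorm(n, 0, 3)) * pi / 180
  r <- runif(2 * n, 0.8, 1.2)
  rec <- data.frame(axon_id = sprintf("a%02d", 1:(2 * n)),
                    r_reward = r * cos(c(th1, th2)),
                    r_aversive = r * sin(c(th1, th2)))
  out1 <- clusterPreference(rec, seed = 1)
  expect_true(all(out1$cluster[1:n] == "reward_preferring"))
  expect_true(all(out1$cluster[(n + 1):(2 * n)] == "aversive_preferring"))
  out2 <- clusterPreference(rec, seed = 99)
  expect_identical(out1$cluster, out2$cluster)
  # invariant to point order
  perm <- sample(2 * n)
  out3 <- clusterPreference(rec[perm, ], seed = 1)
  expect_identical(out3$cluster[order(perm)], out1$cluster)
})

test_that("clustering a bimodal population recovers ground truth with a ~45 deg boundary", {
  cfg <- smallCfg()
  pop <- sampleAxonPopulation(cfg, nAxons = 200, seed = 6)
  set.seed(60)
  rec <- data.frame(axon_id = pop$axon_id,
                    r_reward = pop$amp_reward + rnorm(200, 0, 0.05),
                    r_aversive = pop$amp_aversive + rnorm(200, 0, 0.05))
  out <- clusterPreference(rec, seed = 2)
  agree <- mean((out$cluster == "aversive_preferring") ==
                  (pop$theta_true_deg > 45))
  expect_gte(agree, 0.9)
  bd <- attr(out, "boundary_deg")
  expect_gte(bd, 40); expect_lte(bd, 55)
})

test_that("degenerate clustering input raises", {
  rec <- data.frame(axon_id = c("a", "b", "c"), r_reward = 1,
                    r_aversive = 1)
  expect_error(clusterPreference(rec), "degenerate")
})

test_that("vector averages behave as arithmetic means of response vectors", {
  rec <- data.frame(axon_id = c("a", "b"), r_reward = c(1, 0),
                    r_aversive = c(0, 1), cluster = "x")
  v <- vectorAverage(rec, "x")
  expect_equal(unname(v), c(0.5, 0.5, 45))
  one <- vectorAverage(rec[1, ], "x")
  expect_equal(unname(one[1:2]), c(1, 0))
  # mirror symmetry about 45 degrees
  th <- c(10, 80, 25, 65) * pi / 180
  sym <- data.frame(axon_id = letters[1:4], r_reward = cos(th),
                    r_aversive = sin(th), cluster = "x")
  expect_equal(unname(vectorAverage(sym, "x")["theta_deg"]), 45,
               tolerance = 1e-9)
  expect_error(vectorAverage(rec, "missing"), "no members")
})

test_that("circular comparison: identity gives p = 1, a 90 deg shift is detected", {
  set.seed(9)
  a <- rnorm(40, 20, 5)
  expect_equal(circularCompare(a, a, paired = TRUE, nPerm = 500), 1)
  b <- a + 90
  expect_lt(circularCompare(a, b, paired = TRUE, nPerm = 1000, seed = 2),
            0.01)
  expect_lt(circularCompare(a, b, paired = FALSE, nPerm = 1000, seed = 2),
            0.01)
  expect_error(circularCompare(a, b[-1], paired = TRUE), "equal lengths")
  expect_error(circularCompare(a, b, nPerm = 10), "at least 100")
})

test_that("circular comparison is calibrated under the null", {
  set.seed(123)
  nRep <- 400
  p <- vapply(seq_len(nRep), function(i) {
    a <- rnorm(20, 40, 15); b <- rnorm(20, 40, 15)
    circularCompare(a, b, paired = TRUE, nPerm = 399, seed = i)
  }, numeric(1))
  rate <- mean(p <= 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
  # p-values roughly uniform: mean near 0.5
  expect_lt(abs(mean(p) - 0.5), 0.06)
})

test_that("phase course keeps externally fixed clusters and tracks amplitudes", {
  # hand-built per-phase response tables with a CS_aversive ramp in the
  # aversive cluster only
  axons <- sprintf("ax%02d", 1:12)
  clusters <- data.frame(axon_id = axons,
                         cluster = rep(c("reward_preferring",
                                         "aversive_preferring"), c(4, 8)))
  mkTab <- function(csAvGain) {
    do.call(rbind, lapply(seq_along(axons), function(i) {
      avPref <- i > 4
      data.frame(axon_id = axons[i],
                 event_kind = c("cs_reward", "cs_aversive", "us_reward",
                                "us_aversive"),
                 amplitude = c(0.3,
                               if (avPref) 0.3 * csAvGain else 0.3,
                               if (avPref) 0.2 else 1.0,
                               if (avPref) 1.0 else 0.2),
                 n_trials = 10L)
    }))
  }
  course <- phasePreferenceCourse(
    list(first_day = mkTab(1), late = mkTab(3)), clusters)
  ang <- course$vectors
  firstCs <- ang$theta_deg[ang$phase == "first_day" & ang$axis == "cs" &
                             ang$cluster == "aversive_preferring"]
  lateCs <- ang$theta_deg[ang$phase == "late" & ang$axis == "cs" &
                            ang$cluster == "aversive_preferring"]
  expect_equal(firstCs, 45)
  expect_gt(lateCs, firstCs + 15)
  rewCs <- ang$theta_deg[ang$axis == "cs" &
                           ang$cluster == "reward_preferring"]
  expect_equal(rewCs, c(45, 45))
  # absent axons are recorded as absent, not imputed
  course2 <- phasePreferenceCourse(
    list(first_day = mkTab(1)[-(1:4), ]), clusters)
  expect_false("ax01" %in% course2$amplitudes$axon_id)
})
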