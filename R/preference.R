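# Valence-preference machinery: polar angle on the (reward, aversive)
# response plane, circular kernel density, two-cluster classification,
# vector averages, circular comparisons and learning-phase courses.

#' Polar angle of a (reward, aversive) response pair
#'
#' Full-plane two-argument arctangent in degrees: 0 degrees is a purely
#' reward-preferring response, 90 degrees purely aversive-preferring.
#' Negative amplitudes are permitted (angles cover (-180, 180]); the
#' angle is invariant to positive rescaling of the pair.
#'
#' @param rReward,rAversive response amplitudes (dF/F); vectorised.
#' @return angle(s) in degrees in (-180, 180].
#' @export
polarAngle <- function(rReward, rAversive) {
  if (any(rReward == 0 & rAversive == 0))
    stop("polar angle is undefined for the zero response vector")
  atan2(rAversive, rReward) / pi * 180
}

#' Circular kernel density of preference angles
#'
#' Gaussian kernel wrapped on the circle (period 360 degrees). The
#' default bandwidth follows a circular Silverman rule: the normal
#' reference bandwidth computed from the circular standard deviation
#' `sqrt(-2 log(Rbar))` of the sample.
#'
#' @param angles angles in degrees.
#' @param bandwidthDeg kernel bandwidth in degrees; `NULL` for the
#'   automatic rule.
#' @param gridDeg evaluation grid (default every 0.5 degrees over
#'   (-180, 180]).
#' @return list of class `AngleDensity`: `grid_deg`, `density` (per
#'   degree; trapezoidal integral 1), `bandwidth_deg`.
#' @export
angleDensity <- function(angles, bandwidthDeg = NULL,
                         gridDeg = seq(-179.5, 180, by = 0.5)) {
  stopifnot(length(angles) >= 2)
  a <- wrapDeg(angles)
  if (is.null(bandwidthDeg)) {
    r <- a * pi / 180
    rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
    sdCirc <- sqrt(max(-2 * log(max(rbar, 1e-12)), 1e-12)) * 180 / pi
    bandwidthDeg <- max(1, (4 / (3 * length(a)))^(1 / 5) * sdCirc)
  }
  dens <- vapply(gridDeg, function(g) {
    d <- wrapDeg(a - g)
    # wrap the Gaussian kernel over +/- 2 periods
    mean(rowSums(vapply(c(-720, -360, 0, 360, 720), function(k)
      stats::dnorm(d + k, sd = bandwidthDeg), numeric(length(d)))))
  }, numeric(1))
  # enforce unit trapezoidal integral over the circular support
  width <- diff(c(gridDeg, gridDeg[1] + 360))
  total <- sum(dens * width)
  out <- list(grid_deg = gridDeg, density = dens / total,
              bandwidth_deg = bandwidthDeg)
  class(out) <- c("AngleDensity", "list")
  out
}

#' Two-cluster valence-preference classification
#'
#' k-means (k = 2 by default, 50 restarts, seeded) on the raw
#' (reward, aversive) response vectors of significantly responsive
#' axons; both axes share dF/F units so no standardisation is applied.
#' The cluster whose members have the smaller circular-mean angle is
#' labeled `reward_preferring`, the other `aversive_preferring`. The
#' reported decision-boundary angle is the polar angle at which the
#' perpendicular bisector of the two centroids crosses the circle of
#' median response magnitude.
#'
#' @param records data.frame with columns `axon_id`, `r_reward`,
#'   `r_aversive` (significant axons only).
#' @param k number of clusters (2).
#' @param seed seed for the restarts.
#' @param nstart k-means restarts (50).
#' @return `records` with added columns `theta_deg`, `magnitude`,
#'   `cluster`; attributes `centers` and `boundary_deg`.
#' @export
clusterPreference <- function(records, k = 2, seed = 1L, nstart = 50) {
  stopifnot(nrow(records) >= k)
  xy <- cbind(records$r_reward, records$r_aversive)
  if (nrow(unique(xy)) < k)
    stop("degenerate input: fewer distinct response vectors than clusters")
  km <- withSeed(deriveSeed(seed, "kmeans"),
                 kmeans(xy, centers = k, nstart = nstart))
  ang <- vapply(seq_len(k), function(c)
    circMeanDeg(polarAngle(records$r_reward[km$cluster == c],
                           records$r_aversive[km$cluster == c])),
    numeric(1))
  labels <- rep("aversive_preferring", k)
  labels[which.min(ang)] <- "reward_preferring"
  out <- records
  out$theta_deg <- polarAngle(records$r_reward, records$r_aversive)
  out$magnitude <- sqrt(records$r_reward^2 + records$r_aversive^2)
  out$cluster <- labels[km$cluster]
  attr(out, "centers") <- km$centers
  attr(out, "boundary_deg") <- kmeansBoundaryDeg(km$centers,
                                                 median(out$magnitude))
  out
}

# Polar angle at which the perpendicular bisector of two centroids
# intersects the circle of radius r (the assignment flip point for a
# response vector of typical magnitude).
kmeansBoundaryDeg <- function(centers, r) {
  d <- centers[1, ] - centers[2, ]
  b <- (sum(centers[1, ]^2) - sum(centers[2, ]^2)) / 2
  # solve r*(cos t, sin t) . d = b  for t in [-180, 180]
  amp <- r * sqrt(sum(d^2))
  if (amp < abs(b)) return(NA_real_)
  phi <- atan2(d[2], d[1])
  delta <- acos(b / amp)
  cand <- wrapDeg(c(phi + delta, phi - delta) / pi * 180)
  # report the candidate inside the first quadrant if one exists
  inQ <- cand[cand >= -45 & cand <= 135]
  if (length(inQ)) inQ[which.min(abs(inQ - 45))] else cand[1]
}

#' Vector average of a preference cluster
#'
#' Component-wise arithmetic mean of the (reward, aversive) response
#' vectors of the cluster members, as drawn as the cluster arrows on the
#' preference scatter.
#'
#' @param records a clustered preference table ([clusterPreference()]).
#' @param cluster cluster label to average, or `NULL` for all rows.
#' @return named numeric: `r_reward`, `r_aversive`, `theta_deg`.
#' @export
vectorAverage <- function(records, cluster = NULL) {
  rows <- if (is.null(cluster)) records else
    records[records$cluster == cluster, ]
  if (!nrow(rows)) stop("no members in cluster ", cluster)
  v <- c(r_reward = mean(rows$r_reward), r_aversive = mean(rows$r_aversive))
  c(v, theta_deg = polarAngle(v[["r_reward"]], v[["r_aversive"]]))
}

#' Seeded permutation test for circular means
#'
#' Paired mode: tests whether the circular mean of the wrapped per-axon
#' angle differences is zero, by randomly sign-flipping the differences
#' (the exact null under symmetry). Unpaired mode: permutes group labels
#' and compares the absolute wrapped difference of group circular means.
#' p-values use the add-one permutation estimator.
#'
#' @param anglesA,anglesB angle samples in degrees (equal length when
#'   paired).
#' @param paired paired comparison? Default `TRUE`.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @return the permutation p-value.
#' @export
circularCompare <- function(anglesA, anglesB, paired = TRUE,
                            nPerm = 10000, seed = 1L) {
  if (nPerm < 100) stop("nPerm must be at least 100")
  if (paired && length(anglesA) != length(anglesB))
    stop("paired comparison requires equal lengths")
  withSeed(deriveSeed(seed, "circ"), {
    if (paired) {
      # under H0 the wrapped differences are symmetric about 0, so their
      # sine components are sign-symmetric; |mean sin| measures how far
      # the circular mean of the differences sits from 0
      d <- wrapDeg(anglesA - anglesB) * pi / 180
      n <- length(d)
      obs <- abs(mean(sin(d)))
      sgn <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
      perm <- abs(as.numeric(sgn %*% sin(d)) / n)
      (1 + sum(perm >= obs - 1e-12)) / (nPerm + 1)
    } else {
      ab <- c(anglesA, anglesB)
      nA <- length(anglesA)
      statf <- function(x, y) abs(wrapDeg(circMeanDeg(x) - circMeanDeg(y)))
      obs <- statf(anglesA, anglesB)
      perm <- vapply(seq_len(nPerm), function(i) {
        idx <- sample.int(length(ab), nA)
        statf(ab[idx], ab[-idx])
      }, numeric(1))
      (1 + sum(perm >= obs - 1e-12)) / (nPerm + 1)
    }
  })
}

#' Learning-phase course of valence preference
#'
#' Tracks CS and US response amplitudes, polar angles and vector
#' averages across learning phases for clusters that were fixed before
#' conditioning (labels are supplied, never re-fit per phase). Axons
#' missing from a phase are recorded as absent, not imputed.
#'
#' @param phaseTables named list: phase -> response table
#'   ([responseTable()]) containing `cs_reward`, `cs_aversive`,
#'   `us_reward`, `us_aversive` rows.
#' @param clusters data.frame `axon_id`, `cluster` from the
#'   pre-conditioning [clusterPreference()].
#' @return list with elements `amplitudes` (long data.frame: phase,
#'   cluster, axon_id, event_kind, amplitude), `angles` (per phase,
#'   cluster and axon: CS and US polar angles) and `vectors` (per phase
#'   and cluster: CS and US vector averages).
#' @export
phasePreferenceCourse <- function(phaseTables, clusters) {
  stopifnot(!is.null(names(phaseTables)))
  amp <- list(); ang <- list(); vec <- list()
  for (ph in names(phaseTables)) {
    tab <- phaseTables[[ph]]
    tab <- tab[tab$axon_id %in% clusters$axon_id, ]
    tab$cluster <- clusters$cluster[match(tab$axon_id, clusters$axon_id)]
    amp[[ph]] <- data.frame(phase = ph,
                            tab[, c("cluster", "axon_id", "event_kind",
                                    "amplitude", "n_trials")],
                            stringsAsFactors = FALSE)
    wide <- function(kind) {
      sub <- tab[tab$event_kind == kind, ]
      setNames(sub$amplitude, sub$axon_id)
    }
    for (what in c("cs", "us")) {
      rw <- wide(paste0(what, "_reward")); av <- wide(paste0(what, "_aversive"))
      common <- intersect(names(rw), names(av))
      common <- common[rw[common] != 0 | av[common] != 0]
      if (!length(common)) next
      ang[[paste(ph, what)]] <- data.frame(
        phase = ph, axis = what, axon_id = common,
        cluster = clusters$cluster[match(common, clusters$axon_id)],
        theta_deg = polarAngle(rw[common], av[common]),
        stringsAsFactors = FALSE)
      for (cl in unique(clusters$cluster)) {
        mem <- common[clusters$cluster[match(common,
                                             clusters$axon_id)] == cl]
        if (!length(mem)) next
        vec[[paste(ph, what, cl)]] <- data.frame(
          phase = ph, axis = what, cluster = cl,
          r_reward = mean(rw[mem]), r_aversive = mean(av[mem]),
          theta_deg = polarAngle(mean(rw[mem]), mean(av[mem])),
          n_axons = length(mem), stringsAsFactors = FALSE)
      }
    }
  }
  list(amplitudes = do.call(rbind, c(amp, list(make.row.names = FALSE))),
       angles = do.call(rbind, c(ang, list(make.row.names = FALSE))),
       vectors = do.call(rbind, c(vec, list(make.row.names = FALSE))))
}
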