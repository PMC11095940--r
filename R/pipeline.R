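# End-to-end orchestration: simulate (or load) a multi-day experiment,
# preprocess, quantify responses, derive preference and phase courses,
# analyse behavior and run the cue-discrimination decoder; emit tidy
# figure-substrate tables with a run log. Identical config + seed gives
# byte-identical outputs.

#' Pool response tables across sessions
#'
#' Concatenates the per-trial amplitudes and window means of several
#' response tables (e.g. the days of one learning phase) per axon and
#' event kind, then recomputes the summary amplitude and signed-rank
#' significance on the pooled trials.
#'
#' @param tables list of response tables from [responseTable()] over the
#'   same axons and event kinds.
#' @param alpha,alternative significance parameters.
#' @return a pooled response table.
#' @export
poolResponseTables <- function(tables, alpha = 0.05,
                               alternative = "greater") {
  stopifnot(length(tables) >= 1)
  all <- do.call(rbind, tables)
  keys <- unique(all[, c("axon_id", "event_kind")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- all[all$axon_id == keys$axon_id[i] &
                 all$event_kind == keys$event_kind[i], ]
    per <- unlist(sub$per_trial)
    sm <- unlist(sub$signal_means); cm <- unlist(sub$control_means)
    sig <- responseSignificance(cm, sm, alpha, alternative)
    data.frame(axon_id = keys$axon_id[i], event_kind = keys$event_kind[i],
               amplitude = mean(per), n_trials = length(per),
               signal_means = I(list(sm)), control_means = I(list(cm)),
               per_trial = I(list(per)),
               trial_ids = I(list(unlist(sub$trial_ids))),
               p = sig$p,
               significant = if (is.na(sig$p)) NA else sig$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Flatten the list-columns of a response table into a long per-trial
# data.frame (axon_id, event_kind, trial_id, amplitude).
trialAmplitudes <- function(tab) {
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    data.frame(axon_id = tab$axon_id[i], event_kind = tab$event_kind[i],
               trial_id = tab$trial_ids[[i]],
               amplitude = tab$per_trial[[i]], stringsAsFactors = FALSE)))
}

dropListCols <- function(tab) {
  tab[, !vapply(tab, is.list, logical(1)), drop = FALSE]
}

writeCsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- fmtNum(df[[j]])
  data.table::fwrite(df, path, quote = "auto", na = "NA")
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, compress = FALSE)
  unname(tools::md5sum(f))
}

readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package not available; use a JSON config")
      config <- yaml::read_yaml(config)
    } else config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Simulates one unconditioned pre-training session plus `nDays`
#' conditioned sessions, then: computes dF/F, deduplicates ROIs on the
#' pre-training session (representatives are reused across days, as in
#' longitudinal imaging of one field), quantifies unconditioned
#' responses and fixes the preference clusters before conditioning,
#' quantifies CS/US responses and behavior per day, pools them into
#' learning phases, runs the phase-preference course, decodes cue
#' identity from facial features within each late-phase day, and
#' computes the correct-vs-incorrect contrast from licking-based trial
#' groups. All stage parameters have the pipeline defaults and can be
#' overridden through `config`.
#'
#' @param config a list (or path to a JSON/YAML file) with optional
#'   entries `seed`, `nDays`, `simulation` (arguments to
#'   [simulationConfig()]), `dff` (`windowS`, `percentile`),
#'   `dedupThreshold`, `discrimination` (`k`, `nMembers`,
#'   `memberTrees`, `nFolds`).
#' @param outDir output directory; created if needed.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runAll <- function(config = list(), outDir) {
  config <- readRunConfig(config)
  seed <- config$seed %||% 1L
  nDays <- config$nDays %||% 12L
  cfg <- do.call(simulationConfig, config$simulation %||% list())
  cfg$seed <- as.integer(seed)
  dffW <- (config$dff %||% list())$windowS %||% 30
  dffP <- (config$dff %||% list())$percentile %||% 50
  thr <- config$dedupThreshold %||% 0.65
  dcfg <- config$discrimination %||% list()
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  exp <- simulateExperiment(cfg, nDays = nDays, seed = seed)

  # -- preprocessing: dedup fixed on the pre-training session
  dff0 <- computeDff(exp$pretraining$bundle@fluor, dffW, dffP)
  axonSet <- deduplicateAxons(dff0, thr, seed = seed)
  ax0 <- axonTraces(dff0, axonSet)

  # -- pre-conditioning preference clustering
  tab0 <- responseTable(ax0, timeline(exp$pretraining$bundle),
                        kinds = c("us_reward", "us_aversive"))
  sig0 <- axonSignificance(tab0)
  rec <- data.frame(
    axon_id = sig0$axon_id,
    r_reward = tab0$amplitude[tab0$event_kind == "us_reward"][
      match(sig0$axon_id, tab0$axon_id[tab0$event_kind == "us_reward"])],
    r_aversive = tab0$amplitude[tab0$event_kind == "us_aversive"][
      match(sig0$axon_id, tab0$axon_id[tab0$event_kind == "us_aversive"])],
    significant = sig0$significant, stringsAsFactors = FALSE)
  pref <- clusterPreference(rec[rec$significant %in% TRUE, ],
                            seed = seed)
  clusters <- data.frame(axon_id = rec$axon_id,
                         cluster = ifelse(rec$significant %in% TRUE,
                                          pref$cluster[match(rec$axon_id,
                                                             pref$axon_id)],
                                          "nonsignificant"),
                         stringsAsFactors = FALSE)
  writeCsv(merge(dropListCols(rec),
                 clusters, by = "axon_id", sort = TRUE),
           file.path(outDir, "preference.csv"))
  dens <- angleDensity(pref$theta_deg)
  writeCsv(data.frame(grid_deg = dens$grid_deg, density = dens$density),
           file.path(outDir, "density.csv"))

  # -- per-day responses and behavior
  dayTabs <- list(); behRows <- list(); respRows <- list()
  for (d in seq_len(nDays)) {
    bundle <- exp$days[[d]]$bundle
    dffD <- computeDff(bundle@fluor, dffW, dffP)
    axD <- axonTraces(dffD, axonSet)
    tabD <- responseTable(axD, timeline(bundle))
    dayTabs[[d]] <- tabD
    out <- dropListCols(tabD); out$day <- d
    respRows[[d]] <- out
    beh <- behavior(bundle)
    licks <- detectLicks(beh@tongue, beh@tongueFsHz, cfg$spoutPos)
    bouts <- detectRunningBouts(beh@speed, beh@speedFsHz)
    antL <- anticipatoryResponse(licks, timeline(bundle))
    antR <- anticipatoryResponse(bouts, timeline(bundle))
    behRows[[d]] <- data.frame(
      day = d, trial_id = antL$perTrial$trial_id,
      condition = antL$perTrial$condition,
      anticipatory_lick = antL$perTrial$anticipatory,
      anticipatory_run = antR$perTrial$anticipatory,
      stringsAsFactors = FALSE)
  }
  writeCsv(do.call(rbind, respRows), file.path(outDir, "responses.csv"))
  behTab <- do.call(rbind, behRows)
  writeCsv(behTab, file.path(outDir, "behavior.csv"))

  # -- learning phases and preference course
  phases <- splitPhases(seq_len(nDays))
  writeCsv(data.frame(day = phases$day, phase = as.character(phases$phase)),
           file.path(outDir, "phases.csv"))
  phaseTabs <- lapply(split(phases$day, phases$phase),
                      function(dd) poolResponseTables(dayTabs[dd]))
  course <- phasePreferenceCourse(phaseTabs, clusters)
  writeCsv(course$amplitudes, file.path(outDir, "course_amplitudes.csv"))
  writeCsv(course$angles, file.path(outDir, "course_angles.csv"))
  writeCsv(course$vectors, file.path(outDir, "course_vectors.csv"))

  # -- cue discrimination on late-phase facial features (within-day CV)
  lateDays <- phases$day[phases$phase == "late"]
  discrim <- list()
  for (d in lateDays) {
    bundle <- exp$days[[d]]$bundle
    tl <- timeline(bundle)
    keep <- which(tl$condition %in% c("reward", "aversive"))
    if (length(unique(tl$condition[keep])) < 2 ||
        min(table(tl$condition[keep])) < 2) next
    fac <- bundle@behavior@facial
    times <- bundle@behavior@facialTimesS
    cueFr <- which(times >= 0 & times < cfg$csDurationS)
    xw <- apply(fac[keep, cueFr, , drop = FALSE], c(1, 3), mean)
    res <- crossValidate(xw, tl$condition[keep],
                         nFolds = dcfg$nFolds %||% 5,
                         k = dcfg$k %||% 400,
                         nMembers = dcfg$nMembers %||% 25,
                         memberTrees = dcfg$memberTrees %||% 50,
                         seed = deriveSeed(seed, paste0("discrim", d)))
    discrim[[as.character(d)]] <- list(
      day = d, balanced_accuracy = res@balancedAccuracy,
      fold_accuracy = res@foldAccuracy)
  }
  accs <- vapply(discrim, `[[`, numeric(1), "balanced_accuracy")
  discrimOut <- list(basis = "facial", per_day = unname(discrim),
                     mean_balanced_accuracy = mean(accs))
  writeLines(jsonlite::toJSON(discrimOut, auto_unbox = TRUE, digits = NA),
             file.path(outDir, "discrim.json"))

  # -- correct/incorrect contrast from licking groups: late phase, with
  # fallback to the middle phase when the late phase lacks error trials
  contrastOnDays <- function(days) {
    groups <- do.call(rbind, lapply(days, function(d) {
      tl <- timeline(exp$days[[d]]$bundle)
      ant <- behTab[behTab$day == d,
                    c("trial_id", "condition", "anticipatory_lick")]
      names(ant)[3] <- "anticipatory"
      g <- classifyTrialsByLicking(tl, ant)
      g$trial_id <- g$trial_id + 1000L * d   # unique ids across days
      g
    }))
    trialAmps <- do.call(rbind, lapply(days, function(d) {
      ta <- trialAmplitudes(dayTabs[[d]])
      ta <- ta[ta$event_kind %in% c("cs_reward", "cs_aversive"), ]
      ta$trial_id <- ta$trial_id + 1000L * d
      ta
    }))
    correctIncorrectContrast(trialAmps, groups,
                             seed = deriveSeed(seed, "contrast"))
  }
  midDays <- phases$day[phases$phase == "middle"]
  contrast <- tryCatch(contrastOnDays(lateDays), error = function(e) e)
  contrastPhase <- "late"
  if (inherits(contrast, "error")) {
    contrast <- tryCatch(contrastOnDays(midDays), error = function(e) e)
    contrastPhase <- "middle"
  }
  if (inherits(contrast, "error")) {
    writeCsv(data.frame(note = conditionMessage(contrast)),
             file.path(outDir, "contrast.csv"))
  } else {
    out <- contrast$amplitude
    out$angle_p <- contrast$angle_p
    out$n_excluded <- contrast$n_excluded
    out$phase_used <- contrastPhase
    writeCsv(out, file.path(outDir, "contrast.csv"))
  }

  log <- list(config_hash = configHash(config), seed = seed, nDays = nDays,
              n_rois = length(membership(axonSet)),
              n_axons = length(representatives(axonSet)),
              package_version = as.character(utils::packageVersion("AxonValence")))
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA),
             file.path(outDir, "run.json"))
  invisible(list(experiment = exp, axonSet = axonSet, preference = pref,
                 clusters = clusters, dayTables = dayTabs,
                 phases = phases, course = course, behavior = behTab,
                 discrimination = discrimOut, contrast = contrast,
                 outDir = outDir))
}

#' Render a static summary report from pipeline outputs
#'
#' Reads the tables written by [runAll()] and produces `report.pdf`
#' (preference scatter with vector averages, circular angle density,
#' phase-course amplitudes, per-day decoding accuracy) plus
#' `summary.md`. Missing tables are listed in the summary and skipped;
#' regeneration is idempotent.
#'
#' @param outDir directory written by [runAll()].
#' @return invisibly, the report path.
#' @export
report <- function(outDir) {
  need <- c("preference.csv", "density.csv", "course_amplitudes.csv",
            "behavior.csv", "discrim.json", "contrast.csv")
  present <- file.exists(file.path(outDir, need))
  missing <- need[!present]
  pdfPath <- file.path(outDir, "report.pdf")
  grDevices::pdf(pdfPath, width = 7, height = 6)
  on.exit(grDevices::dev.off())
  if (file.exists(file.path(outDir, "preference.csv"))) {
    pref <- data.table::fread(file.path(outDir, "preference.csv"))
    cols <- ifelse(pref$cluster == "aversive_preferring", "magenta",
                   ifelse(pref$cluster == "reward_preferring", "cyan3",
                          "grey40"))
    plot(pref$r_reward, pref$r_aversive, col = cols, pch = 19,
         xlab = "reward response (dF/F)",
         ylab = "aversive response (dF/F)",
         main = "Valence preference (pre-conditioning)")
    abline(0, 1, lty = 3)
    for (cl in c("reward_preferring", "aversive_preferring")) {
      m <- pref[pref$cluster == cl, ]
      if (nrow(m))
        arrows(0, 0, mean(m$r_reward), mean(m$r_aversive), lwd = 2,
               col = if (cl == "reward_preferring") "cyan3" else "magenta")
    }
  }
  if (file.exists(file.path(outDir, "density.csv"))) {
    dens <- data.table::fread(file.path(outDir, "density.csv"))
    plot(dens$grid_deg, dens$density, type = "l", xlim = c(-45, 135),
         xlab = "polar angle (deg)", ylab = "probability density",
         main = "Preference-angle density")
  }
  if (file.exists(file.path(outDir, "course_amplitudes.csv"))) {
    camp <- data.table::fread(file.path(outDir, "course_amplitudes.csv"))
    agg <- aggregate(amplitude ~ phase + cluster + event_kind,
                     as.data.frame(camp), mean)
    phs <- unique(agg$phase)
    plot(NULL, xlim = c(1, length(phs)), ylim = range(agg$amplitude),
         xaxt = "n", xlab = "phase", ylab = "mean amplitude (dF/F)",
         main = "Phase course of CS/US amplitudes")
    axis(1, seq_along(phs), phs)
    i <- 0
    for (cl in unique(agg$cluster)) for (ek in unique(agg$event_kind)) {
      sub <- agg[agg$cluster == cl & agg$event_kind == ek, ]
      i <- i + 1
      lines(match(sub$phase, phs), sub$amplitude, col = i, type = "b")
    }
  }
  if (file.exists(file.path(outDir, "discrim.json"))) {
    dj <- jsonlite::fromJSON(file.path(outDir, "discrim.json"),
                             simplifyVector = TRUE)
    if (length(dj$per_day)) {
      acc <- dj$per_day$balanced_accuracy
      plot(dj$per_day$day, acc, type = "b", ylim = c(40, 100),
           xlab = "day", ylab = "balanced accuracy (%)",
           main = "Late-phase cue decoding (facial features)")
      abline(h = 50, lty = 3)
    }
  }
  lines <- c("# Pipeline report", "",
             sprintf("Generated from: %s", normalizePath(outDir)), "")
  if (length(missing))
    lines <- c(lines, "Missing tables (sections skipped):",
               paste0("- ", missing), "")
  if (file.exists(file.path(outDir, "contrast.csv"))) {
    ct <- data.table::fread(file.path(outDir, "contrast.csv"), sep = ",")
    lines <- c(lines, "## Correct vs incorrect contrast", "",
               if ("note" %in% names(ct))
                 paste("insufficient trials:", ct$note[1])
               else utils::capture.output(print(as.data.frame(ct))), "")
  }
  writeLines(lines, file.path(outDir, "summary.md"))
  invisible(pdfPath)
}
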