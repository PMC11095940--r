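# Session bundle reader/writer: one directory per session holding
# plain-text CSV arrays plus a JSON manifest. Doubles are serialised with
# 17 significant digits so that write -> read is bit-exact.

MANIFEST_VERSION <- 1L

writeNumericCsv <- function(m, path) {
  m <- as.matrix(m)
  dt <- data.table::as.data.table(
    lapply(seq_len(ncol(m)), function(j) fmtNum(m[, j])))
  data.table::setnames(dt, colnames(m) %||% sprintf("c%d", seq_len(ncol(m))))
  data.table::fwrite(dt, path, quote = FALSE, na = "NA")
}

readNumericCsv <- function(path, what) {
  if (!file.exists(path))
    stop("session container is missing dataset: ", basename(path),
         " (", what, ")")
  dt <- data.table::fread(path, colClasses = "character",
                          na.strings = "NA", header = TRUE)
  m <- vapply(dt, as.numeric, numeric(nrow(dt)))
  if (nrow(dt) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(dt)))
  if (nrow(dt) == 0L) m <- matrix(numeric(0), 0L, ncol(dt),
                                  dimnames = list(NULL, names(dt)))
  m
}

#' Write a SessionBundle to a CSV+JSON session directory
#'
#' Serialises every array of the bundle into an inspectable directory:
#' `manifest.json` (rates, dimensions, metadata), `timeline.csv`,
#' `fluor.csv` (frames x ROI), `shifts.csv`, `tongue.csv`, `speed.csv`
#' and, if facial features are present, `facial.csv`. Floating-point
#' values are stored at full 64-bit precision, so
#' `readBundle(writeBundle(b, p))` reproduces `b` bit-for-bit.
#'
#' @param bundle a validated [SessionBundle-class].
#' @param path directory to create.
#' @param overwrite overwrite an existing directory? Default `FALSE`.
#' @return invisibly, `path`.
#' @seealso [readBundle()]
#' @export
writeBundle <- function(bundle, path, overwrite = FALSE) {
  stopifnot(is(bundle, "SessionBundle"))
  validObject(bundle)
  if (file.exists(path) && !overwrite)
    stop("path already exists (use overwrite = TRUE): ", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  tl <- canonicalTimeline(bundle@timeline)
  tld <- data.frame(trial_id = tl$trial_id, condition = tl$condition,
                    cs_onset_s = fmtNum(tl$cs_onset_s),
                    cs_freq_hz = fmtNum(tl$cs_freq_hz),
                    us_onset_s = fmtNum(tl$us_onset_s),
                    day_index = tl$day_index, stringsAsFactors = FALSE)
  data.table::fwrite(tld, file.path(path, "timeline.csv"), quote = FALSE,
                     na = "NA")

  writeNumericCsv(t(bundle@fluor@values), file.path(path, "fluor.csv"))
  colnames(bundle@shifts) <- c("x_px", "y_px")
  writeNumericCsv(bundle@shifts, file.path(path, "shifts.csv"))
  writeNumericCsv(matrix(bundle@behavior@tongue, ncol = 1,
                         dimnames = list(NULL, "tongue")),
                  file.path(path, "tongue.csv"))
  writeNumericCsv(matrix(bundle@behavior@speed, ncol = 1,
                         dimnames = list(NULL, "speed")),
                  file.path(path, "speed.csv"))

  fac <- bundle@behavior@facial
  manifest <- list(
    format_version = MANIFEST_VERSION,
    fluor = list(fs_hz = bundle@fluor@fsHz, roi_ids = bundle@fluor@roiIds),
    shifts = list(pixel_size_um = bundle@pixelSizeUm),
    behavior = list(tongue_fs_hz = bundle@behavior@tongueFsHz,
                    speed_fs_hz = bundle@behavior@speedFsHz),
    meta = bundle@meta)
  if (!is.null(fac)) {
    manifest$facial <- list(dim = dim(fac),
                            times_s = bundle@behavior@facialTimesS)
    flat <- matrix(aperm(fac, c(2, 1, 3)), nrow = dim(fac)[1] * dim(fac)[2],
                   ncol = dim(fac)[3])
    colnames(flat) <- sprintf("f%04d", seq_len(ncol(flat)))
    writeNumericCsv(flat, file.path(path, "facial.csv"))
  }
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(path, "manifest.json"))
  invisible(path)
}

#' Read a SessionBundle from a session directory
#'
#' Inverse of [writeBundle()]. All invariants of the bundle are re-checked
#' on read; a missing file raises a schema error naming the dataset.
#'
#' @param path session directory written by [writeBundle()].
#' @return a validated [SessionBundle-class].
#' @export
readBundle <- function(path) {
  if (!dir.exists(path)) stop("no session directory at: ", path)
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("session container is missing dataset: manifest.json")
  manifest <- jsonlite::fromJSON(mf, simplifyVector = TRUE)

  tlf <- file.path(path, "timeline.csv")
  if (!file.exists(tlf))
    stop("session container is missing dataset: timeline.csv")
  tl <- data.table::fread(tlf, colClasses = "character", na.strings = "NA",
                          header = TRUE)
  tl <- if (nrow(tl) == 0L)
    data.frame(trial_id = integer(0), condition = character(0),
               cs_onset_s = numeric(0), cs_freq_hz = numeric(0),
               us_onset_s = numeric(0), day_index = integer(0))
  else
    data.frame(trial_id = as.integer(tl$trial_id),
               condition = as.character(tl$condition),
               cs_onset_s = as.numeric(tl$cs_onset_s),
               cs_freq_hz = as.numeric(tl$cs_freq_hz),
               us_onset_s = as.numeric(tl$us_onset_s),
               day_index = as.integer(tl$day_index),
               stringsAsFactors = FALSE)

  fl <- readNumericCsv(file.path(path, "fluor.csv"), "raw fluorescence")
  fluor <- fluorescenceMatrix(t(fl), manifest$fluor$fs_hz,
                              roiIds = manifest$fluor$roi_ids)
  shifts <- readNumericCsv(file.path(path, "shifts.csv"),
                           "registration shifts")
  tongue <- readNumericCsv(file.path(path, "tongue.csv"), "tongue trace")[, 1]
  speed <- readNumericCsv(file.path(path, "speed.csv"), "speed trace")[, 1]

  facial <- NULL; facialTimes <- numeric(0)
  if (!is.null(manifest$facial)) {
    d <- as.integer(manifest$facial$dim)
    flat <- readNumericCsv(file.path(path, "facial.csv"), "facial features")
    facial <- aperm(array(flat, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
    facialTimes <- as.numeric(manifest$facial$times_s)
  }

  meta <- manifest$meta
  if (!is.null(meta$day)) meta$day <- as.integer(meta$day)
  sessionBundle(timeline = tl, fluor = fluor, shifts = shifts,
                pixelSizeUm = manifest$shifts$pixel_size_um,
                behavior = behaviorTraces(tongue,
                                          manifest$behavior$tongue_fs_hz,
                                          speed,
                                          manifest$behavior$speed_fs_hz,
                                          facial, facialTimes),
                meta = meta)
}
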