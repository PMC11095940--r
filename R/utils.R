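# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so that a single seed fans out reproducibly.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed from a parent seed and a stage tag,
# kept below 2^31 (R integers are 32-bit).
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 69069 + h * 7919 + 1) %% 2147483629)
}

# Format doubles so that fread() recovers them bit-exactly (%.17g shortest
# sufficient representation); NA survives as the literal "NA".
fmtNum <- function(x) {
  s <- sprintf("%.17g", as.numeric(x))
  s[is.na(x)] <- NA_character_
  s
}

# Canonical column types for a timeline so that write -> read is identical.
canonicalTimeline <- function(tl) {
  tl <- as.data.frame(tl)[, TIMELINE_COLUMNS, drop = FALSE]
  tl$trial_id <- as.integer(tl$trial_id)
  tl$condition <- as.character(tl$condition)
  tl$cs_onset_s <- as.numeric(tl$cs_onset_s)
  tl$cs_freq_hz <- as.numeric(tl$cs_freq_hz)
  tl$us_onset_s <- as.numeric(tl$us_onset_s)
  tl$day_index <- as.integer(tl$day_index)
  rownames(tl) <- NULL
  tl
}

# Wrap angles in degrees to (-180, 180].
wrapDeg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Circular mean of angles in degrees (direction of the mean resultant).
circMeanDeg <- function(x) {
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) / pi * 180
}
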