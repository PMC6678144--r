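## The analysis core: burst detection with hysteresis, event grouping and
## tonic/phasic/mixed classification, heart-rate surge detection, episode
## coupling, and the bruxism index.

#' Detect supra-threshold EMG bursts
#'
#' A burst opens when the percent-MVC envelope rises strictly above
#' `burstThreshold` (10 %MVC) and closes when it falls below
#' `burstOffsetHysteresis * burstThreshold`; the hysteresis prevents
#' threshold-grazing amplitudes from chattering one burst into many.
#' Bursts shorter than `burstMinDur` are discarded and bursts separated by
#' less than `burstMergeGap` are merged.
#'
#' @param pctEnvelope an [EnvelopeSeries-class] in `%MVC`.
#' @param config a [ScoringConfig-class].
#' @return data.frame with columns `onset`, `offset` (s), `peak` (%MVC),
#'   `channel`; zero rows when nothing crosses.
#' @export
detectBursts <- function(pctEnvelope, config = scoringConfig()) {
  stopifnot(is(pctEnvelope, "EnvelopeSeries"))
  if (pctEnvelope@units != "pctMVC")
    stop("detectBursts expects a %MVC envelope (normalize first)")
  v <- pctEnvelope@values
  fs <- pctEnvelope@rate
  thrOn <- config@burstThreshold
  thrOff <- config@burstOffsetHysteresis * config@burstThreshold

  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak = numeric(0), channel = character(0),
                      stringsAsFactors = FALSE)
  up <- which(v > thrOn)
  if (!length(up)) return(empty)

  ## supra-threshold runs, each extended right until the envelope drops
  ## below the hysteresis level
  brk <- which(diff(up) != 1L)
  starts <- up[c(1L, brk + 1L)]
  ends <- up[c(brk, length(up))]
  belowIdx <- as.numeric(which(v < thrOff))
  pos <- findInterval(ends, belowIdx) + 1L
  ext <- ifelse(pos > length(belowIdx), length(v), belowIdx[pos] - 1L)
  on <- integer(0); off <- integer(0)
  lastOff <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] <= lastOff) next   # swallowed by the previous burst's tail
    on <- c(on, starts[i]); off <- c(off, ext[i])
    lastOff <- ext[i]
  }
  b <- data.frame(onset = (on - 1L) / fs, offset = off / fs)

  ## merge near-contiguous bursts
  if (nrow(b) > 1L) {
    keep <- rep(TRUE, nrow(b))
    for (i in 2:nrow(b)) {
      j <- max(which(keep[1:(i - 1L)]))
      if (b$onset[i] - b$offset[j] < config@burstMergeGap) {
        b$offset[j] <- max(b$offset[j], b$offset[i])
        keep[i] <- FALSE
      }
    }
    b <- b[keep, , drop = FALSE]
  }
  b <- b[b$offset - b$onset >= config@burstMinDur, , drop = FALSE]
  if (!nrow(b)) return(empty)
  b$peak <- vapply(seq_len(nrow(b)), function(i) {
    lo <- max(1L, round(b$onset[i] * fs) + 1L)
    hi <- min(length(v), round(b$offset[i] * fs))
    max(v[lo:hi])
  }, numeric(1))
  b$channel <- pctEnvelope@channel
  rownames(b) <- NULL
  b
}

#' Pool bilateral bursts
#'
#' Bursts are detected per channel on each channel's own percent-MVC
#' envelope, then combined. `union` (default, the most sensitive defensible
#' choice) merges overlapping or near-contiguous cross-channel bursts into
#' single intervals; `left`/`right` keep one side only.
#'
#' @param burstsList list of per-channel burst data.frames from
#'   [detectBursts()].
#' @param config a [ScoringConfig-class]; `emgPooling` selects the mode.
#' @return one time-sorted burst data.frame.
#' @export
poolBursts <- function(burstsList, config = scoringConfig()) {
  mode <- config@emgPooling
  if (mode == "left") {
    b <- burstsList[["EMG_LEFT"]]
    if (is.null(b)) stop("no EMG_LEFT bursts to pool")
    return(b)
  }
  if (mode == "right") {
    b <- burstsList[["EMG_RIGHT"]]
    if (is.null(b)) stop("no EMG_RIGHT bursts to pool")
    return(b)
  }
  b <- do.call(rbind, burstsList)
  if (is.null(b) || !nrow(b)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      peak = numeric(0), channel = character(0),
                      stringsAsFactors = FALSE))
  }
  b <- b[order(b$onset), , drop = FALSE]
  keep <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))[-1L]) {
    j <- max(which(keep[1:(i - 1L)]))
    if (b$onset[i] - b$offset[j] < config@burstMergeGap) {
      b$offset[j] <- max(b$offset[j], b$offset[i])
      b$peak[j] <- max(b$peak[j], b$peak[i])
      b$channel[j] <- if (b$channel[j] == b$channel[i]) b$channel[j]
                      else "EMG_BOTH"
      keep[i] <- FALSE
    }
  }
  b <- b[keep, , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Group bursts into masticatory events
#'
#' Maximal runs of bursts whose sub-threshold gaps are strictly shorter than
#' `eventGap` (3 s of quiescence, the conventional separation for rhythmic
#' masticatory muscle activity scoring) become one event.
#'
#' @param bursts time-sorted burst data.frame (pooled across channels).
#' @param config a [ScoringConfig-class].
#' @return data.frame with `onset`, `offset`, `nBursts`, list-column
#'   `bursts` (per-event burst tables) and `type = "unclassified"`
#'   placeholders (see [classifyEvents()]).
#' @export
groupEvents <- function(bursts, config = scoringConfig()) {
  if (!nrow(bursts)) {
    out <- data.frame(onset = numeric(0), offset = numeric(0),
                      nBursts = integer(0), type = character(0),
                      stringsAsFactors = FALSE)
    out$bursts <- list()
    return(out)
  }
  if (is.unsorted(bursts$onset)) bursts <- bursts[order(bursts$onset), ]
  gap <- c(Inf, bursts$onset[-1L] - bursts$offset[-nrow(bursts)])
  grp <- cumsum(gap >= config@eventGap)
  idx <- split(seq_len(nrow(bursts)), grp)
  out <- data.frame(
    onset = vapply(idx, function(i) bursts$onset[i[1L]], numeric(1)),
    offset = vapply(idx, function(i) max(bursts$offset[i]), numeric(1)),
    nBursts = lengths(idx),
    type = "unclassified",
    stringsAsFactors = FALSE
  )
  out$bursts <- lapply(idx, function(i) bursts[i, , drop = FALSE])
  rownames(out) <- NULL
  out
}

classifyOne <- function(durations, config) {
  tonic <- any(durations > config@tonicMinDur)
  phasic <- sum(durations >= config@phasicBurstBounds[1] &
                durations <= config@phasicBurstBounds[2]) >=
            config@phasicMinBursts
  if (tonic && phasic) "mixed"
  else if (tonic) "tonic"
  else if (phasic) "phasic"
  else "unclassified"
}

#' Classify masticatory events as tonic, phasic or mixed
#'
#' A tonic component is any burst sustained strictly longer than 2 s; a
#' phasic component is three or more rhythmic bursts each lasting 0.25-2 s
#' inclusive. Both components make the event mixed; neither leaves it
#' unclassified (a burst of exactly 2.000 s is phasic-eligible, not tonic).
#'
#' @param events event data.frame from [groupEvents()].
#' @param config a [ScoringConfig-class].
#' @return the events with the `type` column filled in.
#' @export
classifyEvents <- function(events, config = scoringConfig()) {
  if (!nrow(events)) return(events)
  events$type <- vapply(events$bursts, function(b)
    classifyOne(b$offset - b$onset, config), character(1))
  events
}

#' Detect heart-rate surges
#'
#' For each beat the baseline is the mean rate of the trailing
#' `hrBaselineBeats` RR intervals; a surge opens at the first interval whose
#' rate reaches `(1 + hrRise)` times that baseline and stays open over
#' consecutive qualifying intervals, with the baseline frozen while open.
#' The reported onset is the *start* of the first qualifying RR interval --
#' the beat at which the acceleration begins -- which is the time the 1-5 s
#' coupling lag is measured against.
#'
#' @param hrSeries a [HeartRateSeries-class].
#' @param config a [ScoringConfig-class].
#' @return numeric vector of surge onset times (s).
#' @export
detectHrSurges <- function(hrSeries, config = scoringConfig()) {
  stopifnot(is(hrSeries, "HeartRateSeries"))
  r <- hrSeries@rates
  bt <- hrSeries@beatTimes
  nb <- config@hrBaselineBeats
  if (length(r) < nb + 1L)
    stop("heart-rate series too short for the baseline window")
  cs <- cumsum(c(0, r))
  onsets <- numeric(0)
  inSurge <- FALSE
  baseline <- NA_real_
  for (k in (nb + 1L):length(r)) {
    if (!inSurge) baseline <- (cs[k] - cs[k - nb]) / nb
    if (r[k] >= (1 + config@hrRise) * baseline) {
      if (!inSurge) onsets <- c(onsets, bt[k])
      inSurge <- TRUE
    } else {
      inSurge <- FALSE
    }
  }
  onsets
}

#' Couple classified events to heart-rate surges
#'
#' An event with a definite type becomes a sleep-bruxism episode iff some
#' surge onset precedes its onset by a lag inside the closed `lagWindow`
#' (1-5 s): the micro-arousal cascade puts the cardiac activation first.
#' By default each surge licenses at most one episode (the first qualifying
#' event) and each event couples to at most one surge.
#'
#' @param events classified event data.frame ([classifyEvents()]).
#' @param surges surge onset times ([detectHrSurges()]).
#' @param config a [ScoringConfig-class].
#' @return data.frame with `onset`, `offset`, `type`, `surgeOnset`, `lag`.
#' @export
scoreSbEpisodes <- function(events, surges, config = scoringConfig()) {
  ev <- events[events$type != "unclassified", , drop = FALSE]
  out <- data.frame(onset = numeric(0), offset = numeric(0),
                    type = character(0), surgeOnset = numeric(0),
                    lag = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(ev) || !length(surges)) return(out)
  ev <- ev[order(ev$onset), , drop = FALSE]
  surges <- sort(surges)
  lo <- config@lagWindow[1]; hi <- config@lagWindow[2]
  taken <- rep(FALSE, nrow(ev))
  for (ts in surges) {
    cand <- which(!taken & ev$onset - ts >= lo & ev$onset - ts <= hi)
    if (!length(cand)) next
    if (config@oneToOneCoupling) cand <- cand[1L]
    out <- rbind(out, data.frame(
      onset = ev$onset[cand], offset = ev$offset[cand],
      type = ev$type[cand],
      surgeOnset = ts, lag = ev$onset[cand] - ts,
      stringsAsFactors = FALSE))
    taken[cand] <- TRUE
  }
  out <- out[!duplicated(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bruxism index
#'
#' Scored episodes per hour: `count * 3600 / scoredLength`. The denominator
#' is the scored night (examination length minus the calibration prologue);
#' true sleep length is unknowable without EEG.
#'
#' @param episodes episode data.frame ([scoreSbEpisodes()]) or an episode
#'   count.
#' @param scoredLength scored night length in seconds (> 0).
#' @return episodes per hour.
#' @export
bruxismIndex <- function(episodes, scoredLength) {
  if (length(scoredLength) != 1L || !is.finite(scoredLength) ||
      scoredLength <= 0)
    stop("scoredLength must be a single positive number of seconds")
  n <- if (is.data.frame(episodes)) nrow(episodes) else as.numeric(episodes)
  n * 3600 / scoredLength
}

#' Score one recording end to end
#'
#' Runs the full chain: per-channel envelope, MVC calibration and percent-MVC
#' normalization, burst detection, bilateral pooling, event grouping and
#' classification, R-peak detection and heart-rate series, surge detection,
#' episode coupling (events and surges clipped to the post-calibration span),
#' bruxism index and the diagnostic call.
#'
#' @param recording a [Recording-class].
#' @param config a [ScoringConfig-class].
#' @return a [SubjectSummary-class].
#' @export
summarizeSubject <- function(recording, config = scoringConfig()) {
  stopifnot(is(recording, "Recording"))
  emgLabs <- intersect(c("EMG_LEFT", "EMG_RIGHT"), channelLabels(recording))
  mvcs <- list()
  burstsList <- list()
  calEnd <- 0
  for (lab in emgLabs) {
    env <- emgEnvelope(channelSamples(recording, lab),
                       samplingRate(recording, lab),
                       rmsWindow = config@rmsWindow, channel = lab)
    mvc <- detectMvc(env, searchWindow = config@mvcSearchWindow)
    mvcs[[lab]] <- mvc
    calEnd <- max(calEnd, calibrationEnd(mvc))
    pct <- normalizeEnvelope(env, mvc)
    burstsList[[lab]] <- detectBursts(pct, config)
  }
  pooled <- poolBursts(burstsList, config)
  pooled <- pooled[pooled$onset >= calEnd, , drop = FALSE]
  events <- classifyEvents(groupEvents(pooled, config), config)

  beats <- detectRPeaks(channelSamples(recording, "ECG"),
                        samplingRate(recording, "ECG"))
  hr <- heartRateSeries(beats)
  surges <- detectHrSurges(hr, config)
  surges <- surges[surges >= calEnd]
  eps <- scoreSbEpisodes(events, surges, config)

  examLength <- duration(recording)
  scoredLength <- examLength - calEnd
  idx <- bruxismIndex(eps, scoredLength)
  counts <- table(factor(events$type,
                         levels = c("tonic", "phasic", "mixed",
                                    "unclassified")))
  nTon <- as.integer(counts[["tonic"]])
  nPha <- as.integer(counts[["phasic"]])
  nMix <- as.integer(counts[["mixed"]])
  new("SubjectSummary",
      subjectId = subjectId(recording),
      bruxismIndex = idx,
      meanHr = meanHeartRate(hr),
      nTotal = nTon + nPha + nMix, nTonic = nTon, nPhasic = nPha,
      nMixed = nMix,
      examLength = examLength, scoredLength = scoredLength,
      diagnosis = diagnose(idx, config@diagnosticCutoff),
      mvc = mvcs, events = events, episodes = eps)
}
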