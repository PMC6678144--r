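#' @import methods
NULL

CHANNEL_LABELS <- c("EMG_LEFT", "EMG_RIGHT", "ECG")

#' Multichannel overnight recording
#'
#' Container for a raw EMG/ECG night: one or two masseter surface-EMG channels
#' and exactly one single-lead ECG channel, each with its own sampling rate and
#' physical-unit (mV) samples. All times inside the package are seconds from
#' recording start; sample indices are 0-based when converted to times.
#'
#' @slot subjectId opaque subject identifier.
#' @slot channels named list; each element is `list(samples =, rate =)` with
#'   samples in mV and rate in Hz. Names are the canonical labels
#'   `EMG_LEFT`, `EMG_RIGHT`, `ECG`.
#' @slot startTime ISO-8601 timestamp string (informational only).
#' @slot duration examination length in seconds: the time between switching
#'   the device on and off.
#' @export
setClass("Recording",
  representation(
    subjectId = "character",
    channels  = "list",
    startTime = "character",
    duration  = "numeric"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0) {
    msg <- c(msg, "duration must be a single positive number")
  }
  labs <- names(object@channels)
  if (is.null(labs) || !all(labs %in% CHANNEL_LABELS)) {
    msg <- c(msg, sprintf("channel labels must be among %s",
                          paste(CHANNEL_LABELS, collapse = ", ")))
  } else {
    if (sum(labs == "ECG") != 1L)
      msg <- c(msg, "exactly one ECG channel required")
    nEmg <- sum(labs %in% c("EMG_LEFT", "EMG_RIGHT"))
    if (nEmg < 1L || nEmg > 2L)
      msg <- c(msg, "one or two EMG channels required")
    if (anyDuplicated(labs))
      msg <- c(msg, "duplicate channel labels")
    for (lab in labs) {
      ch <- object@channels[[lab]]
      if (!is.numeric(ch$rate) || length(ch$rate) != 1L || ch$rate <= 0) {
        msg <- c(msg, sprintf("%s: sampling rate must be positive", lab))
        next
      }
      if (length(msg) == 0 &&
          abs(length(ch$samples) - round(object@duration * ch$rate)) > 1) {
        msg <- c(msg, sprintf(
          "%s: sample count %d inconsistent with duration %g s at %g Hz",
          lab, length(ch$samples), object@duration, ch$rate))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param subjectId subject identifier string.
#' @param channels named list of `list(samples =, rate =)`; names among
#'   `EMG_LEFT`, `EMG_RIGHT`, `ECG`. Channel order is normalized to
#'   (EMG_LEFT, EMG_RIGHT, ECG).
#' @param duration recording length in seconds; defaults to the value implied
#'   by the first channel.
#' @param startTime informational start timestamp.
#' @return a [Recording-class] object.
#' @export
Recording <- function(subjectId, channels, duration = NULL,
                      startTime = "1970-01-01T00:00:00") {
  if (is.null(duration)) {
    ch <- channels[[1L]]
    duration <- length(ch$samples) / ch$rate
  }
  ord <- intersect(CHANNEL_LABELS, names(channels))
  new("Recording", subjectId = as.character(subjectId),
      channels = channels[ord], startTime = startTime,
      duration = as.numeric(duration))
}

#' Rectified-smoothed EMG amplitude series
#'
#' Moving-RMS envelope of one EMG channel, either in physical units (mV) or,
#' after calibration, in percent of the maximum voluntary clench (%MVC).
#'
#' @slot values non-negative envelope samples.
#' @slot rate sampling rate in Hz (same as the source channel).
#' @slot channel source channel label.
#' @slot units `"mV"` or `"pctMVC"`.
#' @export
setClass("EnvelopeSeries",
  representation(values = "numeric", rate = "numeric",
                 channel = "character", units = "character"),
  prototype(units = "mV")
)

setValidity("EnvelopeSeries", function(object) {
  msg <- character()
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "envelope values must be non-negative")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (!object@units %in% c("mV", "pctMVC"))
    msg <- c(msg, "units must be 'mV' or 'pctMVC'")
  if (length(msg)) msg else TRUE
})

#' Beat-by-beat heart-rate series
#'
#' Beats are events, not samples: the series keeps the detected R-peak times
#' and the instantaneous rate of each RR interval. The rate attached to
#' interval i is `60 / (beatTimes[i+1] - beatTimes[i])` bpm and covers the
#' interval that *starts* at `beatTimes[i]`.
#'
#' @slot beatTimes strictly increasing R-peak times in seconds.
#' @slot rates instantaneous rates in bpm, one per RR interval
#'   (`length(rates) == length(beatTimes) - 1`).
#' @export
setClass("HeartRateSeries",
  representation(beatTimes = "numeric", rates = "numeric"))

setValidity("HeartRateSeries", function(object) {
  msg <- character()
  if (length(object@beatTimes) >= 2L && any(diff(object@beatTimes) <= 0))
    msg <- c(msg, "beat times must be strictly increasing")
  if (length(object@rates) != max(0L, length(object@beatTimes) - 1L))
    msg <- c(msg, "length(rates) must equal length(beatTimes) - 1")
  if (any(object@rates <= 0))
    msg <- c(msg, "rates must be positive")
  if (length(msg)) msg else TRUE
})

#' Maximum-voluntary-clench calibration result
#'
#' @slot clenchWindows matrix with columns `onset`, `offset` (seconds), one
#'   row per located clench (up to three).
#' @slot perClenchPeak peak envelope (mV) of each clench.
#' @slot mvc the greatest per-clench peak; the normalization constant.
#' @slot calibrationEnd end of the calibration span (seconds); the scored
#'   night starts here.
#' @slot qualityRatio largest/smallest clench peak, a flag for sub-maximal
#'   clench effort (reported, never acted on).
#' @export
setClass("MvcResult",
  representation(clenchWindows = "matrix", perClenchPeak = "numeric",
                 mvc = "numeric", calibrationEnd = "numeric",
                 qualityRatio = "numeric"))

setValidity("MvcResult", function(object) {
  msg <- character()
  if (length(object@mvc) != 1L || object@mvc <= 0)
    msg <- c(msg, "mvc must be a single positive number")
  if (length(object@perClenchPeak) &&
      abs(object@mvc - max(object@perClenchPeak)) > 1e-9)
    msg <- c(msg, "mvc must equal the largest per-clench peak")
  if (length(msg)) msg else TRUE
})

#' Scoring rule set
#'
#' Every numeric rule of the episode-scoring protocol in one place. Defaults
#' implement the published device rules: an EMG burst counts when the
#' percent-MVC envelope exceeds 10 %MVC; tonic events are sustained bursts
#' strictly longer than 2 s; phasic events have three or more rhythmic bursts
#' of 0.25-2 s (inclusive bounds); an episode requires a >=20% heart-rate rise
#' whose onset precedes the EMG event onset by 1-5 s; the diagnostic cut-off
#' is strictly more than 2 episodes per hour.
#'
#' @slot burstThreshold burst opening threshold, %MVC.
#' @slot burstMinDur minimum burst duration, s.
#' @slot burstOffsetHysteresis burst closes below `hysteresis * threshold`.
#' @slot burstMergeGap bursts closer than this (s) are merged.
#' @slot eventGap sub-threshold quiescence (s) ending an event (strict <).
#' @slot tonicMinDur tonic component requires one burst longer than this
#'   (strict >), s.
#' @slot phasicBurstBounds inclusive duration bounds (s) for phasic bursts.
#' @slot phasicMinBursts minimum rhythmic burst count for a phasic component.
#' @slot hrRise fractional heart-rate rise defining a surge.
#' @slot hrBaselineBeats trailing beats used for the heart-rate baseline.
#' @slot lagWindow closed interval (s) of allowed surge-to-event onset lags.
#' @slot diagnosticCutoff episodes/h; diagnosis is positive strictly above.
#' @slot emgPooling how bilateral bursts combine: `union`, `left`, `right`.
#' @slot rmsWindow moving-RMS envelope window, s.
#' @slot mvcSearchWindow calibration search window from recording start, s.
#' @slot countUnclassified whether 1-2 short-burst activity unclassifiable as
#'   tonic/phasic/mixed is counted among contractions (default FALSE).
#' @slot oneToOneCoupling whether one surge may license at most one episode.
#' @export
setClass("ScoringConfig",
  representation(
    burstThreshold = "numeric", burstMinDur = "numeric",
    burstOffsetHysteresis = "numeric", burstMergeGap = "numeric",
    eventGap = "numeric", tonicMinDur = "numeric",
    phasicBurstBounds = "numeric", phasicMinBursts = "numeric",
    hrRise = "numeric", hrBaselineBeats = "numeric",
    lagWindow = "numeric", diagnosticCutoff = "numeric",
    emgPooling = "character", rmsWindow = "numeric",
    mvcSearchWindow = "numeric", countUnclassified = "logical",
    oneToOneCoupling = "logical"
  ),
  prototype(
    burstThreshold = 10, burstMinDur = 0.25,
    burstOffsetHysteresis = 0.8, burstMergeGap = 0.05,
    eventGap = 3, tonicMinDur = 2,
    phasicBurstBounds = c(0.25, 2), phasicMinBursts = 3,
    hrRise = 0.20, hrBaselineBeats = 10,
    lagWindow = c(1, 5), diagnosticCutoff = 2,
    emgPooling = "union", rmsWindow = 0.05,
    mvcSearchWindow = 60, countUnclassified = FALSE,
    oneToOneCoupling = TRUE
  )
)

setValidity("ScoringConfig", function(object) {
  msg <- character()
  pos <- c("burstThreshold", "burstMinDur", "burstOffsetHysteresis",
           "burstMergeGap", "eventGap", "tonicMinDur", "phasicMinBursts",
           "hrRise", "hrBaselineBeats", "diagnosticCutoff", "rmsWindow",
           "mvcSearchWindow")
  for (s in pos) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (length(object@lagWindow) != 2L ||
      object@lagWindow[1] >= object@lagWindow[2])
    msg <- c(msg, "lagWindow must be (low, high) with low < high")
  if (length(object@phasicBurstBounds) != 2L ||
      object@phasicBurstBounds[1] >= object@phasicBurstBounds[2])
    msg <- c(msg, "phasicBurstBounds must be (low, high) with low < high")
  if (length(msg) == 0 &&
      object@burstMinDur > object@phasicBurstBounds[1])
    msg <- c(msg, "burstMinDur must not exceed the phasic lower bound")
  if (!object@emgPooling %in% c("union", "left", "right"))
    msg <- c(msg, "emgPooling must be 'union', 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Construct a ScoringConfig
#'
#' @param ... slot overrides; see [ScoringConfig-class] for the rules and
#'   their defaults.
#' @return a validated [ScoringConfig-class].
#' @examples
#' cfg <- scoringConfig()
#' cfg@diagnosticCutoff
#' @export
scoringConfig <- function(...) new("ScoringConfig", ...)

#' Synthetic-night generator settings
#'
#' Defaults emulate the study conditions: a ~7 h night (25200 s), a
#' calibration prologue of three 3-s maximal clenches separated by 10 s rest,
#' a 59.6 bpm baseline heart rate, six planted coupled episodes per hour with
#' a tonic-heavy type mix, plus uncoupled confounder contractions and
#' surge-only micro-arousals at 4/h each. Heart-rate surges of +30% start
#' 1-5 s before their coupled event.
#'
#' @slot seed RNG seed; same seed gives bit-identical samples and truth.
#' @slot nightDuration night length, s.
#' @slot emgRate,ecgRate sampling rates, Hz.
#' @slot mvcAmplitude RMS amplitude (mV) of a maximal clench.
#' @slot noiseFloor resting EMG RMS amplitude, mV.
#' @slot baselineHr baseline heart rate, bpm.
#' @slot episodeRate planted coupled episodes per hour of scored night.
#' @slot typeMix probabilities over tonic/phasic/mixed (sums to 1).
#' @slot confounderRate uncoupled masseter contractions per hour.
#' @slot surgeOnlyRate heart-rate surges without any EMG event, per hour.
#' @slot surgeMagnitude fractional peak heart-rate rise of a planted surge.
#' @slot lagRange (low, high) seconds from surge onset to event onset.
#' @slot burstFraction planted burst amplitude as a fraction of mvcAmplitude.
#' @slot ampJitter multiplicative burst-amplitude jitter (+-fraction).
#' @slot rampDur burst onset/offset ramp, s.
#' @slot minSeparation quiescence (s) enforced between planted structures.
#' @export
setClass("GeneratorConfig",
  representation(
    seed = "numeric", nightDuration = "numeric",
    emgRate = "numeric", ecgRate = "numeric",
    mvcAmplitude = "numeric", noiseFloor = "numeric",
    baselineHr = "numeric", episodeRate = "numeric",
    typeMix = "numeric", confounderRate = "numeric",
    surgeOnlyRate = "numeric", surgeMagnitude = "numeric",
    lagRange = "numeric", burstFraction = "numeric",
    ampJitter = "numeric", rampDur = "numeric",
    minSeparation = "numeric"
  ),
  prototype(
    seed = 1, nightDuration = 25200,
    emgRate = 500, ecgRate = 250,
    mvcAmplitude = 1.0, noiseFloor = 0.02,
    baselineHr = 59.6, episodeRate = 6,
    typeMix = c(tonic = 0.60, phasic = 0.34, mixed = 0.06),
    confounderRate = 4, surgeOnlyRate = 4,
    surgeMagnitude = 0.30,
    lagRange = c(1, 5), burstFraction = 0.4,
    ampJitter = 0.2, rampDur = 0.05,
    minSeparation = 15
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (abs(sum(object@typeMix) - 1) > 1e-8)
    msg <- c(msg, "typeMix must sum to 1")
  if (!all(c("tonic", "phasic", "mixed") %in% names(object@typeMix)))
    msg <- c(msg, "typeMix needs tonic, phasic and mixed entries")
  if (any(c(object@episodeRate, object@confounderRate,
            object@surgeOnlyRate) < 0))
    msg <- c(msg, "event rates must be non-negative")
  if (length(object@lagRange) != 2L || object@lagRange[1] <= 0 ||
      object@lagRange[1] >= object@lagRange[2])
    msg <- c(msg, "lagRange must be 0 < low < high")
  if (object@nightDuration <= 0)
    msg <- c(msg, "nightDuration must be positive")
  if (object@emgRate <= 0 || object@ecgRate <= 0)
    msg <- c(msg, "sampling rates must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneratorConfig
#'
#' @param ... slot overrides; see [GeneratorConfig-class].
#' @return a validated [GeneratorConfig-class].
#' @export
generatorConfig <- function(...) new("GeneratorConfig", ...)

#' Planted ground truth of a synthetic night
#'
#' @slot events data.frame with columns `onset`, `offset`, `type`
#'   (tonic/phasic/mixed/confounder), `shape` (the burst layout actually
#'   planted), `coupled`, `surgeOnset`, `lag`, and list-column `bursts`
#'   (two-column onset/offset matrices).
#' @slot surges data.frame with `onset` (realized, beat-aligned),
#'   `peakFraction`, `kind` (coupled/surge_only).
#' @slot mvcWindows three-row onset/offset matrix of the calibration clenches.
#' @slot trueIndex planted coupled episodes per hour of scored night.
#' @slot calibrationEnd end of the calibration prologue, s.
#' @export
setClass("GroundTruth",
  representation(events = "data.frame", surges = "data.frame",
                 mvcWindows = "matrix", trueIndex = "numeric",
                 calibrationEnd = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  ev <- object@events
  if (nrow(ev) >= 2L) {
    if (is.unsorted(ev$onset)) msg <- c(msg, "events must be time-sorted")
    if (any(ev$onset[-1L] < ev$offset[-nrow(ev)]))
      msg <- c(msg, "events must be non-overlapping")
  }
  if (nrow(ev)) {
    cp <- ev[ev$coupled, , drop = FALSE]
    if (nrow(cp) && any(is.na(cp$surgeOnset)))
      msg <- c(msg, "coupled events must carry a surge onset")
  }
  if (length(msg)) msg else TRUE
})

#' Per-subject scoring summary
#'
#' The measured row of the device report: bruxism index, mean heart rate,
#' contraction counts by type, examination and scored lengths, plus the
#' detail tables the numbers were computed from.
#'
#' @slot subjectId subject identifier.
#' @slot bruxismIndex scored episodes per hour of scored night.
#' @slot meanHr arithmetic mean of beat-to-beat rates, bpm.
#' @slot nTotal,nTonic,nPhasic,nMixed contraction counts
#'   (`nTotal = nTonic + nPhasic + nMixed`).
#' @slot examLength recording duration, s.
#' @slot scoredLength examLength minus the calibration span, s.
#' @slot diagnosis `"positive"` or `"negative"` at the configured cut-off.
#' @slot mvc named list of [MvcResult-class], one per EMG channel.
#' @slot events data.frame of classified masticatory events.
#' @slot episodes data.frame of surge-coupled SB episodes.
#' @export
setClass("SubjectSummary",
  representation(subjectId = "character", bruxismIndex = "numeric",
                 meanHr = "numeric", nTotal = "numeric", nTonic = "numeric",
                 nPhasic = "numeric", nMixed = "numeric",
                 examLength = "numeric", scoredLength = "numeric",
                 diagnosis = "character", mvc = "list",
                 events = "data.frame", episodes = "data.frame"))

setValidity("SubjectSummary", function(object) {
  msg <- character()
  if (length(object@nTotal) == 1L &&
      object@nTotal != object@nTonic + object@nPhasic + object@nMixed)
    msg <- c(msg, "nTotal must equal nTonic + nPhasic + nMixed")
  if (length(object@bruxismIndex) == 1L && object@bruxismIndex < 0)
    msg <- c(msg, "bruxismIndex must be non-negative")
  if (length(msg)) msg else TRUE
})

#' 2x2 screening confusion table
#'
#' Device call against the clinical reference standard.
#'
#' @slot tp,fn,fp,tn non-negative cell counts; `tp + fn` is the number of
#'   clinical positives and `fp + tn` the number of clinical negatives.
#' @export
setClass("ConfusionTable",
  representation(tp = "numeric", fn = "numeric",
                 fp = "numeric", tn = "numeric"))

setValidity("ConfusionTable", function(object) {
  v <- c(object@tp, object@fn, object@fp, object@tn)
  if (length(v) != 4L || any(!is.finite(v)) || any(v < 0) ||
      any(v != round(v)))
    "cells must be non-negative integers" else TRUE
})

#' Screening accuracy of the device call
#'
#' @slot sensitivity percent of clinical positives called positive
#'   (NA when there are no clinical positives).
#' @slot specificity percent of clinical negatives called negative
#'   (NA when there are no clinical negatives).
#' @slot table the underlying [ConfusionTable-class].
#' @export
setClass("DiagnosticAccuracy",
  representation(sensitivity = "numeric", specificity = "numeric",
                 table = "ConfusionTable"))
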