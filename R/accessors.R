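#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("subjectId", "Recording", function(x) x@subjectId)

#' @rdname accessors
setMethod("subjectId", "SubjectSummary", function(x) x@subjectId)

#' @rdname accessors
setMethod("duration", "Recording", function(x) x@duration)

#' @rdname accessors
setMethod("channelLabels", "Recording", function(x) names(x@channels))

#' @rdname accessors
setMethod("channelSamples", "Recording", function(x, label) {
  ch <- x@channels[[label]]
  if (is.null(ch)) stop("no channel labelled '", label, "'")
  ch$samples
})

#' @rdname accessors
setMethod("samplingRate", "Recording", function(x, label) {
  ch <- x@channels[[label]]
  if (is.null(ch)) stop("no channel labelled '", label, "'")
  ch$rate
})

#' @rdname accessors
setMethod("beatTimes", "HeartRateSeries", function(x) x@beatTimes)

#' @rdname accessors
setMethod("beatRates", "HeartRateSeries", function(x) x@rates)

#' @rdname accessors
setMethod("mvcValue", "MvcResult", function(x) x@mvc)

#' @rdname accessors
setMethod("calibrationEnd", "MvcResult", function(x) x@calibrationEnd)

#' @rdname accessors
setMethod("calibrationEnd", "GroundTruth", function(x) x@calibrationEnd)

#' @rdname accessors
setMethod("truthEvents", "GroundTruth", function(x) x@events)

#' @rdname accessors
setMethod("truthSurges", "GroundTruth", function(x) x@surges)

#' @rdname accessors
setMethod("trueIndex", "GroundTruth", function(x) x@trueIndex)

#' @rdname accessors
setMethod("bruxismIndexOf", "SubjectSummary", function(x) x@bruxismIndex)

#' @rdname accessors
setMethod("episodes", "SubjectSummary", function(x) x@episodes)

#' @rdname accessors
setMethod("scoredEvents", "SubjectSummary", function(x) x@events)

#' Flatten a SubjectSummary to a one-row data.frame
#'
#' The row-unit of the cohort tables: index, mean heart rate, contraction
#' counts by type, lengths and the diagnosis call.
#'
#' @param x a [SubjectSummary-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @return a one-row data.frame.
#' @export
as.data.frame.SubjectSummary <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    subject_id = x@subjectId,
    bruxism_index = x@bruxismIndex,
    mean_hr = x@meanHr,
    n_total = x@nTotal, n_tonic = x@nTonic,
    n_phasic = x@nPhasic, n_mixed = x@nMixed,
    exam_length = x@examLength, scored_length = x@scoredLength,
    diagnosis = x@diagnosis,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s': %.1f s (%.2f h)\n",
              object@subjectId, object@duration, object@duration / 3600))
  for (lab in names(object@channels)) {
    ch <- object@channels[[lab]]
    cat(sprintf("  %-9s %g Hz, %d samples\n", lab, ch$rate,
                length(ch$samples)))
  }
})

setMethod("show", "EnvelopeSeries", function(object) {
  cat(sprintf("EnvelopeSeries [%s, %s]: %d samples at %g Hz\n",
              object@channel, object@units, length(object@values),
              object@rate))
})

setMethod("show", "HeartRateSeries", function(object) {
  n <- length(object@beatTimes)
  cat(sprintf("HeartRateSeries: %d beats", n))
  if (n >= 2L)
    cat(sprintf(", mean %.1f bpm over %.1f s",
                mean(object@rates), diff(range(object@beatTimes))))
  cat("\n")
})

setMethod("show", "MvcResult", function(object) {
  cat(sprintf(
    "MvcResult: %d clench(es), MVC = %.3g mV, calibration ends %.1f s, quality ratio %.2f\n",
    nrow(object@clenchWindows), object@mvc, object@calibrationEnd,
    object@qualityRatio))
})

setMethod("show", "GroundTruth", function(object) {
  ev <- object@events
  cat(sprintf(
    "GroundTruth: %d events (%d coupled), %d surges, true index %.2f /h\n",
    nrow(ev), sum(ev$coupled), nrow(object@surges), object@trueIndex))
})

setMethod("show", "ScoringConfig", function(object) {
  cat("ScoringConfig:\n")
  cat(sprintf("  burst  : > %g %%MVC, >= %g s, hysteresis %g\n",
              object@burstThreshold, object@burstMinDur,
              object@burstOffsetHysteresis))
  cat(sprintf("  events : gap < %g s; tonic > %g s; phasic >= %g bursts in [%g, %g] s\n",
              object@eventGap, object@tonicMinDur, object@phasicMinBursts,
              object@phasicBurstBounds[1], object@phasicBurstBounds[2]))
  cat(sprintf("  surge  : +%g%% over trailing %g-beat baseline; lag [%g, %g] s\n",
              100 * object@hrRise, object@hrBaselineBeats,
              object@lagWindow[1], object@lagWindow[2]))
  cat(sprintf("  cutoff : > %g episodes/h; pooling %s\n",
              object@diagnosticCutoff, object@emgPooling))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: %.2f h night, %g/h episodes (+%g/h confounders, +%g/h surge-only), HR %g bpm, seed %g\n",
    object@nightDuration / 3600, object@episodeRate, object@confounderRate,
    object@surgeOnlyRate, object@baselineHr, object@seed))
})

setMethod("show", "SubjectSummary", function(object) {
  cat(sprintf("SubjectSummary '%s' (%s)\n", object@subjectId,
              object@diagnosis))
  cat(sprintf("  bruxism index : %.2f episodes/h (%d episodes in %.2f h)\n",
              object@bruxismIndex, nrow(object@episodes),
              object@scoredLength / 3600))
  cat(sprintf("  contractions  : %d (tonic %d, phasic %d, mixed %d)\n",
              object@nTotal, object@nTonic, object@nPhasic, object@nMixed))
  cat(sprintf("  mean HR       : %.1f bpm; exam %.2f h\n",
              object@meanHr, object@examLength / 3600))
})

setMethod("show", "ConfusionTable", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(device = c("positive", "negative"),
                              clinical = c("positive", "negative")))
  print(m)
})

setMethod("show", "DiagnosticAccuracy", function(object) {
  cat(sprintf("DiagnosticAccuracy: sensitivity %.1f%%, specificity %.1f%%\n",
              object@sensitivity, object@specificity))
  show(object@table)
})
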