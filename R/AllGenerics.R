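#' @include AllClasses.R
NULL

#' Accessors for bruxscore objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object.
#' @param label a canonical channel label (`EMG_LEFT`, `EMG_RIGHT`, `ECG`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("channelSamples", function(x, label)
  standardGeneric("channelSamples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x, label) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))

#' @rdname accessors
#' @export
setGeneric("beatRates", function(x) standardGeneric("beatRates"))

#' @rdname accessors
#' @export
setGeneric("mvcValue", function(x) standardGeneric("mvcValue"))

#' @rdname accessors
#' @export
setGeneric("calibrationEnd", function(x) standardGeneric("calibrationEnd"))

#' @rdname accessors
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' @rdname accessors
#' @export
setGeneric("truthSurges", function(x) standardGeneric("truthSurges"))

#' @rdname accessors
#' @export
setGeneric("trueIndex", function(x) standardGeneric("trueIndex"))

#' @rdname accessors
#' @export
setGeneric("bruxismIndexOf", function(x) standardGeneric("bruxismIndexOf"))

#' @rdname accessors
#' @export
setGeneric("episodes", function(x) standardGeneric("episodes"))

#' @rdname accessors
#' @export
setGeneric("scoredEvents", function(x) standardGeneric("scoredEvents"))

#' Sensitivity and specificity of a screening table
#'
#' `sensitivity` is 100 * tp / (tp + fn); `specificity` is
#' 100 * tn / (tn + fp). Either is NA when its denominator is zero
#' (undefined margin).
#'
#' @param x a [ConfusionTable-class] or [DiagnosticAccuracy-class].
#' @return percent, or NA when undefined.
#' @name screening-accessors
NULL

#' @rdname screening-accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname screening-accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
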