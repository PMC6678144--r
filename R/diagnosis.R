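## Diagnostic cut-off and screening accuracy.

#' Diagnostic call from the bruxism index
#'
#' Positive iff the index is strictly greater than the cut-off (default:
#' more than 2 episodes per hour of sleep). Vectorized over indices.
#'
#' @param index bruxism index, episodes/h (non-negative).
#' @param cutoff episodes/h.
#' @return `"positive"` / `"negative"`, one per index.
#' @export
diagnose <- function(index, cutoff = 2) {
  if (any(!is.finite(index)) || any(index < 0))
    stop("index must be non-negative")
  ifelse(index > cutoff, "positive", "negative")
}

#' Cross-tabulate device calls against the clinical reference
#'
#' @param deviceCalls character vector of `"positive"`/`"negative"` device
#'   calls.
#' @param clinicalLabels equal-length reference labels, same coding.
#' @return a [ConfusionTable-class].
#' @export
confusionTable <- function(deviceCalls, clinicalLabels) {
  if (length(deviceCalls) != length(clinicalLabels))
    stop("deviceCalls and clinicalLabels must have equal length")
  ok <- c("positive", "negative")
  if (!all(deviceCalls %in% ok) || !all(clinicalLabels %in% ok))
    stop("labels must be 'positive' or 'negative'")
  new("ConfusionTable",
      tp = sum(deviceCalls == "positive" & clinicalLabels == "positive"),
      fn = sum(deviceCalls == "negative" & clinicalLabels == "positive"),
      fp = sum(deviceCalls == "positive" & clinicalLabels == "negative"),
      tn = sum(deviceCalls == "negative" & clinicalLabels == "negative"))
}

#' @rdname screening-accessors
setMethod("sensitivity", "ConfusionTable", function(x) {
  d <- x@tp + x@fn
  if (d == 0) NA_real_ else 100 * x@tp / d
})

#' @rdname screening-accessors
setMethod("specificity", "ConfusionTable", function(x) {
  d <- x@tn + x@fp
  if (d == 0) NA_real_ else 100 * x@tn / d
})

#' @rdname screening-accessors
setMethod("sensitivity", "DiagnosticAccuracy", function(x) x@sensitivity)

#' @rdname screening-accessors
setMethod("specificity", "DiagnosticAccuracy", function(x) x@specificity)

#' Screening accuracy from a confusion table
#'
#' @param table a [ConfusionTable-class].
#' @return a [DiagnosticAccuracy-class]; an undefined margin yields NA for
#'   the corresponding rate.
#' @export
diagnosticAccuracy <- function(table) {
  stopifnot(is(table, "ConfusionTable"))
  new("DiagnosticAccuracy",
      sensitivity = sensitivity(table),
      specificity = specificity(table),
      table = table)
}

#' Percent of subjects exceeding the diagnostic cut-off
#'
#' @param indices bruxism indices of one group (non-empty).
#' @param cutoff episodes/h (strict >).
#' @return percent of the group above the cut-off.
#' @export
cutoffMatchRate <- function(indices, cutoff = 2) {
  if (!length(indices)) stop("empty group")
  100 * sum(indices > cutoff) / length(indices)
}
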