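## MVC calibration: locate the three voluntary clenches at the start of the
## night and derive the percent-MVC normalization constant.

#' Locate the maximum-voluntary-clench prologue
#'
#' The protocol opens with three maximal clenches of 3 s separated by 10 s of
#' rest. Within the search window the envelope is thresholded at five times
#' its median (an adaptive supra-noise level), contiguous supra-threshold
#' segments of 1-6 s are kept as clench candidates, and the three with the
#' largest peak envelope win. The normalization constant is the greatest
#' per-clench peak. Fewer than three clenches is tolerated with a warning
#' (unsupervised home use); none is a hard error.
#'
#' @param envelope an [EnvelopeSeries-class] in mV.
#' @param searchWindow seconds of recording searched from the start. The
#'   protocol needs 29 s; the default leaves slack for patient delay.
#' @param postPad seconds appended after the last clench offset to form the
#'   calibration span excluded from scoring.
#' @return an [MvcResult-class].
#' @export
detectMvc <- function(envelope, searchWindow = 60, postPad = 5) {
  stopifnot(is(envelope, "EnvelopeSeries"))
  fs <- envelope@rate
  n <- min(length(envelope@values), round(searchWindow * fs))
  if (n < fs) stop("envelope does not cover the calibration search window")
  v <- envelope@values[seq_len(n)]
  thr <- 5 * stats::median(v)
  above <- v > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(seg)) {
    seg$dur <- (seg$end - seg$start + 1L) / fs
    seg <- seg[seg$dur >= 1 & seg$dur <= 6, , drop = FALSE]
  }
  if (!nrow(seg)) stop("no MVC calibration detected")
  seg$peak <- vapply(seq_len(nrow(seg)),
                     function(i) max(v[seg$start[i]:seg$end[i]]), numeric(1))
  seg <- seg[order(seg$peak, decreasing = TRUE), , drop = FALSE]
  seg <- utils::head(seg, 3L)
  seg <- seg[order(seg$start), , drop = FALSE]
  if (nrow(seg) < 3L)
    warning(sprintf("only %d clench(es) found in calibration window",
                    nrow(seg)))
  windows <- cbind(onset = (seg$start - 1L) / fs, offset = seg$end / fs)
  mvc <- max(seg$peak)
  new("MvcResult",
      clenchWindows = windows,
      perClenchPeak = seg$peak,
      mvc = mvc,
      calibrationEnd = max(windows[, "offset"]) + postPad,
      qualityRatio = max(seg$peak) / min(seg$peak))
}

#' Normalize an envelope to percent MVC
#'
#' `values' = 100 * values / mvc`. Scoring thresholds are expressed on this
#' scale, so multiplying a recording's EMG gain by any positive constant
#' leaves all downstream results unchanged.
#'
#' @param envelope an [EnvelopeSeries-class] in mV.
#' @param mvc normalization constant in mV (from [detectMvc()]), or an
#'   [MvcResult-class].
#' @return an [EnvelopeSeries-class] in `%MVC`.
#' @export
normalizeEnvelope <- function(envelope, mvc) {
  stopifnot(is(envelope, "EnvelopeSeries"))
  if (is(mvc, "MvcResult")) mvc <- mvcValue(mvc)
  if (!is.numeric(mvc) || length(mvc) != 1L || mvc <= 0)
    stop("mvc must be a single positive number")
  new("EnvelopeSeries", values = 100 * envelope@values / mvc,
      rate = envelope@rate, channel = envelope@channel, units = "pctMVC")
}
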