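## Signal conditioning: moving-RMS EMG envelope and beat-domain heart rate.

runningMean <- function(x, w) {
  ## centered moving average via cumulative sums, edges use the available
  ## part of the window
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving-RMS EMG envelope
#'
#' Rectified-smoothed amplitude of a raw EMG channel: the signal is
#' mean-subtracted, squared, averaged over a centered window and square-
#' rooted. The default 50 ms window resolves the 0.25 s lower bound of
#' phasic bursts with modest edge smearing while suppressing the carrier.
#'
#' @param samples raw EMG samples (mV).
#' @param fs sampling rate, Hz. Below 200 Hz a warning is issued (the
#'   80-250 Hz EMG band is then poorly sampled).
#' @param rmsWindow window length, s.
#' @param channel label carried on the result.
#' @return an [EnvelopeSeries-class] in mV, same length and rate as the
#'   input.
#' @export
emgEnvelope <- function(samples, fs, rmsWindow = 0.05,
                        channel = "EMG_LEFT") {
  w <- round(rmsWindow * fs)
  if (w < 2L) stop("RMS window shorter than 2 samples")
  if (fs < 200) warning("EMG sampling rate below 200 Hz; envelope may alias")
  x <- samples - mean(samples)
  env <- sqrt(pmax(runningMean(x * x, w), 0))
  new("EnvelopeSeries", values = env, rate = fs, channel = channel,
      units = "mV")
}

#' Detect R peaks in a single-lead ECG
#'
#' Adaptive-threshold integration pipeline in the Pan-Tompkins style:
#' band-emphasis filtering (5-15 Hz), differentiation, squaring (polarity
#' invariant), 150 ms moving-window integration, then peak picking with
#' running signal/noise threshold estimates and a 250 ms refractory period.
#' Each accepted peak is refined to the largest squared deflection of the
#' band-passed signal within +-100 ms.
#'
#' @param samples ECG samples (mV).
#' @param fs sampling rate, Hz.
#' @param refractory minimum beat spacing, s.
#' @return numeric vector of R-peak times (s from signal start).
#' @export
detectRPeaks <- function(samples, fs, refractory = 0.25) {
  if (length(samples) < 10 * fs)
    stop("need at least 10 s of ECG signal")
  ny <- fs / 2
  bp <- signal::butter(2, c(5, min(15, 0.9 * ny)) / ny, type = "pass")
  xf <- signal::filtfilt(bp, samples - mean(samples))
  d <- c(0, diff(xf))
  sq <- d * d
  integ <- runningMean(sq, max(3L, round(0.150 * fs)))

  ## candidate local maxima of the integrated signal
  n <- length(integ)
  isPk <- which(integ[2:(n - 1L)] > integ[1:(n - 2L)] &
                integ[2:(n - 1L)] >= integ[3:n]) + 1L
  if (!length(isPk)) stop("unusable ECG: no peaks found")

  init <- integ[seq_len(min(n, round(2 * fs)))]
  spki <- max(init) * 0.8
  npki <- mean(init) * 0.5
  refr <- round(refractory * fs)
  keep <- integer(0)
  lastAccept <- -Inf
  for (p in isPk) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[p] >= thr) {
      if (p - lastAccept >= refr) {
        keep <- c(keep, p)
        lastAccept <- p
        spki <- 0.125 * integ[p] + 0.875 * spki
      } else if (integ[p] > integ[lastAccept]) {
        ## taller peak inside the refractory window supersedes
        keep[length(keep)] <- p
        lastAccept <- p
        spki <- 0.125 * integ[p] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
    }
  }
  if (!length(keep)) stop("unusable ECG: no peaks found")

  ## refine to the sharpest band-passed deflection near each candidate
  half <- round(0.100 * fs)
  xf2 <- xf * xf
  half <- as.integer(half)
  refined <- vapply(keep, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(xf2[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  ## enforce refractory once more after refinement
  if (length(refined) > 1L) {
    out <- refined[1L]
    for (p in refined[-1L]) {
      if (p - out[length(out)] >= refr) out <- c(out, p)
    }
    refined <- out
  }
  (refined - 1L) / fs
}

#' Beat-by-beat heart-rate series from R-peak times
#'
#' The rate attached to interval i is `60 / (beatTimes[i+1] - beatTimes[i])`
#' bpm; it covers the RR interval that starts at `beatTimes[i]`.
#'
#' @param beatTimes strictly increasing R-peak times, s.
#' @return a [HeartRateSeries-class].
#' @export
heartRateSeries <- function(beatTimes) {
  if (length(beatTimes) < 2L) stop("need at least 2 beats")
  if (any(diff(beatTimes) <= 0)) stop("beat times must be strictly increasing")
  new("HeartRateSeries", beatTimes = as.numeric(beatTimes),
      rates = 60 / diff(beatTimes))
}

#' Mean heart rate of a series
#'
#' Arithmetic mean of the beat-to-beat rates, in bpm.
#'
#' @param series a [HeartRateSeries-class].
#' @return mean rate, bpm.
#' @export
meanHeartRate <- function(series) {
  stopifnot(is(series, "HeartRateSeries"))
  if (!length(series@rates)) stop("empty heart-rate series")
  mean(series@rates)
}
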