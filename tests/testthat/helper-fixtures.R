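# Shared fixtures built in code.

# small equal-rate recording for IO tests: sines + noise, 10 s at 50 Hz
tinyRecording <- function(seed = 1, fs = 50, secs = 10) {
  set.seed(seed)
  t <- (0:(fs * secs - 1)) / fs
  Recording("tiny", list(
    EMG_LEFT = list(samples = 0.8 * sin(2 * pi * 7 * t), rate = fs),
    EMG_RIGHT = list(samples = stats::rnorm(length(t), 0, 0.3), rate = fs),
    ECG = list(samples = cos(2 * pi * 3 * t), rate = fs)
  ))
}

# short synthetic night; heavier rates than the defaults so a few hundred
# seconds carry enough structure to test against
shortNightConfig <- function(seed = 1, nightDuration = 900,
                             episodeRate = 12, confounderRate = 6,
                             surgeOnlyRate = 6, ...) {
  generatorConfig(seed = seed, nightDuration = nightDuration,
                  episodeRate = episodeRate, confounderRate = confounderRate,
                  surgeOnlyRate = surgeOnlyRate, ...)
}

# envelope series straight from a piecewise-constant %MVC profile
pctEnvelope <- function(values, rate = 100, channel = "EMG_LEFT") {
  new("EnvelopeSeries", values = values, rate = rate, channel = channel,
      units = "pctMVC")
}

# %MVC profile builder: list of (onset, offset, level) on a flat floor
pctProfile <- function(dur, segments, floor = 2, rate = 100) {
  v <- rep(floor, round(dur * rate))
  for (s in segments) {
    i0 <- floor(s[1] * rate) + 1
    i1 <- min(length(v), ceiling(s[2] * rate))
    v[i0:i1] <- s[3]
  }
  pctEnvelope(v, rate)
}

# beat times with one or more RR intervals overridden
beatTrain <- function(n = 40, rr = 1, overrides = list()) {
  rrs <- rep(rr, n - 1)
  for (o in overrides) rrs[o[1]] <- o[2]
  cumsum(c(0, rrs))
}

manifestDf <- function(nStudy = 2, nControl = 2) {
  n <- nStudy + nControl
  data.frame(
    subject_id = sprintf("P%02d", seq_len(n)),
    group = rep(c("study", "control"), c(nStudy, nControl)),
    sex = rep(c("female", "male"), length.out = n),
    age = 30 + seq_len(n),
    twi = rep(c(1L, 0L), c(nStudy, nControl)),
    symptoms_present = rep(c(TRUE, FALSE), c(nStudy, nControl)),
    self_report_positive = rep(c(TRUE, FALSE), c(nStudy, nControl)),
    recording_path = sprintf("P%02d.edf", seq_len(n)),
    stringsAsFactors = FALSE
  )
}
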