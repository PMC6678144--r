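## Synthetic overnight EMG/ECG generator with planted ground truth.
##
## The generated night reproduces the recording protocol: a calibration
## prologue of three 3-s maximal clenches separated by 10 s of rest, then
## hours of sleep-phase signal containing tonic/phasic/mixed masseter events
## whose coupled heart-rate surges start 1-5 s before the EMG onset, plus
## confounder contractions without a cardiac signature and surge-only
## micro-arousals without any EMG event.

## relative burst layouts (onset/offset from structure start)
layoutTonic <- function() {
  dur <- stats::runif(1, 2.5, 6)
  matrix(c(0, dur), 1L, 2L, dimnames = list(NULL, c("onset", "offset")))
}

layoutPhasic <- function(nMin = 3L, nMax = 6L) {
  nb <- sample(nMin:nMax, 1L)
  durs <- stats::runif(nb, 0.4, 0.8)
  gaps <- stats::runif(nb, 0.3, 0.6)   # gap before each burst (first unused)
  on <- cumsum(c(0, durs[-nb] + gaps[-1L]))
  cbind(onset = on, offset = on + durs)
}

layoutMixed <- function() {
  tonic <- matrix(c(0, stats::runif(1, 2.5, 4)), 1L, 2L)
  gap <- stats::runif(1, 0.5, 1.5)
  ph <- layoutPhasic(3L, 4L)
  ph <- ph + tonic[2L] + gap
  rbind(tonic, ph)
}

drawLayout <- function(shape) {
  switch(shape,
         tonic = layoutTonic(),
         phasic = layoutPhasic(),
         mixed = layoutMixed(),
         stop("unknown shape ", shape))
}

## trapezoidal amplitude profile: amp plateau with rampDur linear edges;
## returned as (indices, values) so the caller can patch the envelope in
## place without copying the full-night vector
burstProfile <- function(n, on, off, amp, rampDur, fs, floorAmp) {
  i0 <- max(1L, floor(on * fs) + 1L)
  i1 <- min(n, ceiling(off * fs))
  if (i1 <= i0) return(NULL)
  nr <- max(1L, round(rampDur * fs))
  len <- i1 - i0 + 1L
  prof <- rep(amp, len)
  r <- seq_len(min(nr, len))
  ramp <- floorAmp + (amp - floorAmp) * r / nr
  prof[r] <- pmin(prof[r], ramp)
  prof[len - r + 1L] <- pmin(prof[len - r + 1L], ramp)
  list(seg = i0:i1, prof = prof)
}

## band-limited (80 Hz .. ~0.48 fs) noise carrier, amplitude-stabilized so
## its short-time RMS is ~1 everywhere: the planted envelope then IS the
## realized envelope, which keeps amplitude ground truth sharp
emgCarrier <- function(n, fs) {
  x <- stats::rnorm(n)
  hi <- min(240, 0.48 * fs)
  b <- signal::fir1(100, c(80, hi) / (fs / 2), type = "pass")
  x <- signal::fftfilt(b, x, n = 2^14)   # overlap-add; O(n log blocksize)
  x <- x / sqrt(mean(x * x))
  local <- sqrt(pmax(runningMean(x * x, round(0.05 * fs)), 1e-6))
  x / local
}

#' Generate one synthetic night with ground truth
#'
#' Produces a [Recording-class] (two EMG channels and one ECG channel) and
#' the [GroundTruth-class] describing everything planted. EMG is
#' band-limited noise amplitude-modulated by a planted envelope: the
#' resting floor outside bursts, clench bursts at the MVC amplitude in the
#' prologue, and event bursts at `burstFraction` of MVC (with amplitude
#' jitter and 50 ms ramps) during sleep. ECG is a 40 ms biphasic QRS
#' impulse train whose RR intervals follow the baseline heart rate with
#' mild (~0.8%) multiplicative jitter; a planted surge raises the rate to
#' `(1 + surgeMagnitude)` times baseline, holding ~1 s and decaying over
#' ~10 s.
#'
#' Planted structures are drawn from independent Poisson processes (coupled
#' events, confounders, surge-only arousals), time-sorted and thinned to
#' `minSeparation` seconds of quiescence between structures so that planted
#' counts survive the 3 s event-grouping rule. Surge onsets are realized at
#' a beat boundary (autonomic input takes effect at the next sinus beat) and
#' planted lags are kept strictly inside the lag window so beat quantization
#' cannot push a true lag across the window boundary; the truth records the
#' realized onset and lag.
#'
#' @param config a [GeneratorConfig-class]; same config (and seed) twice
#'   gives bit-identical samples and truth.
#' @param subjectId id stored on the recording.
#' @return `list(recording =, truth =)`.
#' @export
generateRecording <- function(config = generatorConfig(),
                              subjectId = "synthetic") {
  validObject(config)
  set.seed(config@seed)
  night <- config@nightDuration
  fsE <- config@emgRate; fsC <- config@ecgRate
  A <- config@mvcAmplitude
  floorAmp <- config@noiseFloor
  rrNom <- 60 / config@baselineHr

  clenchOn <- c(2, 15, 28); clenchDur <- 3
  calEnd <- clenchOn[3] + clenchDur + 5
  if (night < calEnd + 30)
    stop("night too short to fit the calibration prologue")

  ## ---- plant structures -------------------------------------------------
  hours <- (night - calEnd) / 3600
  spanLo <- calEnd + 20
  spanHi <- night - 40
  kinds <- c("coupled", "confounder", "surge_only")
  rates <- c(config@episodeRate, config@confounderRate, config@surgeOnlyRate)
  cand <- do.call(rbind, lapply(seq_along(kinds), function(i) {
    k <- stats::rpois(1, rates[i] * hours)
    if (!k) return(NULL)
    data.frame(anchor = stats::runif(k, spanLo, spanHi), kind = kinds[i],
               stringsAsFactors = FALSE)
  }))
  events <- data.frame(onset = numeric(0), offset = numeric(0),
                       type = character(0), shape = character(0),
                       coupled = logical(0), surgeOnset = NA_real_[0],
                       lag = numeric(0), stringsAsFactors = FALSE)
  events$bursts <- list()
  surgePlan <- data.frame(te = numeric(0), kind = character(0))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$anchor), , drop = FALSE]
    lastEnd <- calEnd
    mix <- config@typeMix[c("tonic", "phasic", "mixed")]
    for (i in seq_len(nrow(cand))) {
      t0 <- cand$anchor[i]
      if (t0 - lastEnd < config@minSeparation) next
      kind <- cand$kind[i]
      if (kind == "surge_only") {
        surgePlan <- rbind(surgePlan,
                           data.frame(te = t0, kind = "surge_only"))
        lastEnd <- t0
        next
      }
      shape <- sample(names(mix), 1L, prob = mix)
      rel <- drawLayout(shape)
      if (t0 + max(rel) > spanHi) next
      abs <- rel + t0
      colnames(abs) <- c("onset", "offset")
      row <- data.frame(onset = t0, offset = t0 + max(rel),
                        type = if (kind == "coupled") shape else "confounder",
                        shape = shape,
                        coupled = kind == "coupled",
                        surgeOnset = NA_real_, lag = NA_real_,
                        stringsAsFactors = FALSE)
      row$bursts <- list(abs)
      events <- rbind(events, row)
      if (kind == "coupled")
        surgePlan <- rbind(surgePlan, data.frame(te = t0, kind = "coupled"))
      lastEnd <- t0 + max(rel)
    }
  }

  ## ---- EMG channels -----------------------------------------------------
  nE <- round(night * fsE)
  env <- rep(floorAmp, nE)
  clenchAmp <- A * stats::runif(3, 0.88, 1.0)
  clenchAmp[sample(3, 1L)] <- A
  for (i in 1:3) {
    p <- burstProfile(nE, clenchOn[i], clenchOn[i] + clenchDur,
                      clenchAmp[i], config@rampDur, fsE, floorAmp)
    if (!is.null(p)) env[p$seg] <- pmax(env[p$seg], p$prof)
  }
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      b <- events$bursts[[i]]
      for (j in seq_len(nrow(b))) {
        amp <- config@burstFraction * A *
          (1 + stats::runif(1, -config@ampJitter, config@ampJitter))
        p <- burstProfile(nE, b[j, 1L], b[j, 2L], amp,
                          config@rampDur, fsE, floorAmp)
        if (!is.null(p)) env[p$seg] <- pmax(env[p$seg], p$prof)
      }
    }
  }
  emgL <- env * emgCarrier(nE, fsE)
  gainR <- 0.92   # mild physiological left/right asymmetry
  envR <- floorAmp + (env - floorAmp) * gainR
  emgR <- envR * emgCarrier(nE, fsE)

  ## ---- ECG with beat-aligned surges -------------------------------------
  ## trigger time: first beat at/after it realizes the surge onset; the
  ## guard keeps the realized lag strictly inside the lag window even after
  ## beat quantization
  guard <- 1.3 + rrNom * 1.05
  hiLag <- config@lagRange[2] - 0.1
  if (nrow(surgePlan)) {
    lags <- stats::runif(nrow(surgePlan), config@lagRange[1],
                         config@lagRange[2])
    surgePlan$trigger <- surgePlan$te - pmax(pmin(lags, hiLag), guard)
    surgePlan <- surgePlan[order(surgePlan$trigger), , drop = FALSE]
    surgePlan$realized <- NA_real_
  }
  holdDur <- 1.0; tau <- 1.5
  maxBeats <- ceiling(night / rrNom * (1 + config@surgeMagnitude) + 10)
  beats <- numeric(maxBeats)
  nb <- 0L
  t <- stats::runif(1, 0.1, 0.1 + rrNom)
  sIdx <- 1L
  activeOnset <- -Inf
  while (t < night) {
    nb <- nb + 1L
    beats[nb] <- t
    if (sIdx <= nrow(surgePlan) && t >= surgePlan$trigger[sIdx]) {
      surgePlan$realized[sIdx] <- t
      activeOnset <- t
      sIdx <- sIdx + 1L
    }
    dt <- t - activeOnset
    m <- if (dt < holdDur) config@surgeMagnitude
         else config@surgeMagnitude * exp(-(dt - holdDur) / tau)
    if (m < 0.01) m <- 0
    hrInst <- config@baselineHr * (1 + m) * exp(stats::rnorm(1, 0, 0.008))
    t <- t + 60 / hrInst
  }
  beats <- beats[seq_len(nb)]

  nC <- round(night * fsC)
  ecg <- stats::rnorm(nC, 0, 0.01)
  ## 40 ms biphasic pulse with a dominant R lobe so peak refinement locks
  ## onto one deflection
  tlen <- max(4L, round(0.040 * fsC))
  nR <- ceiling(0.6 * tlen)
  template <- c(sin(pi * seq_len(nR) / nR),
                -0.35 * sin(pi * seq_len(tlen - nR) / (tlen - nR)))
  bi <- round(beats * fsC) + 1L
  for (k in seq_along(bi)) {
    i0 <- bi[k]
    i1 <- min(nC, i0 + tlen - 1L)
    if (i0 < 1L || i0 > nC) next
    ecg[i0:i1] <- ecg[i0:i1] + template[seq_len(i1 - i0 + 1L)]
  }

  ## ---- truth ------------------------------------------------------------
  if (nrow(surgePlan)) {
    surgePlan <- surgePlan[order(surgePlan$te), , drop = FALSE]
    if (nrow(events)) {
      cp <- surgePlan$kind == "coupled"
      m <- match(surgePlan$te[cp], events$onset)
      events$surgeOnset[m] <- surgePlan$realized[cp]
      events$lag[m] <- events$onset[m] - events$surgeOnset[m]
    }
  }
  surges <- data.frame(onset = surgePlan$realized,
                       peakFraction = rep(config@surgeMagnitude,
                                          nrow(surgePlan)),
                       kind = surgePlan$kind, stringsAsFactors = FALSE)
  surges <- surges[!is.na(surges$onset), , drop = FALSE]
  rownames(surges) <- NULL
  mvcW <- cbind(onset = clenchOn, offset = clenchOn + clenchDur)
  truth <- new("GroundTruth",
               events = events, surges = surges, mvcWindows = mvcW,
               trueIndex = sum(events$coupled) / hours,
               calibrationEnd = calEnd)

  rec <- Recording(subjectId, list(
    EMG_LEFT = list(samples = emgL, rate = fsE),
    EMG_RIGHT = list(samples = emgR, rate = fsE),
    ECG = list(samples = ecg, rate = fsC)
  ), duration = night)
  list(recording = rec, truth = truth)
}

truncNorm <- function(n, mean, sd, lower = 0) {
  if (sd < 0) stop("sd must be non-negative")
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower) break
    }
    out[i] <- x
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws each subject's planted episode rate from their group's truncated
#' normal distribution (defaults: study mean 6.04 SD 2.55, control mean
#' 1.35 SD 0.86, truncated at 0 -- the published group-level index
#' distributions) and generates one night per subject. With `dir` set,
#' recordings (EDF), truth sidecars (`<id>.truth.json`) and the manifest
#' CSV are written there and recordings are not kept in memory; otherwise
#' everything is returned in lists (use short nights).
#'
#' @param nStudy,nControl group sizes (>= 0).
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @param config base [GeneratorConfig-class]; each subject's
#'   `episodeRate` and `seed` are overridden.
#' @param studyIndexDist,controlIndexDist `list(mean =, sd =)` of the
#'   truncated-normal planted-rate distributions.
#' @param dir output directory, or NULL to keep objects in memory.
#' @return `list(manifest =, recordings =, truths =)`; `recordings` is NULL
#'   when `dir` is given.
#' @export
generateCohort <- function(nStudy, nControl, seed = 1,
                           config = generatorConfig(),
                           studyIndexDist = list(mean = 6.04, sd = 2.55),
                           controlIndexDist = list(mean = 1.35, sd = 0.86),
                           dir = NULL) {
  if (nStudy < 0 || nControl < 0) stop("group sizes must be >= 0")
  for (d in list(studyIndexDist, controlIndexDist))
    if (!is.numeric(d$mean) || !is.numeric(d$sd) || d$sd < 0)
      stop("invalid index distribution parameters")
  set.seed(seed)
  n <- nStudy + nControl
  groups <- rep(c("study", "control"), c(nStudy, nControl))
  rates <- c(truncNorm(nStudy, studyIndexDist$mean, studyIndexDist$sd),
             truncNorm(nControl, controlIndexDist$mean, controlIndexDist$sd))
  seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1L))
  sexes <- sample(c("female", "male"), max(n, 1L), replace = TRUE,
                  prob = c(0.7, 0.3))
  ages <- round(stats::runif(max(n, 1L), 20, 60))
  twis <- integer(max(n, 1L))

  manifest <- data.frame(
    subject_id = character(0), group = character(0), sex = character(0),
    age = numeric(0), twi = integer(0), symptoms_present = logical(0),
    self_report_positive = logical(0), recording_path = character(0),
    stringsAsFactors = FALSE)
  recordings <- list(); truths <- list()
  if (!is.null(dir) && n > 0 && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  for (i in seq_len(n)) {
    id <- sprintf("%s%02d", ifelse(groups[i] == "study", "S", "C"), i)
    cfg <- config
    cfg@episodeRate <- rates[i]
    cfg@seed <- seeds[i]
    gen <- generateRecording(cfg, subjectId = id)
    twi <- if (groups[i] == "study") sample(1:2, 1L, prob = c(30, 5)) else 0L
    path <- paste0(id, ".edf")
    manifest <- rbind(manifest, data.frame(
      subject_id = id, group = groups[i], sex = sexes[i], age = ages[i],
      twi = twi,
      symptoms_present = groups[i] == "study",
      self_report_positive = groups[i] == "study",
      recording_path = path, stringsAsFactors = FALSE))
    truths[[id]] <- gen$truth
    if (is.null(dir)) {
      recordings[[id]] <- gen$recording
    } else {
      writeRecordingEdf(gen$recording, file.path(dir, path))
      writeGroundTruth(gen$truth, file.path(dir, paste0(id, ".truth.json")))
    }
  }
  if (!is.null(dir) && n > 0)
    writeManifest(manifest, file.path(dir, "manifest.csv"))
  list(manifest = manifest,
       recordings = if (is.null(dir)) recordings else NULL,
       truths = truths)
}
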