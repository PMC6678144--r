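test_that("same seed gives bit-identical samples and truth", {
  cfg <- shortNightConfig(seed = 21, nightDuration = 600)
  a <- generateRecording(cfg)
  b <- generateRecording(cfg)
  for (lab in channelLabels(a$recording)) {
    expect_identical(channelSamples(a$recording, lab),
                     channelSamples(b$recording, lab))
  }
  expect_identical(truthEvents(a$truth), truthEvents(b$truth))
  expect_identical(truthSurges(a$truth), truthSurges(b$truth))
})

test_that("an empty night has no events and a flat sleep envelope", {
  cfg <- generatorConfig(seed = 2, nightDuration = 600, episodeRate = 0,
                         confounderRate = 0, surgeOnlyRate = 0)
  g <- generateRecording(cfg)
  expect_equal(nrow(truthEvents(g$truth)), 0)
  expect_equal(trueIndex(g$truth), 0)
  env <- emgEnvelope(channelSamples(g$recording, "EMG_LEFT"), 500)
  sleep <- env@values[(100 * 500):(590 * 500)]
  # nothing in the sleep phase approaches the burst scale
  expect_lt(max(sleep), 0.1 * cfg@mvcAmplitude)
})

test_that("nights too short for the calibration prologue are rejected", {
  expect_error(generateRecording(generatorConfig(nightDuration = 50)),
               "too short")
})

test_that("planted structure satisfies its own invariants", {
  for (seed in c(5, 17)) {
    g <- generateRecording(shortNightConfig(seed = seed, nightDuration = 1200))
    ev <- truthEvents(g$truth)
    expect_false(is.unsorted(ev$onset))
    if (nrow(ev) > 1)
      expect_true(all(ev$onset[-1] >= ev$offset[-nrow(ev)]))
    cp <- ev[ev$coupled, ]
    expect_true(all(cp$lag >= 1 & cp$lag <= 5))
    expect_equal(cp$lag, cp$onset - cp$surgeOnset)
    hours <- (1200 - calibrationEnd(g$truth)) / 3600
    expect_equal(trueIndex(g$truth), nrow(cp) / hours)
    # surge-only surges never sit 1-5 s before a planted event onset
    so <- truthSurges(g$truth)
    so <- so$onset[so$kind == "surge_only"]
    for (s in so) expect_false(any(ev$onset - s >= 1 & ev$onset - s <= 5))
  }
})

test_that("planted bursts separate cleanly from the resting floor", {
  cfg <- shortNightConfig(seed = 8, nightDuration = 900, ampJitter = 0)
  g <- generateRecording(cfg)
  env <- emgEnvelope(channelSamples(g$recording, "EMG_LEFT"), 500)
  ev <- truthEvents(g$truth)
  expect_gt(nrow(ev), 0)
  thr <- 0.1 * cfg@mvcAmplitude
  inBurst <- rep(FALSE, length(env@values))
  for (i in seq_len(nrow(ev))) {
    b <- ev$bursts[[i]]
    for (j in seq_len(nrow(b))) {
      mid <- round(mean(b[j, ]) * 500)
      # burst cores clear the 10%-of-MVC line
      expect_gt(env@values[mid], thr)
      lo <- max(1, floor((b[j, 1] - 0.1) * 500))
      hi <- min(length(inBurst), ceiling((b[j, 2] + 0.1) * 500))
      inBurst[lo:hi] <- TRUE
    }
  }
  sleepIdx <- (ceiling(calibrationEnd(g$truth) * 500)):length(inBurst)
  quiet <- sleepIdx[!inBurst[sleepIdx]]
  expect_lt(max(env@values[quiet]), thr)
})

test_that("surge-free heart rate averages to the configured baseline", {
  cfg <- generatorConfig(seed = 6, nightDuration = 600, episodeRate = 0,
                         confounderRate = 0, surgeOnlyRate = 0,
                         baselineHr = 59.6)
  g <- generateRecording(cfg)
  beats <- detectRPeaks(channelSamples(g$recording, "ECG"), 250)
  hr <- heartRateSeries(beats)
  expect_equal(meanHeartRate(hr), 59.6, tolerance = 0.02)
  # planted beat count recovered within 1%
  expected <- 600 / (60 / 59.6)
  expect_lt(abs(length(beats) - expected) / expected, 0.01)
})

test_that("planted surges reach their configured magnitude", {
  cfg <- generatorConfig(seed = 13, nightDuration = 900, episodeRate = 8,
                         confounderRate = 0, surgeOnlyRate = 0)
  g <- generateRecording(cfg)
  beats <- detectRPeaks(channelSamples(g$recording, "ECG"), 250)
  hr <- heartRateSeries(beats)
  so <- truthSurges(g$truth)$onset
  expect_gt(length(so), 0)
  for (s in so) {
    win <- hr@rates[hr@beatTimes[-length(hr@beatTimes)] >= s - 0.2 &
                    hr@beatTimes[-length(hr@beatTimes)] <= s + 3]
    # surge-peak rate recovered within 5%
    expect_equal(max(win), (1 + cfg@surgeMagnitude) * cfg@baselineHr,
                 tolerance = 0.05)
  }
})

test_that("cohort generation honours sizes, groups and determinism", {
  cfg <- generatorConfig(nightDuration = 300)
  a <- generateCohort(2, 2, seed = 7, config = cfg)
  expect_equal(nrow(a$manifest), 4)
  expect_equal(as.vector(table(a$manifest$group)[c("study", "control")]),
               c(2L, 2L))
  expect_length(a$recordings, 4)
  b <- generateCohort(2, 2, seed = 7, config = cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(channelSamples(a$recordings[[1]], "EMG_LEFT"),
                   channelSamples(b$recordings[[1]], "EMG_LEFT"))

  empty <- generateCohort(0, 0, seed = 1, config = cfg)
  expect_equal(nrow(empty$manifest), 0)
  expect_length(empty$recordings, 0)

  expect_error(generateCohort(2, 2, seed = 1, config = cfg,
                              studyIndexDist = list(mean = 6, sd = -1)),
               "invalid")
})

test_that("planted study rates follow the configured truncated normal", {
  set.seed(1)
  draws <- bruxscore:::truncNorm(200, 6.04, 2.55)
  expect_true(all(draws >= 0))
  se <- stats::sd(draws) / sqrt(length(draws))
  # truncation at 0 is 2.4 sd out, so the mean shift is well under 3 SE
  expect_lt(abs(mean(draws) - 6.04), 3 * se)
})
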